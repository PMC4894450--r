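#' Effective contour model: energy-minimizing width profile
#'
#' Computes the instantaneous cell shape as a surface of revolution
#' `r(u)`, `u` in `[0, L]` from stalked tip to swarmer tip, by minimizing
#' the discretized wall energy
#' \deqn{E[r] = \int_0^L \Big[-P \pi r^2 + 2\pi\gamma(u)\, r\sqrt{1 + r'^2}
#'   + \frac{k_m}{2}\Big(\frac{1}{r} - c_0(u)\Big)^2
#'   2\pi r \sqrt{1 + r'^2}\Big]\, du}
#' with the tip radii held fixed.  The preferred circumferential curvature
#' field `c_0(u)` equals `1/R_m` along the cell body and, inside each pole
#' region, the inverse of that pole's Laplace radius `2 gamma_pole / P` —
#' so a stiffer (higher-tension) pole prefers a larger cap, and the two pole
#' maxima of the experimental width profile emerge with the stalked one the
#' larger.  The tension field `gamma(u)` is uniform except for a septal band
#' of width `delta` centered on the midpoint of the cell body (the region
#' between the two cap junctions); because a larger pole tension implies a
#' larger cap, raising `gamma_st / gamma_sw` displaces the mid-body point —
#' and with it the invagination — away from the stalked pole, linearly in
#' the tension ratio.
#'
#' Constriction is imposed as the constraint `w(l_st) = w_min` through a
#' quadratic penalty at the septal-band center.  Minimization uses L-BFGS-B
#' with an analytic gradient; by default the solver is run from two
#' different initial profiles and the solutions compared (`init_agreement`).
#' The reported invagination position is refined by parabolic interpolation
#' around the discrete minimum, so it varies smoothly below grid resolution.
#'
#' @param params a [mech_params()] object.
#' @param l total tip-to-tip length L, um.
#' @param w_min optional septal constraint width, um (`NULL`: unconstrained).
#' @param delta longitudinal extent of the septal band, um.
#' @param n_nodes number of discretization nodes (>= 100).
#' @param r_tip fixed tip radius, um.
#' @param penalty quadratic penalty weight for the septal constraint.
#' @param tol relative energy-change tolerance.
#' @param max_iter maximum optimizer iterations.
#' @param check_inits logical; relax from two initial profiles and compare.
#' @return list with `u`, `w` (profile), `invagination_fraction` (u/L of the
#'   interior width minimum, NA if the profile has no interior minimum),
#'   `energy`, `converged`, `init_agreement` (Linf distance between the two
#'   relaxed profiles, um), and the cap extents and band center.
#' @export
contour_model <- function(params, l = 2.9, w_min = NULL, delta = 0.3,
                          n_nodes = 200, r_tip = 0.08, penalty = 5e3,
                          tol = 1e-8, max_iter = 3000, check_inits = TRUE) {
  stopifnot(n_nodes >= 100, l > 0, r_tip > 0)
  p <- params
  u <- seq(0, l, length.out = n_nodes)
  du <- u[2] - u[1]
  cap_st <- laplace_pole(p$gamma_st, p$P)
  cap_sw <- laplace_pole(p$gamma_sw, p$P)
  band_c <- (cap_st + (l - cap_sw)) / 2
  um <- (u[-1] + u[-n_nodes]) / 2   # segment midpoints
  gam <- septal_tension_field(um, p, band_c, delta)
  c0 <- preferred_curvature_field(um, l, p, cap_st, cap_sw)
  # constraint applied at the (generally off-grid) band center via linear
  # interpolation between the bracketing nodes, so the minimum location
  # varies continuously with the tension ratio
  i_lo <- max(2L, min(n_nodes - 2L, findInterval(band_c, u)))
  alpha <- (band_c - u[i_lo]) / du
  r_target <- if (is.null(w_min)) NA_real_ else w_min / 2

  ener <- function(r) {
    rm <- (r[-1] + r[-n_nodes]) / 2
    ds <- sqrt(du^2 + diff(r)^2)
    e <- sum(-p$P * pi * rm^2 * du +
             (gam + p$k_m / 2 * (1 / rm - c0)^2) * 2 * pi * rm * ds)
    if (!is.na(r_target)) {
      r_site <- (1 - alpha) * r[i_lo] + alpha * r[i_lo + 1]
      e <- e + penalty * (r_site - r_target)^2
    }
    e
  }
  grad <- function(r) {
    rm <- (r[-1] + r[-n_nodes]) / 2
    dr <- diff(r)
    ds <- sqrt(du^2 + dr^2)
    well <- p$k_m / 2 * (1 / rm - c0)^2
    # segment energy: -P pi rm^2 du + c(rm) ds, c(rm) = 2 pi rm (gam + well)
    dc_drm <- 2 * pi * (gam + well +
                rm * p$k_m * (1 / rm - c0) * (-1 / rm^2))
    de_drm <- -2 * p$P * pi * rm * du + dc_drm * ds
    de_ddr <- 2 * pi * rm * (gam + well) * dr / ds
    n <- length(r)
    g <- numeric(n)
    g[-n] <- g[-n] + de_drm / 2 - de_ddr
    g[-1] <- g[-1] + de_drm / 2 + de_ddr
    if (!is.na(r_target)) {
      r_site <- (1 - alpha) * r[i_lo] + alpha * r[i_lo + 1]
      g[i_lo] <- g[i_lo] + 2 * penalty * (r_site - r_target) * (1 - alpha)
      g[i_lo + 1] <- g[i_lo + 1] + 2 * penalty * (r_site - r_target) * alpha
    }
    g
  }

  relax <- function(r0) {
    free <- seq(2, n_nodes - 1)
    fn <- function(x) { r <- r0; r[free] <- x; ener(r) }
    gr <- function(x) { r <- r0; r[free] <- x; grad(r)[free] }
    o <- stats::optim(r0[free], fn, gr, method = "L-BFGS-B",
                      lower = 0.03, upper = 1.2,
                      control = list(maxit = max_iter, factr = tol / 1e-15))
    r <- r0; r[free] <- o$par
    list(r = r, value = o$value, convergence = o$convergence)
  }

  init1 <- rep(0.37, n_nodes); init1[c(1, n_nodes)] <- r_tip
  init2 <- r_tip + (0.42 - r_tip) * sqrt(sin(pi * u / l))
  init2[c(1, n_nodes)] <- r_tip
  s1 <- relax(init1)
  sol <- s1
  agree <- NA_real_
  if (check_inits) {
    s2 <- relax(init2)
    agree <- max(abs(s1$r - s2$r))
    if (s2$value < sol$value) sol <- s2
  }
  if (sol$convergence != 0)
    warning("contour model did not converge: optimizer code ", sol$convergence)
  w <- 2 * sol$r
  interior <- seq(ceiling(n_nodes * 0.06), floor(n_nodes * 0.94))
  imin <- interior[local_minima_idx(w[interior])]
  if (length(imin)) {
    i0 <- imin[which.min(w[imin])]
    frac <- refine_extremum(u, w, i0) / l
  } else {
    frac <- NA_real_
  }
  list(u = u, w = w, invagination_fraction = frac,
       energy = sol$value, converged = sol$convergence == 0,
       init_agreement = agree,
       cap_st = cap_st, cap_sw = cap_sw, band_center = band_c)
}

septal_tension_field <- function(u, p, band_c, delta, ramp = 0.08) {
  p$gamma + (p$gamma_sep - p$gamma) *
    smooth_step((delta / 2 - abs(u - band_c)) / ramp)
}

preferred_curvature_field <- function(u, l, p, cap_st, cap_sw, ramp = 0.1) {
  c_body <- 1 / p$R_m
  c_st <- 1 / cap_st
  c_sw <- 1 / cap_sw
  c_body +
    (c_st - c_body) * smooth_step((cap_st - u) / ramp) +
    (c_sw - c_body) * smooth_step((u - (l - cap_sw)) / ramp)
}

smooth_step <- function(x) {
  # 0 for x <= -1, 1 for x >= 1, smooth in between
  y <- pmin(1, pmax(-1, x))
  (1 + sin(pi * y / 2)) / 2
}

local_minima_idx <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
}

# parabolic sub-grid refinement of an extremum location
refine_extremum <- function(u, y, i) {
  if (i <= 1 || i >= length(y)) return(u[i])
  d1 <- (y[i + 1] - y[i - 1]) / 2
  d2 <- y[i + 1] - 2 * y[i] + y[i - 1]
  if (abs(d2) < 1e-300) return(u[i])
  off <- -d1 / d2
  u[i] + max(-1, min(1, off)) * (u[2] - u[1])
}
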