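#' Septal geometry: area of new cell wall vs. constriction-zone width
#'
#' The constriction zone is modeled as two intersecting, partially formed
#' hemispheres of radius `w_max/2`.  Each forming cap is a spherical zone
#' running from its equator (where it meets the sidewall at width `w_max`)
#' to the current septal opening of diameter `w_min`; the zone height is
#' `d = sqrt((w_max/2)^2 - (w_min/2)^2)` and the zone area `2 pi (w_max/2) d`.
#' Summed over both caps,
#' \deqn{S = \pi w_{max} \sqrt{w_{max}^2 - w_{min}^2},}
#' with maximum `S_max = pi w_max^2` reached when the septum closes
#' (`w_min = 0`, two completed hemispheres of radius `w_max/2`).
#'
#' @param w_min current width of the constriction zone, um.
#' @param w_max diameter of the forming hemispheres, um.
#' @return `septal_area()`: synthesized septal area S, um^2.
#' @export
septal_area <- function(w_min, w_max) {
  stopifnot(all(w_max > 0))
  if (any(w_min < 0 | w_min > w_max))
    stop("w_min must lie in [0, w_max]")
  pi * w_max * sqrt(w_max^2 - w_min^2)
}

#' @rdname septal_area
#' @param S synthesized septal area, um^2.
#' @return `septal_width()`: the inverse map, `w_min(S)`.
#' @export
septal_width <- function(S, w_max) {
  s_max <- pi * w_max^2
  if (any(S < 0 | S > s_max + 1e-12))
    stop("S must lie in [0, pi * w_max^2]")
  S <- pmin(S, s_max)
  w_max * sqrt(pmax(0, 1 - (S / s_max)^2))
}

#' Kinetics of septal cell-wall synthesis
#'
#' New wall at the division plane initiates at rate `kappa_0` and thereafter
#' grows autocatalytically at rate `kappa_d`:
#' `dS/dt = kappa_0 + kappa_d * S`, `S(0) = 0`, whose solution is
#' \deqn{S(t) = \frac{\kappa_0}{\kappa_d}\left(e^{\kappa_d t} - 1\right),}
#' reducing to `kappa_0 * t` as `kappa_d -> 0`.
#'
#' @param t time since division, min (vectorized).
#' @param kappa0 initiation rate, um^2/min.
#' @param kappa_d autocatalytic rate, 1/min.
#' @return septal area S(t), um^2.
#' @export
septal_growth <- function(t, kappa0 = 0.016, kappa_d = 1 / 125) {
  stopifnot(kappa0 >= 0, kappa_d >= 0, all(t >= 0))
  if (kappa_d < 1e-12) return(kappa0 * t)
  kappa0 / kappa_d * (exp(kappa_d * t) - 1)
}

#' Width of the constriction zone over time
#'
#' Composes [septal_growth()] with the inverse septal geometry: once the
#' synthesized area reaches `S_max` the zone is pinched off and the width
#' reported as zero.
#'
#' @inheritParams septal_growth
#' @inheritParams septal_area
#' @return w_min(t), um; monotone non-increasing.
#' @export
w_min_trajectory <- function(t, w_max = 0.805, kappa0 = 0.016,
                             kappa_d = 1 / 125) {
  S <- pmin(septal_growth(t, kappa0, kappa_d), pi * w_max^2)
  septal_width(S, w_max)
}

#' Model-predicted average width and centerline radius during constriction
#'
#' Averages the simplified constricting shape (uniform tube plus the
#' two-partial-hemisphere constriction zone) along the medial axis to
#' predict the mean width, and maps the constriction onto the centerline
#' radius through a pluggable relation.  The default relation makes the
#' fractional increase in centerline curvature equal the fractional drop in
#' `w_min`, anchored at `R(phi = 0.5) = R_star`; supply `R_of_wmin` to
#' replace it.
#'
#' @param phi cell-cycle phase values in `[0, 1]`.
#' @param l cell length(s) at `phi`, um (recycled).
#' @param w_tube unconstricted tube width, um.
#' @param w_max constriction-zone hemisphere diameter, um.
#' @param wmin_fun function `phi -> w_min` (defaults to the printed-parameter
#'   trajectory via [w_min_trajectory()] with `tau` minutes per cycle).
#' @param tau division time used to convert `phi` to minutes.
#' @param delta optional longitudinal extent of the constriction zone, um;
#'   default uses the geometric extent `2 d` of the intersecting hemispheres.
#'   As `delta -> 0` the zone has vanishing measure and the mean width is
#'   unaffected.
#' @param R_star steady-state centerline radius anchor, um.
#' @param R_of_wmin optional function `(w_min, w_min_anchor) -> R`.
#' @return data.frame with `phi`, `w_min`, `w_bar`, `R`.
#' @export
constricting_averages <- function(phi, l = 2.9, w_tube = 0.72, w_max = 0.805,
                                  wmin_fun = NULL, tau = 73, delta = NULL,
                                  R_star = 4.44, R_of_wmin = NULL) {
  stopifnot(all(phi >= 0 & phi <= 1))
  if (is.null(wmin_fun))
    wmin_fun <- function(ph) w_min_trajectory(ph * tau)
  w_min <- pmin(wmin_fun(phi), w_max)
  l <- rep_len(l, length(phi))
  a <- w_max / 2
  d <- sqrt(pmax(0, a^2 - (w_min / 2)^2))
  # zone profile w(x) = 2 sqrt(a^2 - (d - |x|)^2), clipped at the sidewall
  # width (the forming hemispheres are wider than the tube near their
  # equators, but the measured profile there is still the sidewall)
  Fz <- function(y) y * sqrt(pmax(0, a^2 - y^2)) + a^2 * asin(pmin(1, y / a))
  y_t <- sqrt(pmax(0, a^2 - (pmin(w_tube, 2 * a) / 2)^2))
  yt_eff <- pmin(y_t, d)
  # per side: clipped stretch at w_tube plus the free neck part
  zone_int <- 2 * (w_tube * yt_eff + (Fz(d) - Fz(yt_eff)))
  ext <- if (is.null(delta)) 2 * d else pmin(delta, 2 * d)
  # compress the zone longitudinally to extent `ext` if delta is supplied
  scale <- ifelse(d > 0, ext / (2 * d), 0)
  w_bar <- w_tube + scale * (zone_int - w_tube * 2 * d) / l
  if (is.null(R_of_wmin)) {
    w_anchor <- pmin(wmin_fun(0.5), w_max)
    R <- R_star * w_min / w_anchor
  } else {
    R <- R_of_wmin(w_min, pmin(wmin_fun(0.5), w_max))
  }
  data.frame(phi = phi, w_min = w_min, w_bar = w_bar, R = R)
}
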