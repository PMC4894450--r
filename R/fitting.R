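#' Fit exponential growth to a length series
#'
#' Nonlinear least squares on `l = l0 * exp(kappa * t)`, initialized from
#' the log-linear regression; both the log-linear and the NLS estimates
#' are reported.
#'
#' @param t times, min (or `phi * tau`).
#' @param l lengths, um (strictly positive).
#' @param weights optional weights (e.g. 1/sd^2 of ensemble bins).
#' @return a `fit_result` list: `l0`, `kappa`, `kappa_inv`, `se_kappa`,
#'   `loglinear` (the initializing estimates), `residual_norm`,
#'   `converged`, `n`.
#' @export
fit_exponential <- function(t, l, weights = NULL) {
  ok <- is.finite(t) & is.finite(l)
  t <- t[ok]; l <- l[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(t) < 5) stop("need >= 5 points")
  if (any(l <= 0)) stop("lengths must be positive")
  lm0 <- stats::lm(log(l) ~ t, weights = weights)
  k0 <- unname(stats::coef(lm0)[2])
  a0 <- exp(unname(stats::coef(lm0)[1]))
  df <- data.frame(t = t, l = l)
  fit <- tryCatch(
    minpack.lm::nlsLM(l ~ l0 * exp(k * t), data = df,
                      start = list(l0 = a0, k = k0),
                      weights = if (is.null(weights))
                        rep(1, length(t)) else weights,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)   # degenerate data: keep the log-linear fit
  if (is.null(fit)) {
    return(structure(list(l0 = a0, kappa = k0, kappa_inv = 1 / k0,
                          se_kappa = NA_real_,
                          loglinear = list(l0 = a0, kappa = k0),
                          residual_norm = sqrt(sum((l - a0 * exp(k0 * t))^2)),
                          converged = TRUE, n = length(t)),
                     class = "fit_result"))
  }
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["k"]],
                 error = function(e) NA_real_)
  structure(list(l0 = unname(co[["l0"]]), kappa = unname(co[["k"]]),
                 kappa_inv = 1 / unname(co[["k"]]), se_kappa = se,
                 loglinear = list(l0 = a0, kappa = k0),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv, n = length(t)),
            class = "fit_result")
}

#' Constriction-width model
#'
#' `w_min(phi)` obtained by composing the septal kinetics with the septal
#' geometry:
#' `w_min = w_max * sqrt(1 - (S(phi * tau) / (pi w_max^2))^2)` with
#' `S(t) = (kappa0/kappa_d)(exp(kappa_d t) - 1)`, clipped at pinch-off.
#'
#' @param phi phase values.
#' @param w_max,kappa0,kappa_d model parameters.
#' @param tau division time, min.
#' @return predicted `w_min`, um.
#' @export
constriction_model <- function(phi, w_max, kappa0, kappa_d, tau) {
  S <- septal_growth(phi * tau, kappa0, kappa_d)
  s <- pmin(1, S / (pi * w_max^2))
  w_max * sqrt(pmax(0, 1 - s^2))
}

#' Fit the constriction kinetics to a w_min(phi) curve
#'
#' Weighted nonlinear least squares of [constriction_model()] to measured
#' minimum widths, restricted to `phi <= phi_max` (the pinch-off beyond
#' ~0.9 is below imaging resolution and is not fit).  Initialization:
#' `w_max` from the largest observed width, `kappa_d = 1/tau`, `kappa0`
#' from the earliest finite decrement.  When the inherited birth
#' invagination hides the early part of the curve (the measured width is
#' flat at the birth-dip level before the septal kinetics overtake it),
#' restrict the fit with `active_only = TRUE`, which drops leading bins
#' within `flat_tol` of the starting width.
#'
#' @param phi phases of the observations.
#' @param w_min observed minimum widths, um.
#' @param tau division time, min.
#' @param weights optional weights (e.g. 1/sd^2).
#' @param phi_max upper phase limit of the fit.
#' @param active_only drop the leading flat segment before fitting.
#' @param flat_tol flatness tolerance, um.
#' @return a `fit_result` list with `w_max`, `kappa0`, `kappa_d`, derived
#'   time constants `tau_d` (= 1/kappa_d) and `t_pinch` (time to reach
#'   S_max), `flat_input` flag, `converged`, `n`.
#' @export
fit_constriction <- function(phi, w_min, tau, weights = NULL,
                             phi_max = 0.9, active_only = FALSE,
                             flat_tol = 0.01) {
  ok <- is.finite(phi) & is.finite(w_min) & phi <= phi_max
  phi <- phi[ok]; w_min <- w_min[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (active_only && length(w_min) > 3) {
    start_w <- stats::median(w_min[seq_len(max(2, length(w_min) %/% 10))])
    drop <- cumprod(w_min > start_w - flat_tol) == 1
    keep <- !drop | seq_along(w_min) == max(1, sum(drop))
    if (sum(keep) >= 10) {
      phi <- phi[keep]; w_min <- w_min[keep]
      if (!is.null(weights)) weights <- weights[keep]
    }   # else: too little active signal, fit the full range
  }
  o <- order(phi)
  phi <- phi[o]; w_min <- w_min[o]
  if (!is.null(weights)) weights <- weights[o]
  if (length(phi) < 10) stop("need >= 10 points for the constriction fit")
  if (max(w_min) - min(w_min) < 1e-6) {
    return(structure(list(w_max = max(w_min), kappa0 = 0, kappa_d = NA_real_,
                          tau_d = NA_real_, t_pinch = NA_real_,
                          flat_input = TRUE, converged = FALSE,
                          n = length(phi)),
                     class = "fit_result"))
  }
  w0 <- max(w_min)
  kd0 <- 1 / tau
  i1 <- which(w_min < w0 - 1e-3)[1]
  k00 <- if (is.na(i1) || phi[i1] <= 0) 0.01 else {
    s1 <- septal_area(w_min[i1], w0 + 1e-6)
    max(1e-4, s1 / (phi[i1] * tau))
  }
  df <- data.frame(phi = phi, w = w_min)
  fit <- minpack.lm::nlsLM(
    w ~ constriction_model(phi, w_max, kappa0, kappa_d, tau),
    data = df,
    start = list(w_max = w0, kappa0 = k00, kappa_d = kd0),
    lower = c(w_max = 0.1, kappa0 = 1e-6, kappa_d = 1e-6),
    upper = c(w_max = 3, kappa0 = 1, kappa_d = 1),
    weights = if (is.null(weights)) rep(1, length(phi)) else weights,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- stats::coef(fit)
  s_max <- pi * co[["w_max"]]^2
  t_pinch <- log(1 + s_max * co[["kappa_d"]] / co[["kappa0"]]) /
    co[["kappa_d"]]
  structure(list(w_max = unname(co[["w_max"]]),
                 kappa0 = unname(co[["kappa0"]]),
                 kappa_d = unname(co[["kappa_d"]]),
                 tau_d = 1 / unname(co[["kappa_d"]]),
                 t_pinch = unname(t_pinch),
                 flat_input = FALSE,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = fit$convInfo$isConv, n = length(phi)),
            class = "fit_result")
}

#' Structured summary report of an analyzed ensemble
#'
#' Collects the headline quantities: mean interdivision time, fitted
#' growth time constant, the asymmetry fractions, the pole-width ratio and
#' (when computable) the pole-asymmetry correlation.  Missing pieces are
#' listed in `warnings` and the report stays partial rather than failing.
#'
#' @param records phase-normalized records (may be NULL).
#' @param growth_fit a `fit_result` from [fit_exponential()] (or NULL).
#' @param constriction_fit a `fit_result` from [fit_constriction()] (or
#'   NULL).
#' @param correlation result of [pole_asymmetry_stats()] (or NULL).
#' @return list of scalars, suitable for JSON export.
#' @export
summary_report <- function(records = NULL, growth_fit = NULL,
                           constriction_fit = NULL, correlation = NULL) {
  rep_ <- list()
  warn <- character(0)
  if (!is.null(records) && nrow(records)) {
    taus <- unique(records[, c("cell_id", "generation", "tau")])
    rep_$mean_tau_min <- mean(taus$tau)
    rep_$n_generations <- nrow(taus)
    rep_$mean_lst_over_l <- mean(records$l_st / records$l, na.rm = TRUE)
    rep_$mean_lst2_over_lst <- mean(records$l_st2 / records$l_st,
                                    na.rm = TRUE)
    rep_$mean_pole_ratio <- mean(records$w_max_st / records$w_max_sw,
                                 na.rm = TRUE)
  } else warn <- c(warn, "no records")
  if (!is.null(growth_fit)) {
    rep_$kappa_inv_min <- growth_fit$kappa_inv
  } else warn <- c(warn, "no growth fit")
  if (!is.null(constriction_fit) && isTRUE(constriction_fit$converged)) {
    rep_$w_max_um <- constriction_fit$w_max
    rep_$kappa0_um2_min <- constriction_fit$kappa0
    rep_$kappa_d_inv_min <- constriction_fit$tau_d
  } else warn <- c(warn, "no converged constriction fit")
  if (!is.null(correlation)) rep_$pole_asymmetry_r <- correlation$r
  rep_$warnings <- warn
  rep_
}
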