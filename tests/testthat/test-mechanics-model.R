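test_that("torus geometry obeys Pappus and its limits", {
  g <- torus_geometry(4.44, 0.72, 0.54)
  expect_equal(g$A_lat, 2 * pi * 0.36 * 4.44 * 0.54, tolerance = 1e-12)
  expect_equal(g$A_lat, 5.42, tolerance = 1e-3)
  # theta -> 0: sphere of diameter w
  g0 <- torus_geometry(4.44, 0.72, 0)
  expect_equal(g0$V, 4 / 3 * pi * 0.36^3, tolerance = 1e-12)
  # doubling theta doubles the lateral quantities exactly
  g2 <- torus_geometry(4.44, 0.72, 1.08)
  expect_equal(g2$A_lat, 2 * g$A_lat, tolerance = 1e-12)
  expect_equal(g2$V - g0$V, 2 * (g$V - g0$V), tolerance = 1e-12)
  expect_error(torus_geometry(0.3, 0.72, 0.5), "self-intersecting")
})

test_that("analytic energy gradients match central finite differences", {
  p <- mech_params()
  fd <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
  for (caps in c(TRUE, FALSE)) {
    for (pt in list(c(0.72, 4.44), c(0.5, 2), c(1.1, 8))) {
      g <- torus_geometry(pt[2], pt[1], 0.54)
      gr <- energy_gradient(g, p, include_caps = caps)
      fw <- fd(function(w) energy_total(torus_geometry(pt[2], w, 0.54), p,
                                        include_caps = caps), pt[1])
      fR <- fd(function(R) energy_total(torus_geometry(R, pt[1], 0.54), p,
                                        include_caps = caps), pt[2])
      expect_equal(unname(gr[1]), fw, tolerance = 1e-5)
      expect_equal(unname(gr[2]), fR, tolerance = 1e-5)
    }
  }
})

test_that("both harmonic wells vanish at their preferred curvatures", {
  p <- mech_params()
  g <- torus_geometry(p$R_c, 2 * p$R_m, 0.54)
  e_full <- energy_total(g, p)
  e_bare <- -p$P * g$V + p$gamma * g$A
  expect_equal(e_full, e_bare, tolerance = 1e-12)
})

test_that("without crescentin the energy is independent of R at fixed l", {
  p0 <- mech_params(k_c = 0)
  l <- 2.4
  e1 <- energy_total(torus_geometry(3, 0.72, l / 3), p0)
  e2 <- energy_total(torus_geometry(10, 0.72, l / 10), p0)
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("calibrated parameters give the observed steady state", {
  p <- calibrate_tension(mech_params(), w_star = 0.75, R_star = 4.44)
  # calibration lands near the round literature values
  expect_equal(p$gamma, 50, tolerance = 0.05)
  expect_equal(p$k_m, 40, tolerance = 0.05)
  ss <- steady_state_shape(p)
  expect_true(ss$interior)
  expect_true(ss$hessian_pd)
  expect_equal(ss$w, 0.75, tolerance = 1e-3)
  expect_equal(ss$R, 4.44, tolerance = 1e-3)
})

test_that("the optimizer agrees with a grid-search oracle", {
  p <- calibrate_tension(mech_params())
  ss <- steady_state_shape(p)
  wg <- seq(0.2, 1.6, length.out = 200)
  Rg <- seq(1, 20, length.out = 200)
  E <- outer(wg, Rg, function(w, R) {
    a <- w / 2; l <- R * 0.54
    -p$P * pi * a^2 * l + p$gamma * 2 * pi * a * l +
      p$k_m / 2 * (2 / w - 1 / p$R_m)^2 * 2 * pi * a * l +
      p$k_c / 2 * (1 / R - 1 / p$R_c)^2 * l
  })
  ij <- which(E == min(E), arr.ind = TRUE)
  expect_lt(abs(wg[ij[1]] - ss$w), diff(wg[1:2]) + 1e-9)
  expect_lt(abs(Rg[ij[2]] - ss$R), diff(Rg[1:2]) + 1e-9)
})

test_that("a stiff crescentin spring pins R at its preferred radius", {
  p <- calibrate_tension(mech_params())
  p2 <- mech_params(P = p$P, gamma = p$gamma, k_m = p$k_m, R_m = p$R_m,
                    k_c = 1e5, R_c = 0.5)
  ss <- steady_state_shape(p2, lower = c(0.2, 0.45))
  expect_equal(ss$R, 0.5, tolerance = 0.01)
})

test_that("growth is exponential with kappa = -Phi_theta * U", {
  p <- mech_params()
  g0 <- grow(0.54, p, 0)
  expect_equal(g0$theta, 0.54)
  g <- grow(0.54, p, 73)
  expect_equal(g$theta / 0.54, exp(73 / 125), tolerance = 5e-3)
  expect_equal(g$theta / 0.54, 1.79, tolerance = 5e-3)
  # self-consistency of the fitted energy density and mobility
  expect_lt(abs(p$Phi_theta * abs(p$U) * 125 - 1), 0.05)
  expect_warning(gs <- grow(0.54, p, 10, U = 1), "static")
  expect_equal(gs$kappa, 0)
})

test_that("Laplace's law sets pole size and tension ratio", {
  expect_equal(laplace_pole(50, 300), 1 / 3, tolerance = 1e-12)
  expect_equal(pole_tension_ratio(0.76, 0.76), 1)
  r <- pole_tension_ratio(0.805, 0.76)
  expect_gt(r, 1.05); expect_lt(r, 1.09)
})

test_that("septal area matches a surface-of-revolution quadrature", {
  w_max <- 0.805
  a <- w_max / 2
  oracle <- function(w_min) {
    # two spherical zones of radius a from the equator to opening w_min/2
    d <- sqrt(a^2 - (w_min / 2)^2)
    # z from 0 to d; profile r(z) = sqrt(a^2 - z^2)
    2 * stats::integrate(function(z) {
      r <- sqrt(a^2 - z^2)
      2 * pi * r * sqrt(1 + (z / r)^2)
    }, 0, d, rel.tol = 1e-10)$value
  }
  for (wm in c(0.1, 0.4, 0.6, 0.79)) {
    expect_equal(septal_area(wm, w_max), oracle(wm), tolerance = 1e-6)
  }
  expect_equal(septal_area(w_max, w_max), 0)
  expect_equal(septal_area(0, w_max), pi * w_max^2)
  expect_equal(septal_area(0.4, 0.805), 1.767, tolerance = 1e-3)
  expect_error(septal_area(1, 0.805), "w_min")
})

test_that("septal width inverts septal area to machine precision", {
  w_max <- 0.805
  wm <- seq(0, w_max, length.out = 101)
  expect_lt(max(abs(septal_width(septal_area(wm, w_max), w_max) - wm)),
            1e-10)
})

test_that("septal growth solves dS/dt = kappa0 + kappa_d S", {
  skip_if_not_installed("deSolve")
  tt <- seq(0, 73, by = 1)
  ode <- deSolve::ode(c(S = 0), tt, function(t, y, p)
    list(0.016 + y[1] / 125), NULL)
  expect_equal(septal_growth(tt), unname(ode[, "S"]), tolerance = 1e-6)
  expect_equal(septal_growth(73), 2 * (exp(0.584) - 1), tolerance = 1e-3)
  expect_equal(septal_growth(10, kappa_d = 0), 0.16)
  # composed trajectory is monotone non-increasing
  wt <- w_min_trajectory(seq(0, 200, by = 1))
  expect_true(all(diff(wt) <= 1e-12))
})

test_that("predicted mean width dips only while constricting", {
  phi <- seq(0, 1, by = 0.02)
  flat <- constricting_averages(phi, wmin_fun = function(p) rep(0.805,
                                                                length(p)))
  expect_true(all(abs(flat$w_bar - 0.72) < 1e-9))
  cur <- constricting_averages(phi)
  late <- cur$w_bar[phi > 0.5]
  expect_true(all(diff(late) < 1e-9))
  # a zero-measure constriction zone leaves the mean width unchanged
  z0 <- constricting_averages(phi, delta = 0)
  expect_true(all(abs(z0$w_bar - 0.72) < 1e-9))
  # the centerline radius drops with w_min past the anchor
  expect_lt(cur$R[length(phi)], cur$R[which.min(abs(phi - 0.5))])
})

test_that("the contour model is symmetric, convergent and monotone", {
  p_sym <- mech_params(gamma_st = 57, gamma_sw = 57)
  cm <- contour_model(p_sym, w_min = 0.5, n_nodes = 150)
  expect_true(cm$converged)
  expect_lt(cm$init_agreement, 1e-3)
  expect_equal(cm$invagination_fraction, 0.5, tolerance = 5e-3)
  fr <- vapply(c(1, 1.05, 1.1), function(r) {
    pp <- mech_params(gamma_st = 57 * r, gamma_sw = 57)
    contour_model(pp, w_min = 0.5, n_nodes = 150,
                  check_inits = FALSE)$invagination_fraction
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  # constraining at the tube width changes nothing
  un <- contour_model(p_sym, w_min = NULL, n_nodes = 150,
                      check_inits = FALSE)
  tu <- contour_model(p_sym, w_min = 2 * 0.37, n_nodes = 150,
                      check_inits = FALSE)
  expect_lt(max(abs(un$w - tu$w)), 2e-3)
})

test_that("energy bookkeeping: subunit count and thermal scale", {
  expect_equal(mpa_to_nn_um2(0.3), 300)
  n_lo <- peptidoglycan_subunits(12.5)
  n_hi <- peptidoglycan_subunits(25)
  expect_gt(n_hi, 1e6); expect_lt(n_lo, 1e6)
  e <- energy_per_subunit(2.4, 1e6)
  expect_equal(e / thermal_energy(31), 0.6, tolerance = 0.05)
})
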