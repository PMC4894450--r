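test_that("a capsule is measured exactly: length, width, mean width", {
  o <- capsule_outline(3, 0.8)
  ax <- medial_axis(o)
  expect_equal(attr(ax, "length"), 3, tolerance = 0.01 / 3)
  wp <- width_profile(o, ax)
  expect_true(all(abs(wp$w - 0.8) < 0.005))
  expect_equal(attr(wp, "w_bar"), 0.8, tolerance = 0.005 / 0.8)
})

test_that("the axis of a torus segment follows the true arc", {
  o <- torus_outline(R = 4.44, theta = 0.6)
  ax <- medial_axis(o)
  # generator arc: circle of radius 4.44 centered at (0, 4.44)
  d <- abs(sqrt(ax$x^2 + (ax$y - 4.44)^2) - 4.44)
  expect_lt(max(d), 0.01)
  expect_equal(attr(ax, "length"), 4.44 * 0.6 + 0.72, tolerance = 0.005)
  wp <- width_profile(o, ax)
  expect_equal(attr(wp, "w_bar"), 0.72, tolerance = 0.01)  # no curvature bias
})

test_that("mirroring the contour mirrors the axis", {
  o <- crescent_outline()
  om <- cbind(o[, 1], -o[, 2])
  ax <- medial_axis(o)
  axm <- medial_axis(om)
  # same u grid; y flipped (allow either axis direction)
  err1 <- max(abs(axm$y + ax$y), abs(axm$x - ax$x))
  err2 <- max(abs(rev(axm$y) + ax$y), abs(rev(axm$x) - ax$x))
  expect_lt(min(err1, err2), 5e-3)
})

test_that("the Taubin fit is exact on a circle and flags straight axes", {
  th <- seq(0.1, 0.7, length.out = 50)
  ax <- data.frame(u = 4.44 * (th - 0.1), x = 4.44 * sin(th),
                   y = 4.44 * (1 - cos(th)))
  fc <- fit_circle(ax)
  expect_equal(fc$R, 4.44, tolerance = 1e-3 / 4.44)
  expect_false(fc$straight)
  line <- data.frame(u = seq(0, 3, length.out = 30),
                     x = seq(0, 3, length.out = 30), y = 0)
  fl <- fit_circle(line)
  expect_true(fl$straight)
  expect_equal(fl$R, 1e3)
  expect_error(fit_circle(ax[1:4, ]), ">= 5")
})

test_that("the circle fit stays within 5% on noisy arcs", {
  th <- seq(0, 0.75, length.out = 50)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    ax <- data.frame(u = 4 * th, x = 4 * sin(th) + rnorm(50, 0, 0.01),
                     y = 4 * (1 - cos(th)) + rnorm(50, 0, 0.01))
    abs(fit_circle(ax)$R - 4) / 4
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
  expect_lt(mean(errs > 0.05), 0.05)
})

test_that("l = R * theta holds by construction", {
  o <- crescent_outline()
  ax <- medial_axis(o)
  fc <- fit_circle(ax)
  expect_equal(fc$R * fc$theta, attr(ax, "length") - 0,
               tolerance = 1e-12)
})

test_that("shape parameters are invariant under rigid motion", {
  o <- crescent_outline()
  ang <- 0.83
  rot <- cbind(o[, 1] * cos(ang) - o[, 2] * sin(ang) + 3.1,
               o[, 1] * sin(ang) + o[, 2] * cos(ang) - 1.2)
  m1 <- medial_axis(o); m2 <- medial_axis(rot)
  expect_lt(abs(attr(m2, "length") / attr(m1, "length") - 1), 0.005)
  w1 <- width_profile(o, m1); w2 <- width_profile(rot, m2)
  expect_lt(abs(attr(w2, "w_bar") / attr(w1, "w_bar") - 1), 0.005)
  expect_lt(abs(fit_circle(m2)$R / fit_circle(m1)$R - 1), 0.005)
})

test_that("a deep dip is found at its position and depth", {
  o <- crescent_outline(l_total = 3.18, frac = 0.54, w_min = 0.4)
  ax <- orient_axis(medial_axis(o), c(0, -0.4))
  wp <- width_profile(o, ax)
  inv <- find_invaginations(wp)
  expect_equal(unname(inv$l_st) / attr(wp, "l"), 0.54, tolerance = 0.01)
  expect_equal(unname(inv$primary["w"]), 0.4, tolerance = 0.01)
})

test_that("primary and secondary dips are told apart by depth", {
  o <- crescent_outline(secondary = TRUE, w_min = 0.5, w_sec = 0.67)
  ax <- orient_axis(medial_axis(o), c(0, -0.4))
  wp <- width_profile(o, ax)
  inv <- find_invaginations(wp)
  expect_equal(unname(inv$l_st) / attr(wp, "l"), 0.54, tolerance = 0.015)
  expect_false(is.null(inv$secondary_st))
  expect_equal(unname(inv$secondary_st["u"]) / unname(inv$l_st), 0.54,
               tolerance = 0.02)
  expect_gt(unname(inv$pole_st["w"]), unname(inv$pole_sw["w"]))
})

test_that("a uniform profile is flagged, with no extrema invented", {
  o <- capsule_outline(3, 0.8)
  ax <- medial_axis(o)
  wp <- width_profile(o, ax)
  inv <- find_invaginations(wp, smooth_w = 1)
  expect_true(inv$flagged)
  expect_true(is.na(inv$l_st2))
})

test_that("kymographs stack profiles on fixed grids", {
  o1 <- crescent_outline(3.0); o2 <- crescent_outline(3.4)
  mk <- function(o) { ax <- orient_axis(medial_axis(o), c(0, -0.4))
                      width_profile(o, ax) }
  ky1 <- kymograph(list(mk(o1)))
  expect_equal(nrow(ky1$absolute), 1)
  ky <- kymograph(list(mk(o1), mk(o2)), n_u = 80)
  expect_equal(dim(ky$absolute), c(2, 80))
  # the shorter cell leaves NA beyond its length on the absolute grid
  expect_true(any(is.na(ky$absolute[1, ])) && !all(is.na(ky$absolute[1, ])))
  # constant-width capsule rows are constant
  kc <- kymograph(list(mk(capsule_outline())), n_u = 50)
  vals <- kc$normalized[1, is.finite(kc$normalized[1, ])]
  expect_lt(diff(range(vals)), 0.01)
})
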