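test_that("straight uniform outline encloses l*w + pi*(w/2)^2", {
  o <- make_cell_outline(2.4, Inf, list(tube_width = 0.72))
  expect_equal(polygon_area(o), 2.4 * 0.72 + pi * 0.36^2, tolerance = 2e-3)
})

test_that("body arc length and tip-to-tip length follow l = R * theta", {
  o <- make_cell_outline(4.44 * 0.5405, 4.44, list(tube_width = 0.72))
  expect_equal(attr(o, "l_body"), 2.39982, tolerance = 1e-6)
  expect_equal(attr(o, "l_total"), attr(o, "l_body") + 0.72,
               tolerance = 1e-9)
})

test_that("a primary dip renders as the minimum rib at its set fraction", {
  o <- crescent_outline(l_total = 3.18, frac = 0.54, w_min = 0.5)
  ax <- orient_axis(medial_axis(o), c(0, -0.4))
  wp <- width_profile(o, ax)
  inv <- find_invaginations(wp)
  expect_equal(unname(inv$l_st) / attr(wp, "l"), 0.54, tolerance = 0.01)
  expect_equal(unname(inv$primary["w"]), 0.5, tolerance = 0.02)
})

test_that("outline construction rejects impossible geometries", {
  expect_error(make_cell_outline(5, 1.5, list(tube_width = 0.72)),
               "arc spans")
  expect_error(make_cell_outline(1, 0.34, list(tube_width = 0.72)),
               "self-intersecting")
})

test_that("noise-free growth is exponential with the set time constant", {
  cfg <- synth_config(n_cells = 1, n_generations = 3,
                      division_ratio_cv = 0,
                      noise = list(length_cv = 0, width_cv = 0), seed = 2)
  mv <- simulate_lineages(cfg)
  tr <- mv$truth[mv$truth$generation == 2, ]
  fit <- stats::lm(log(l_total) ~ t, data = tr)
  expect_gt(summary(fit)$r.squared, 0.9999)
  expect_equal(unname(coef(fit)[2]), 1 / 125, tolerance = 1e-6)
  # first cycle starts at the setpoint: interdivision time is the closed
  # form 125 * ln(1.8); later cycles settle at 125 * ln(1/0.54)
  g1 <- mv$truth[mv$truth$generation == 1, ]
  expect_equal(unique(g1$tau_true), 125 * log(1.8), tolerance = 1e-9)
  expect_equal(unique(tr$tau_true),
               125 * log(1.8 / (0.54 * 1.8 *
                 exp((ceiling(125 * log(1.8)) - 125 * log(1.8)) / 125))),
               tolerance = 1e-6)
})

test_that("zero generations give an empty series and log", {
  mv <- simulate_lineages(synth_config(n_cells = 1, n_generations = 0))
  expect_equal(nrow(mv$truth), 0)
  expect_equal(nrow(mv$divisions), 0)
})

test_that("a fixed seed reproduces the ground-truth log bit for bit", {
  cfg <- synth_config(n_cells = 2, n_generations = 3, seed = 42)
  expect_identical(simulate_lineages(cfg)$truth, simulate_lineages(cfg)$truth)
})

test_that("adding cells does not perturb existing per-cell streams", {
  t2 <- simulate_lineages(synth_config(n_cells = 2, n_generations = 2,
                                       seed = 9))$truth
  t3 <- simulate_lineages(synth_config(n_cells = 3, n_generations = 2,
                                       seed = 9))$truth
  expect_identical(t2, t3[t3$cell_id <= 2, ])
})

test_that("the division log inherits the secondary site exactly", {
  mv <- shared_movie()
  expect_true(all(mv$divisions$inherited_fraction ==
                    mv$config$asymmetry_fraction))
  # daughter generations start at the inherited fraction
  for (ci in unique(mv$truth$cell_id)) {
    tr <- mv$truth[mv$truth$cell_id == ci & mv$truth$generation > 1, ]
    expect_true(all(abs(tr$frac_primary - 0.54) < 1e-12))
  }
})

test_that("an empty frame renders as background plus noise", {
  cfg <- synth_config(seed = 3)
  set.seed(10)
  img <- render_frame(list(), cfg, blur = FALSE)
  expect_equal(mean(img), cfg$intensities$background, tolerance = 0.01)
  expect_equal(stats::sd(img), cfg$noise$photon_noise_sd, tolerance = 0.1)
})

test_that("rasterization fills the right number of pixels", {
  cfg <- synth_config(seed = 3)
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  disc <- cbind(64 + 20 * cos(th), 64 + 20 * sin(th))
  img <- render_frame(disc, cfg, noise = FALSE, blur = FALSE)
  dark <- sum(img < 0.5)
  expect_lt(abs(dark - pi * 20^2), 20)
})

test_that("a rendered default cell round-trips its area within 3%", {
  mv <- shared_movie()
  cc0 <- mv$cells[[1]]$contours[[20]]
  img <- render_frame(cc0, mv$config, noise = FALSE)
  cts <- extract_contours(img)
  expect_length(cts, 1)
  a <- abs(polygon_area(as.matrix(cts[[1]])))
  expect_lt(abs(a / abs(polygon_area(cc0)) - 1), 0.03)
})

test_that("a contour leaving the frame warns about clipping", {
  cfg <- synth_config(seed = 1)
  sq <- cbind(c(-5, 10, 10, -5), c(10, 10, 20, 20))
  expect_warning(render_frame(sq, cfg, noise = FALSE, blur = FALSE),
                 "clip")
})
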