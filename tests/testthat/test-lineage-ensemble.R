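test_that("phase normalization maps birth to 0 and division to 1", {
  rec <- data.frame(t = seq(0, 72, by = 1), l = 2.4)
  pn <- phase_normalize(rec, tau = 73)
  expect_equal(pn$phi[1], 0)
  expect_equal(pn$phi[pn$t == 36.5], numeric(0))  # integer frames only
  expect_equal(max(pn$phi), 72 / 73)
  expect_equal(phase_normalize(data.frame(t = c(0, 36.5, 73)), tau = 73,
                               min_frames = 3)$phi[2], 0.5)
})

test_that("too-short generations are excluded from binning", {
  expect_message(out <- phase_normalize(data.frame(t = 0:2), tau = 3),
                 "excluded")
  expect_null(out)
})

test_that("identical generations bin with zero spread", {
  rec <- do.call(rbind, lapply(1:5, function(g)
    data.frame(phi = seq(0.01, 0.99, by = 0.02), q = seq(2, 4, length.out = 50))))
  ec <- bin_ensemble(rec, "q", n_bins = 50)
  expect_true(all(ec$sd[ec$n > 1] < 1e-12))
  expect_true(all(ec$n > 0))
})

test_that("sparse records populate only their own bins", {
  rec <- data.frame(phi = c(0.1, 0.9), q = c(1, 2))
  ec <- bin_ensemble(rec, "q", n_bins = 10)
  expect_equal(sum(ec$n > 0), 2)
  expect_true(all(is.na(ec$mean[ec$n == 0])))
})

test_that("binning is invariant under generation permutation", {
  set.seed(4)
  rec <- data.frame(phi = runif(300), q = rnorm(300))
  ec1 <- bin_ensemble(rec, "q")
  ec2 <- bin_ensemble(rec[sample.int(300), ], "q")
  expect_equal(ec1, ec2)
})

test_that("two-generation series place mother phases as phi - 1", {
  mother <- data.frame(cell_id = 1, generation = 2,
                       phi = c(0.5, 0.8, 0.95), l_st2 = 0.7, l_st = 1.3,
                       l = 2.4)
  daughter <- data.frame(cell_id = 1, generation = 3,
                         phi = c(0, 0.2), l_st2 = NA, l_st = 0.75, l = 1.4)
  ts <- two_generation_series(mother, daughter)
  expect_equal(ts$phi[ts$side == "mother"], c(-0.5, -0.2, -0.05))
  expect_equal(ts$phi[ts$side == "daughter"], c(0, 0.2))
  bad <- daughter; bad$generation <- 5
  expect_error(two_generation_series(mother, bad), "linked")
})

test_that("stalked and swarmer fractions sum to one in every bin", {
  rec <- shared_truth_records()
  rec <- rec[is.finite(rec$l_st), ]
  expect_true(all(abs(rec$l_st + rec$l_sw - rec$l) < 1e-9))
})

test_that("measured stalked fraction is flat over the cycle at 0.54", {
  rec <- shared_truth_records()
  pn <- phase_normalize_all(rec, min_frames = 5)
  ec <- bin_ensemble(transform(pn, f = l_st / l), "f", n_bins = 10)
  expect_lt(max(abs(ec$mean[ec$n > 3] - 0.54)), 0.02)
})

test_that("the division site is inherited across generations", {
  rec <- shared_truth_records()
  pn <- phase_normalize_all(rec, min_frames = 5)
  inh <- inheritance_continuity(pn)
  expect_gt(inh$n_pre, 5)
  expect_gt(inh$n_post, 5)
  expect_lt(inh$gap, 0.02)
})

test_that("kymograph minima are continuous across a division", {
  rec <- shared_truth_records()
  mv <- shared_movie()
  cfg <- mv$config
  cell <- mv$cells[[1]]
  r1 <- rec[rec$cell_id == 1 & rec$generation %in% c(2, 3), ]
  profs <- lapply(as.character(r1$frame), function(k) {
    cc <- as.matrix(cell$contours[[k]]) * cfg$pixel_size
    ax <- orient_axis(medial_axis(cc), stalk_anchor_xy(mv, 1))
    width_profile(cc, ax)
  })
  ky <- kymograph(profs, n_u = 60)
  gen <- r1$generation
  last_m <- max(which(gen == 2)); first_d <- min(which(gen == 3))
  # column of the mother's secondary minimum just before division vs the
  # daughter's primary minimum just after: within 2 grid columns
  row_m <- ky$absolute[last_m, ]
  row_d <- ky$absolute[first_d, ]
  l_d <- r1$l[first_d]
  in_d <- ky$u_grid < l_d * 0.9 & ky$u_grid > l_d * 0.2
  col_d <- which(in_d)[which.min(row_d[in_d])]
  in_m <- ky$u_grid < l_d * 0.9 & ky$u_grid > l_d * 0.2
  col_m <- which(in_m)[which.min(row_m[in_m])]
  expect_lte(abs(col_m - col_d), 2)
})

test_that("pole asymmetry correlates when built in, not otherwise", {
  set.seed(11)
  n <- 200
  ratio_l <- exp(rnorm(n, log(0.54 / 0.46), 0.08))
  rec <- data.frame(phi = runif(n, 0, 0.1),
                    w_max_st = 0.76 * (1 + 0.05 * (ratio_l - mean(ratio_l))) +
                      rnorm(n, 0, 0.001),
                    w_max_sw = 0.76,
                    l_st = ratio_l / (1 + ratio_l) * 2.4)
  rec$l_sw <- 2.4 - rec$l_st
  ps <- pole_asymmetry_stats(rec, n_boot = 200, seed = 3)
  expect_gt(ps$r, 0.8)
  rec2 <- rec
  rec2$w_max_st <- 0.76 + rnorm(n, 0, 0.01)   # independent of lengths
  ps2 <- pole_asymmetry_stats(rec2, n_boot = 200, seed = 3)
  expect_lt(abs(ps2$r), 0.2)
  rec3 <- rec
  rec3$w_max_st <- rec3$w_max_sw   # degenerate ratio
  ps3 <- pole_asymmetry_stats(rec3, n_boot = 10, seed = 3)
  expect_false(ps3$defined)
})
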