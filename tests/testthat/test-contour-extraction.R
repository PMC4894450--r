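test_that("a blank noise image yields zero regions", {
  set.seed(1)
  img <- matrix(0.85 + rnorm(128 * 128, 0, 0.02), 128, 128)
  expect_equal(detect_cells(img)$n, 0)
})

test_that("one rendered cell is segmented with the right area", {
  mv <- shared_movie()
  cc0 <- mv$cells[[1]]$contours[[10]]
  set.seed(5)
  img <- render_frame(cc0, mv$config)
  det <- detect_cells(img)
  expect_equal(det$n, 1)
  expect_lt(abs(det$areas[1] / abs(polygon_area(cc0)) - 1), 0.1)
})

test_that("two well-separated cells give two regions, correctly placed", {
  cfg <- synth_config(image_shape = c(192L, 128L), seed = 1)
  o <- capsule_outline(2.5, 0.7) / cfg$pixel_size
  o <- sweep(o, 2, colMeans(o))   # center the outline on its centroid
  c1 <- sweep(o, 2, c(48, 64), "+")
  c2 <- sweep(o, 2, c(140, 64), "+")
  set.seed(2)
  img <- render_frame(list(c1, c2), cfg)
  det <- detect_cells(img)
  expect_equal(det$n, 2)
  cx <- sort(det$centroids[, 1])
  expect_lt(abs(cx[1] - 48), 3)
  expect_lt(abs(cx[2] - 140), 3)
})

test_that("splined pixelated circle recovers radius at sub-pixel accuracy", {
  xx <- matrix(0, 64, 64)
  ctr <- c(32.3, 31.7); r <- 15
  for (i in 1:64) for (j in 1:64)
    if ((i - ctr[1])^2 + (j - ctr[2])^2 <= r^2) xx[i, j] <- 1
  oc <- EBImage::ocontour(EBImage::Image(xx))[[1]] + 1
  cc <- spline_contour(oc)
  rad <- sqrt((cc$x - mean(cc$x))^2 + (cc$y - mean(cc$y))^2)
  expect_equal(mean(rad), 15, tolerance = 0.3 / 15)
  expect_lt(stats::sd(rad), 0.3)
})

test_that("a zero smoothing budget interpolates the boundary pixels", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  b <- cbind(20 + 8 * cos(th), 20 + 8 * sin(th))
  cc <- spline_contour(b, smooth_budget_px = 0, n_points = 32,
                       edge_offset_px = 0)
  d <- vapply(seq_len(nrow(b)), function(i)
    min(sqrt((cc$x - b[i, 1])^2 + (cc$y - b[i, 2])^2)), numeric(1))
  expect_lt(max(d), 1e-6)
})

test_that("degenerate boundary loops are rejected", {
  expect_error(spline_contour(cbind(1:5, 1:5)), "degenerate")
  expect_error(spline_contour(cbind(1:20, 1:20)), "degenerate")
})

test_that("extracted contours stay within half a pixel of the truth", {
  mv <- shared_movie()
  cc0 <- mv$cells[[1]]$contours[[25]]
  set.seed(8)
  img <- render_frame(cc0, mv$config)
  cc <- extract_contours(img)[[1]]
  d <- vapply(seq_len(nrow(cc)), function(i)
    min(sqrt((cc0[, 1] - cc$x[i])^2 + (cc0[, 2] - cc$y[i])^2)), numeric(1))
  expect_lt(mean(d), 0.5)
})

test_that("contour extraction is equivariant under integer translation", {
  mv <- shared_movie()
  cc0 <- mv$cells[[1]]$contours[[15]]
  img1 <- render_frame(cc0, mv$config, noise = FALSE)
  img2 <- render_frame(sweep(cc0, 2, c(7, -5), "+"), mv$config,
                       noise = FALSE)
  c1 <- extract_contours(img1)[[1]]
  c2 <- extract_contours(img2)[[1]]
  expect_equal(abs(polygon_area(as.matrix(c1))),
               abs(polygon_area(as.matrix(c2))), tolerance = 5e-3)
  expect_equal(mean(c2$x) - mean(c1$x), 7, tolerance = 0.05)
  expect_equal(mean(c2$y) - mean(c1$y), -5, tolerance = 0.05)
})

test_that("a stationary cell gives one track of full length", {
  o <- capsule_outline() * 10
  frames <- replicate(10, list(o), simplify = FALSE)
  tr <- track_cells(frames)
  expect_length(tr, 1)
  expect_length(tr[[1]]$frames, 10)
})

test_that("a gap longer than max_gap splits the track", {
  o <- capsule_outline() * 10
  frames <- c(replicate(3, list(o), simplify = FALSE),
              replicate(4, list(), simplify = FALSE),
              replicate(3, list(o), simplify = FALSE))
  tr <- track_cells(frames, max_gap = 2)
  expect_length(tr, 2)
})

test_that("division detection fires on a length drop, not on growth", {
  l <- c(seq(2.4, 4.3, by = 0.1), 2.35)
  dv <- detect_divisions(l)
  expect_equal(dv$division_at, length(l))
  expect_equal(detect_divisions(seq(2.4, 4.3, by = 0.1))$division_at,
               integer(0))
})

test_that("triple splits mark the generation as discarded", {
  l <- c(3, 3.1, 3.2, 3.3)
  dv <- detect_divisions(l, n_regions = c(1, 1, 3, 1))
  expect_true(any(dv$discard))
})

test_that("the generation filter is strictly 'more than'", {
  mk <- function(cid, ngen) {
    do.call(rbind, lapply(seq_len(ngen), function(g)
      data.frame(cell_id = cid, generation = g, frame = g * 10 + 1:3,
                 l = 2.5)))
  }
  rec <- rbind(mk("a", 10), mk("b", 11))
  out <- filter_trajectories(rec)
  expect_false("a" %in% out$records$cell_id)
  expect_true("b" %in% out$records$cell_id)
})

test_that("a single-frame length spike is removed, neighbors kept", {
  rec <- data.frame(cell_id = "c", generation = 1, frame = 1:20,
                    l = 2.5 * exp((1:20) / 125))
  rec$l[10] <- rec$l[10] * 1.3
  out <- filter_trajectories(rec, min_generations = 0)
  expect_false(10 %in% out$records$frame)
  expect_true(all(c(9, 11) %in% out$records$frame))
  expect_match(out$qc$reason, "spike")
})
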