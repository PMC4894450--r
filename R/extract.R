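#' Segment cell candidates in one frame
#'
#' Pixel-based edge detection in the style used for phase-contrast
#' bacterial movies: local Gaussian smoothing, a bottom-hat operation
#' (morphological closing minus the image, which highlights dark objects
#' narrower than the structuring disc), thresholding, and connected-
#' component labeling.  Regions below `min_area` pixels are discarded; a
#' blank image legitimately yields zero regions.
#'
#' @param image an [EBImage::Image] or matrix, grayscale in [0, 1], cells
#'   dark on bright.
#' @param params list of: `smooth_sigma` (px), `structuring_radius` (px,
#'   about one cell width), `threshold_method` (`"otsu"` or a fixed numeric
#'   threshold on the bottom-hat image), `min_area` (px).
#' @return list with `mask` (logical matrix), `labels` (integer matrix),
#'   `n`, `areas`, `centroids` (n x 2, px).
#' @export
detect_cells <- function(image,
                         params = list()) {
  p <- utils::modifyList(list(smooth_sigma = 1, structuring_radius = 12,
                              threshold_method = "otsu", min_area = 150,
                              min_contrast = 0.1),
                         params)
  img <- EBImage::Image(as.matrix(image))
  if (p$smooth_sigma > 0) img <- EBImage::gblur(img, sigma = p$smooth_sigma)
  brush <- EBImage::makeBrush(2 * p$structuring_radius + 1, shape = "disc")
  bh <- EBImage::closing(img, brush) - img   # bottom-hat: dark features
  bh[bh < 0] <- 0
  if (is.numeric(p$threshold_method)) {
    thr <- p$threshold_method
  } else {
    # Otsu gives a first cut; re-threshold at half the interior plateau so
    # the boundary sits at the mid-level of the edge ramp (Otsu alone lands
    # above it and biases the mask inward)
    thr0 <- EBImage::otsu(bh, range = c(0, max(1e-6, max(bh))))
    core <- EBImage::erode(bh > thr0, EBImage::makeBrush(5, "disc"))
    thr <- if (any(core > 0))
      max(stats::median(bh[core > 0]) / 2, 0.4 * thr0) else thr0
    # absolute contrast floor: smoothed shot noise percolates into large
    # low-contrast blobs that Otsu happily segments on a blank frame
    thr <- max(thr, p$min_contrast)
  }
  mask <- bh > thr
  labels <- EBImage::bwlabel(mask)
  plateau <- 2 * thr
  tab <- tabulate(labels[labels > 0])
  keep <- which(tab >= p$min_area)
  relab <- integer(length(tab))
  relab[keep] <- seq_along(keep)
  lm <- as.matrix(labels)
  lm[lm > 0] <- relab[lm[lm > 0]]
  cents <- NULL
  if (length(keep)) {
    idx <- which(lm > 0, arr.ind = TRUE)
    lab <- lm[lm > 0]
    cents <- cbind(tapply(idx[, 1], lab, mean), tapply(idx[, 2], lab, mean))
  }
  list(mask = lm > 0, labels = lm, n = length(keep),
       areas = tab[keep], centroids = cents,
       bottom_hat = as.matrix(bh), smoothed = as.matrix(img),
       edge_level = thr)
}

#' Sub-pixel contour from boundary pixels
#'
#' Fits a smoothing periodic curve through an ordered loop of boundary
#' pixel centers and evaluates it at `n_points` sub-pixel vertices.  The
#' smoother is a periodic Gaussian kernel smoother applied in the Fourier
#' (trigonometric) representation of the closed curve: the bandwidth is
#' the largest for which the total squared deviation from the boundary
#' pixels stays within the budget `n_pixels * smooth_budget_px^2`; with a
#' zero budget the curve interpolates the pixel centers.
#'
#' @param boundary k x 2 matrix of ordered boundary pixel coordinates
#'   forming one loop (k >= 8).
#' @param smooth_budget_px per-pixel RMS deviation budget, px.
#' @param n_points number of output vertices.
#' @param edge_offset_px outward offset applied to the smoothed curve:
#'   boundary-pixel centers lie half a pixel inside the segmented region,
#'   so 0.5 px recovers the region edge.
#' @return a `cell_contour`: data.frame with `x`, `y` (sub-pixel, px),
#'   counter-clockwise, closed implicitly.
#' @export
spline_contour <- function(boundary, smooth_budget_px = 0.15,
                           n_points = 200, edge_offset_px = 0.5) {
  boundary <- as.matrix(boundary)
  k <- nrow(boundary)
  if (k < 8) stop("degenerate loop: need >= 8 boundary pixels")
  if (abs(polygon_area(boundary)) < 1) stop("degenerate loop: zero area")
  z <- complex(real = boundary[, 1], imaginary = boundary[, 2])
  Z <- stats::fft(z) / k
  freq <- fourier_freqs(k)
  budget <- k * smooth_budget_px^2
  # Gaussian attenuation of the harmonics (a periodic kernel smoother in
  # arc length; no Gibbs ringing, unlike a hard truncation), with the
  # bandwidth chosen as the largest that keeps the total squared deviation
  # from the pixel centers within the budget
  perim <- sum(Mod(diff(c(z, z[1]))))
  atten <- function(sig) exp(-0.5 * (2 * pi * freq * sig / perim)^2)
  dev2 <- function(sig) k * sum(Mod(Z)^2 * (1 - atten(sig))^2)
  lo <- 0; hi <- perim / 4
  if (dev2(hi) > budget) {
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (dev2(mid) <= budget) lo <- mid else hi <- mid
    }
  } else lo <- hi
  Zs <- Z * atten(lo)
  tt <- seq(0, 1, length.out = n_points + 1)[-(n_points + 1)]
  basis <- exp(2i * pi * outer(tt, freq))
  zz <- as.vector(basis %*% Zs)
  if (edge_offset_px != 0) {
    # boundary-pixel centers sit half a pixel inside the true region edge;
    # push the curve outward along the local normal to compensate
    dz <- as.vector(basis %*% (Zs * 2i * pi * freq))
    nrm <- dz / Mod(dz) * (-1i)   # outward for counter-clockwise curves
    ccw <- polygon_area(cbind(Re(zz), Im(zz))) > 0
    zz <- zz + (if (ccw) 1 else -1) * edge_offset_px * nrm
  }
  out <- data.frame(x = Re(zz), y = Im(zz))
  if (polygon_area(as.matrix(out)) < 0) out <- out[rev(seq_len(nrow(out))), ]
  rownames(out) <- NULL
  class(out) <- c("cell_contour", "data.frame")
  out
}

fourier_freqs <- function(k) {
  f <- c(0, seq_len(k - 1))
  ifelse(f > k / 2, f - k, f)
}

#' Extract sub-pixel contours from one frame
#'
#' Convenience wrapper: [detect_cells()] then, for each labeled region, the
#' ordered boundary pixels (via [EBImage::ocontour()]) smoothed by
#' [spline_contour()].
#'
#' @inheritParams detect_cells
#' @inheritParams spline_contour
#' @return list of `cell_contour` objects (possibly empty).
#' @export
extract_contours <- function(image, params = list(),
                             smooth_budget_px = 0.15, n_points = 200,
                             subpixel = TRUE) {
  det <- detect_cells(image, params)
  if (det$n == 0) return(list())
  oc <- EBImage::ocontour(EBImage::Image(det$labels))
  out <- list()
  for (i in seq_along(oc)) {
    b <- oc[[i]] + 1  # ocontour is zero-based
    if (nrow(b) < 8) next
    cc <- spline_contour(b, smooth_budget_px, n_points,
                         edge_offset_px = if (subpixel) 0 else 0.5)
    if (subpixel)
      cc <- refine_contour_subpixel(cc, det$smoothed)
    out[[length(out) + 1L]] <- cc
  }
  out
}

#' Gray-level sub-pixel refinement of a contour
#'
#' Binary masks carry sub-pixel information only through staircase
#' dithering, which vanishes when an edge runs parallel to the pixel grid.
#' This step restores it from the gray values of the smoothed image (not
#' the bottom-hat, whose morphological closing distorts the edge zone):
#' each vertex is moved along its local outward normal to the point where
#' the intensity crosses the local mid-level between interior (dark) and
#' exterior (bright), found by linear interpolation of bilinearly sampled
#' values.  The shifts are lightly smoothed along the contour, and the
#' level-set convexity bias of the blur (about `sigma^2 * curvature / 2`)
#' is compensated.
#'
#' @param contour a `cell_contour` (px).
#' @param img smoothed image matrix (indexed \code{[x, y]}), cells dark.
#' @param max_shift_px search range along the normal, px.
#' @param blur_sigma_px assumed total edge blur (PSF plus analysis
#'   smoothing), used for the convexity correction of the level set.
#' @param step_px sampling step along the normal, px.
#' @return the refined `cell_contour`.
#' @export
refine_contour_subpixel <- function(contour, img, max_shift_px = 4,
                                    step_px = 0.25, blur_sigma_px = 1.4) {
  x <- contour$x; y <- contour$y
  n <- length(x)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1))
  tx <- x[ip] - x[im]; ty <- y[ip] - y[im]
  tl <- sqrt(tx^2 + ty^2)
  ccw <- polygon_area(cbind(x, y)) > 0
  sgn <- if (ccw) -1 else 1      # outward normal
  nx <- sgn * (-ty / tl); ny <- sgn * (tx / tl)
  offs <- seq(-max_shift_px, max_shift_px, by = step_px)
  # samples[i, j]: bh at vertex i displaced by offs[j] along the normal
  sx <- outer(nx, offs) + x
  sy <- outer(ny, offs) + y
  sv <- matrix(bilinear_sample(img, as.vector(sx), as.vector(sy)),
               n, length(offs))
  # per-vertex mid-level between the far interior and exterior values
  # (near-asymptotic at 2.5-4 px for the expected edge blur; closer
  # windows sit on the ramp and bias the level)
  lev <- (rowMeans(sv[, offs <= -2.5, drop = FALSE]) +
          rowMeans(sv[, offs >= 2.5, drop = FALSE])) / 2
  shift <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    row <- sv[i, ] < lev[i]   # dark interior
    # inside->outside transition nearest offset 0
    tr <- which(row[-length(row)] & !row[-1])
    if (!length(tr)) next
    j <- tr[which.min(abs(offs[tr]))]
    v1 <- sv[i, j]; v2 <- sv[i, j + 1]
    frac <- if (abs(v1 - v2) < 1e-12) 0.5 else (lev[i] - v1) / (v2 - v1)
    shift[i] <- offs[j] + frac * step_px
  }
  # vertices without a clean crossing (tips, deep notches) take the
  # interpolated shift of their neighbors rather than staying put
  if (anyNA(shift)) {
    if (all(is.na(shift))) shift[] <- 0 else {
      idx <- which(!is.na(shift))
      shift <- stats::approx(c(idx - n, idx, idx + n),
                             rep(shift[idx], 3), xout = seq_len(n))$y
    }
  }
  shift <- circular_smooth(shift, 3)
  # the mid-level set of a blurred edge is displaced toward the convex
  # side's center by about sigma^2 * curvature / 2; undo it (outward on
  # convex stretches, inward in concavities)
  kmag <- abs(polyline_curvature(x, y))
  ddx <- x[c(2:n, 1)] + x[c(n, 1:(n - 1))] - 2 * x
  ddy <- y[c(2:n, 1)] + y[c(n, 1:(n - 1))] - 2 * y
  conv <- -sign(ddx * nx + ddy * ny)   # +1 where center of curvature inside
  corr <- pmax(-0.5, pmin(0.5, blur_sigma_px^2 / 2 * kmag * conv))
  shift <- shift + circular_smooth(corr, 5)
  out <- data.frame(x = x + shift * nx, y = y + shift * ny)
  class(out) <- c("cell_contour", "data.frame")
  out
}

# discrete curvature (1/px) of a closed polyline
polyline_curvature <- function(x, y, k = 3) {
  n <- length(x)
  ip <- ((seq_len(n) - 1 + k) %% n) + 1
  im <- ((seq_len(n) - 1 - k) %% n) + 1
  ax <- x[im] - x; ay <- y[im] - y
  bx <- x[ip] - x; by <- y[ip] - y
  cr <- ax * by - ay * bx
  la <- sqrt(ax^2 + ay^2); lb <- sqrt(bx^2 + by^2)
  lc <- sqrt((x[ip] - x[im])^2 + (y[ip] - y[im])^2)
  2 * cr / pmax(1e-12, la * lb * lc)
}

bilinear_sample <- function(img, x, y) {
  W <- nrow(img); H <- ncol(img)
  x <- pmin(pmax(x, 1), W - 1e-9); y <- pmin(pmax(y, 1), H - 1e-9)
  x0 <- pmin(floor(x), W - 1); y0 <- pmin(floor(y), H - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i10] * fx * (1 - fy) +
    img[i01] * (1 - fx) * fy + img[i11] * fx * fy
}

circular_smooth <- function(v, k) {
  n <- length(v)
  out <- v
  h <- k %/% 2
  for (d in seq_len(h)) {
    out <- out + v[((seq_len(n) - 1 + d) %% n) + 1] +
      v[((seq_len(n) - 1 - d) %% n) + 1]
  }
  out / (2 * h + 1)
}

#' Track cells across frames
#'
#' Greedy nearest-centroid matching: each contour in frame `t+1` is
#' assigned to the open track whose last centroid is nearest, provided the
#' displacement is below `max_displacement_px` (the default accommodates
#' the centroid jump at division, about half the flushed daughter's
#' length); ties in distance are broken
#' by the smaller area difference.  Unmatched contours open new tracks;
#' tracks are bridged across up to `max_gap` missing frames.  Adequate for
#' adherent, sparse cells.
#'
#' @param frame_contours list over frames; each element a list of
#'   `cell_contour` objects.  Names are taken as frame indices if present.
#' @param max_displacement_px matching radius, px.
#' @param max_gap frames a track may go unseen before being closed.
#' @return list of tracks: each a list with `cell_id`, `frames` (integer
#'   vector) and `contours` (list).
#' @export
track_cells <- function(frame_contours, max_displacement_px = 25,
                        max_gap = 2) {
  fr_ids <- names(frame_contours)
  fr_ids <- if (is.null(fr_ids)) seq_along(frame_contours) else
    as.integer(fr_ids)
  tracks <- list()
  open <- integer(0)   # indices into tracks
  for (fi in seq_along(frame_contours)) {
    fr <- fr_ids[fi]
    cts <- frame_contours[[fi]]
    cents <- t(vapply(cts, function(cc) colMeans(as.matrix(cc)[, 1:2]),
                      numeric(2)))
    assigned <- rep(FALSE, length(cts))
    # open tracks matched in order of distance
    if (length(open) && length(cts)) {
      last_c <- t(vapply(tracks[open], function(tr)
        colMeans(as.matrix(tr$contours[[length(tr$contours)]])[, 1:2]),
        numeric(2)))
      dmat <- outer(seq_len(nrow(last_c)), seq_len(nrow(cents)),
                    Vectorize(function(i, j)
                      sqrt(sum((last_c[i, ] - cents[j, ])^2))))
      while (TRUE) {
        if (all(is.na(dmat)) || min(dmat, na.rm = TRUE) > max_displacement_px)
          break
        ij <- which(dmat == min(dmat, na.rm = TRUE), arr.ind = TRUE)
        if (nrow(ij) > 1) {  # tie: smallest area difference
          ad <- apply(ij, 1, function(rc) {
            tr <- tracks[[open[rc[1]]]]
            a1 <- abs(polygon_area(as.matrix(
              tr$contours[[length(tr$contours)]][, 1:2])))
            abs(a1 - abs(polygon_area(as.matrix(cts[[rc[2]]][, 1:2]))))
          })
          ij <- ij[which.min(ad), , drop = FALSE]
        }
        i <- ij[1, 1]; j <- ij[1, 2]
        ti <- open[i]
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, fr)
        tracks[[ti]]$contours <- c(tracks[[ti]]$contours, cts[j])
        assigned[j] <- TRUE
        dmat[i, ] <- NA; dmat[, j] <- NA
      }
    }
    for (j in which(!assigned)) {
      tracks[[length(tracks) + 1L]] <- list(cell_id = length(tracks) + 1L,
                                            frames = fr, contours = cts[j])
    }
    # close tracks unseen for more than max_gap frames
    open <- which(vapply(tracks, function(tr)
      fr - tr$frames[length(tr$frames)] <= max_gap, logical(1)))
  }
  tracks
}

#' Detect division events on a length series
#'
#' A division is declared at the first frame where the measured length
#' drops by more than `drop_fraction` between consecutive frames (in the
#' adherent-cell geometry the swarmer daughter is flushed away, so the
#' tracked object's length falls to the stalked fraction), or where the
#' tracked object splits into two labeled regions if `n_regions` is given.
#'
#' @param lengths numeric vector of per-frame lengths (um or px).
#' @param drop_fraction relative drop declaring a division.
#' @param n_regions optional integer vector of per-frame region counts for
#'   the tracked object; a 1 -> 2 transition also declares a division, and
#'   a jump to three or more flags the generation as discarded.
#' @return list with `division_at` (integer indices of the first frame of
#'   each new generation), `generation` (integer vector, one per frame),
#'   `discard` (logical vector of generations to drop).
#' @export
detect_divisions <- function(lengths, drop_fraction = 0.25,
                             n_regions = NULL) {
  stopifnot(length(lengths) >= 2)
  n <- length(lengths)
  drop <- which(lengths[-1] < (1 - drop_fraction) * lengths[-n]) + 1L
  splits <- integer(0)
  triple <- integer(0)
  if (!is.null(n_regions)) {
    splits <- which(n_regions[-1] >= 2 & n_regions[-n] == 1) + 1L
    triple <- which(n_regions >= 3)
  }
  division_at <- sort(unique(c(drop, splits)))
  generation <- cumsum(seq_len(n) %in% division_at) + 1L
  discard <- logical(max(generation))
  if (length(triple)) discard[unique(generation[triple])] <- TRUE
  list(division_at = division_at, generation = generation, discard = discard)
}

#' Filter trajectories for ensemble analysis
#'
#' Applies the inclusion rule (cells must have divided *more than*
#' `min_generations` times, i.e. a cell with exactly `min_generations`
#' generations is excluded) and removes spurious length spikes: frames
#' whose length deviates more than `z * robust sd` from a rolling median.
#'
#' @param records data.frame with columns `cell_id`, `generation`, `frame`,
#'   `l` (and anything else, carried through).
#' @param min_generations inclusion threshold (strict).
#' @param despike_window rolling-median window (odd).
#' @param despike_z robust z threshold.
#' @param rsd_floor lower bound on the robust sd, um, so that noise-free
#'   series are not shredded by a near-zero scale estimate.
#' @return list with `records` (retained rows) and `qc` (data.frame of
#'   discarded cells/frames with reasons).
#' @export
filter_trajectories <- function(records, min_generations = 10,
                                despike_window = 5, despike_z = 3,
                                rsd_floor = 0.01) {
  stopifnot(all(c("cell_id", "generation", "frame", "l") %in%
                  names(records)))
  qc <- list()
  ngen <- tapply(records$generation, records$cell_id,
                 function(g) length(unique(g)))
  drop_cells <- names(ngen)[ngen <= min_generations]
  if (length(drop_cells)) {
    qc[[length(qc) + 1L]] <- data.frame(
      cell_id = drop_cells, frame = NA_integer_,
      reason = sprintf("only %d generations (need > %d)",
                       as.integer(ngen[drop_cells]), min_generations))
    records <- records[!records$cell_id %in% drop_cells, , drop = FALSE]
  }
  keep <- rep(TRUE, nrow(records))
  if (nrow(records)) {
    grp <- interaction(records$cell_id, records$generation, drop = TRUE)
    for (g in levels(grp)) {
      idx <- which(grp == g)
      l <- records$l[idx]
      if (length(l) < 3) next
      med <- rolling_median(l, despike_window)
      res <- l - med
      rsd <- max(rsd_floor, 1.4826 * stats::mad(res, center = 0))
      bad <- abs(res) > despike_z * rsd
      if (any(bad)) {
        keep[idx[bad]] <- FALSE
        qc[[length(qc) + 1L]] <- data.frame(
          cell_id = records$cell_id[idx[bad]],
          frame = records$frame[idx[bad]],
          reason = "length spike removed")
      }
    }
  }
  list(records = records[keep, , drop = FALSE],
       qc = if (length(qc)) do.call(rbind, qc) else
         data.frame(cell_id = character(), frame = integer(),
                    reason = character()))
}

#' Remove single-frame spikes from a length series
#'
#' Flags frames whose length deviates more than `z` robust standard
#' deviations from a rolling median.  Sustained steps (real divisions)
#' survive because the rolling median follows them within half a window.
#'
#' @param l length series.
#' @param window rolling-median window (odd).
#' @param z robust z threshold.
#' @param rsd_floor lower bound on the scale estimate, um.
#' @return logical keep mask.
#' @export
despike_series <- function(l, window = 5, z = 3, rsd_floor = 0.01) {
  if (length(l) < 3) return(rep(TRUE, length(l)))
  med <- rolling_median(l, window)
  res <- l - med
  rsd <- max(rsd_floor, 1.4826 * stats::mad(res, center = 0))
  abs(res) <= z * rsd
}

rolling_median <- function(x, window = 5) {
  n <- length(x)
  h <- window %/% 2
  vapply(seq_len(n), function(i)
    stats::median(x[max(1, i - h):min(n, i + h)]), numeric(1))
}
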