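#' Medial axis of a cell contour
#'
#' Locates the two poles as the farthest-apart pair of contour points,
#' splits the contour into the two side arcs between them,
#' and takes the axis as the lightly smoothed midpoints of boundary points
#' matched by equal fractional arc length along the two sides, resampled to
#' uniform spacing in arc length.  `u = 0` at the first pole; orientation
#' (which pole is the stalked one) is decided at track level, see
#' [orient_axis()].
#'
#' @param contour a `cell_contour` or two-column matrix (any length unit).
#' @param n_axis number of uniformly spaced axis samples.
#' @param refine_iter rib-midpoint refinement passes.
#' @return a `medial_axis`: data.frame `u`, `x`, `y` with attributes
#'   `length` (pole-to-pole arc length) and `poles` (2 x 2 matrix).
#' @export
medial_axis <- function(contour, n_axis = 61, refine_iter = 3) {
  P <- as.matrix(contour)[, 1:2]
  if (nrow(P) < 16) stop("contour too short for a medial axis")
  P <- resample_closed(P, 192L)
  n <- nrow(P)
  # poles: the farthest-apart pair of contour points (diameter of the
  # convex hull), which is exact for tube-with-cap shapes and immune to the
  # high local curvature of invagination shoulders
  poles <- hull_diameter(P)
  i1 <- min(poles); i2 <- max(poles)
  sideA <- P[i1:i2, , drop = FALSE]
  sideB <- P[c(i2:n, 1:i1), , drop = FALSE]
  sideB <- sideB[rev(seq_len(nrow(sideB))), , drop = FALSE]
  m <- max(41, n_axis)
  A <- resample_polyline(sideA, m)
  B <- resample_polyline(sideB, m)
  mid <- (A + B) / 2
  # the fractional-arc-length pairing is biased on bent cells (the outer
  # side is longer); refine by replacing interior points with midpoints of
  # perpendicular ribs, which is a fixed point of the true centerline
  for (it in seq_len(refine_iter)) {
    mid <- smooth_polyline(mid)
    mid <- resample_polyline(mid, m)
    mid <- refine_axis_midpoints(mid, P)
  }
  # the refined interior is accurate but the cap neighborhoods are not:
  # trim them and extend the axis to the contour along its own best-fit
  # circle (or line, for straight cells)
  mid <- extend_axis_through_caps(mid, P)
  mid <- smooth_polyline(mid)
  mid <- resample_polyline(mid, n_axis)
  u <- c(0, cumsum(sqrt(rowSums(diff(mid)^2))))
  out <- data.frame(u = u, x = mid[, 1], y = mid[, 2])
  structure(out, length = u[n_axis], poles = rbind(P[i1, ], P[i2, ]),
            class = c("medial_axis", "data.frame"))
}

extend_axis_through_caps <- function(mid, P, trim_frac = 0.12) {
  m <- nrow(mid)
  k <- max(3L, round(trim_frac * m))
  core <- mid[(k + 1):(m - k), , drop = FALSE]
  nc <- nrow(core)
  step <- mean(sqrt(rowSums(diff(core)^2)))
  # extend along the local tangent, bending with the (clamped) local
  # curvature of the end window: exact for arc-shaped cells, and bounded
  # when the curvature estimate is noisy
  k2 <- min(nc - 1, max(4L, ceiling(0.5 / max(step, 1e-9))))
  head_seg <- core[seq_len(k2 + 1), , drop = FALSE]
  tail_seg <- core[(nc - k2):nc, , drop = FALSE]
  d_head <- end_direction(head_seg, rev = TRUE)
  d_tail <- end_direction(tail_seg, rev = FALSE)
  k_head <- end_curvature(head_seg, core[1, ], d_head)
  k_tail <- end_curvature(tail_seg, core[nc, ], d_tail)
  # the fitted window direction is the chord direction; rotate by half the
  # window's turn to get the tangent at the end point
  wl <- k2 * step
  d_head <- rotate_vec(d_head, k_head * wl / 2)
  d_tail <- rotate_vec(d_tail, k_tail * wl / 2)
  head_ext <- ray_to_boundary(core[1, ], d_head, P, step, kappa = k_head)
  tail_ext <- ray_to_boundary(core[nc, ], d_tail, P, step, kappa = k_tail)
  rbind(head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE], core,
        tail_ext)
}

# unit direction of travel at the end of a polyline segment (least-squares
# line through the points, oriented outward)
end_direction <- function(seg, rev) {
  cx <- colMeans(seg)
  sv <- svd(sweep(seg, 2, cx))$v[, 1]
  ref <- if (rev) seg[1, ] - seg[nrow(seg), ] else
    seg[nrow(seg), ] - seg[1, ]
  if (sum(sv * ref) < 0) sv <- -sv
  sv
}

# signed curvature of the end window (positive bends left of `d`),
# clamped so that a noisy fit cannot curl the extension back into the cell
end_curvature <- function(seg, p_end, d, clamp = 1 / 1.5) {
  tb <- tryCatch(taubin_circle(seg[, 1], seg[, 2]), error = function(e) NULL)
  if (is.null(tb) || !is.finite(tb$R) || tb$R < 1e-6) return(0)
  v <- tb$center - p_end
  sgn <- sign(d[1] * v[2] - d[2] * v[1])
  max(-clamp, min(clamp, sgn / tb$R))
}

rotate_vec <- function(d, a) {
  c(cos(a) * d[1] - sin(a) * d[2], sin(a) * d[1] + cos(a) * d[2])
}

ray_to_boundary <- function(p0, d, P, step, max_len = 1, kappa = 0) {
  pts <- NULL
  p <- p0
  trav <- 0
  rot <- kappa * step
  cs <- cos(rot); sn <- sin(rot)
  repeat {
    d <- c(cs * d[1] - sn * d[2], sn * d[1] + cs * d[2])
    q <- p + step * d
    trav <- trav + step
    if (!point_in_polygon(q, P)) {
      lo <- 0; hi <- step
      for (j in 1:25) {
        mid2 <- (lo + hi) / 2
        if (point_in_polygon(p + mid2 * d, P)) lo <- mid2 else hi <- mid2
      }
      pts <- rbind(pts, p + lo * d)
      break
    }
    pts <- rbind(pts, q)
    p <- q
    if (trav > max_len) break
  }
  if (is.null(pts)) matrix(numeric(0), 0, 2) else pts
}

point_in_polygon <- function(q, P) {
  n <- nrow(P)
  j <- c(2:n, 1L)
  x <- P[, 1]; y <- P[, 2]
  up <- (y <= q[2] & y[j] > q[2]) | (y[j] <= q[2] & y > q[2])
  if (!any(up)) return(FALSE)
  xi <- x[up] + (q[2] - y[up]) * (x[j][up] - x[up]) / (y[j][up] - y[up])
  sum(xi > q[1]) %% 2 == 1
}

hull_diameter <- function(P) {
  h <- grDevices::chull(P[, 1], P[, 2])
  H <- P[h, , drop = FALSE]
  d <- as.matrix(stats::dist(H))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  c(h[ij[1]], h[ij[2]])
}

refine_axis_midpoints <- function(mid, P) {
  m <- nrow(mid)
  tx <- c(mid[2, 1] - mid[1, 1], mid[3:m, 1] - mid[1:(m - 2), 1],
          mid[m, 1] - mid[m - 1, 1])
  ty <- c(mid[2, 2] - mid[1, 2], mid[3:m, 2] - mid[1:(m - 2), 2],
          mid[m, 2] - mid[m - 1, 2])
  tl <- sqrt(tx^2 + ty^2)
  nx <- -ty / tl; ny <- tx / tl
  idx <- 2:(m - 1)
  b <- rib_batch(P, mid[idx, 1], mid[idx, 2], nx[idx], ny[idx])
  out <- mid
  ok <- is.finite(b$w)
  out[idx[ok], 1] <- (b$x1[ok] + b$x2[ok]) / 2
  out[idx[ok], 2] <- (b$y1[ok] + b$y2[ok]) / 2
  out
}

# uniform arc-length resampling of a closed polygon (the Fourier low-pass
# assumes uniform parameterization)
resample_closed <- function(P, m) {
  if (any(P[1, ] != P[nrow(P), ])) P <- rbind(P, P[1, ])
  s <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  keep <- c(TRUE, diff(s) > 1e-12)
  P <- P[keep, , drop = FALSE]; s <- s[keep]
  si <- seq(0, s[length(s)], length.out = m + 1)[-(m + 1)]
  cbind(stats::approx(s, P[, 1], si)$y, stats::approx(s, P[, 2], si)$y)
}

resample_polyline <- function(P, m) {
  s <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  L <- s[length(s)]
  si <- seq(0, L, length.out = m)
  cbind(stats::approx(s, P[, 1], si)$y, stats::approx(s, P[, 2], si)$y)
}

smooth_polyline <- function(P, passes = 2) {
  for (i in seq_len(passes)) {
    n <- nrow(P)
    Q <- P
    Q[2:(n - 1), ] <- (P[1:(n - 2), ] + 2 * P[2:(n - 1), ] + P[3:n, ]) / 4
    P <- Q
  }
  P
}

#' Orient a medial axis so that u = 0 is the stalked pole
#'
#' @param axis a `medial_axis`.
#' @param stalk_xy coordinates of the stalk anchor (same units as the axis).
#' @return the axis, possibly reversed.
#' @export
orient_axis <- function(axis, stalk_xy) {
  d0 <- sum((c(axis$x[1], axis$y[1]) - stalk_xy)^2)
  d1 <- sum((c(axis$x[nrow(axis)], axis$y[nrow(axis)]) - stalk_xy)^2)
  if (d0 <= d1) return(axis)
  rev_axis(axis)
}

rev_axis <- function(axis) {
  n <- nrow(axis)
  out <- data.frame(u = axis$u[n] - rev(axis$u),
                    x = rev(axis$x), y = rev(axis$y))
  structure(out, length = attr(axis, "length"),
            poles = attr(axis, "poles")[2:1, ],
            class = c("medial_axis", "data.frame"))
}

#' Algebraic circle fit (Taubin) to a medial axis
#'
#' Least-squares circle minimizing the Taubin-normalized algebraic
#' distance.  Near-straight axes (sagitta below `straight_tol`) are
#' reported with the capped radius `straight_cap` and a straightness flag;
#' the spanning angle follows from `l = R * theta`.
#'
#' @param axis a `medial_axis` (or data.frame with `u`, `x`, `y`).
#' @param straight_tol sagitta below which the axis counts as straight
#'   (same units as the axis; 0.032 um is half a pixel at 0.064 um/px).
#' @param straight_cap radius reported for straight axes.
#' @return list with `R`, `theta`, `center`, `straight` (logical),
#'   `concave_side` (+1 / -1, sign of the sagitta).
#' @export
fit_circle <- function(axis, straight_tol = 0.032, straight_cap = 1e3) {
  x <- axis$x; y <- axis$y
  if (length(x) < 5) stop("need >= 5 axis points for a circle fit")
  l <- axis$u[length(axis$u)] - axis$u[1]
  # sagitta relative to the chord
  ch <- c(x[length(x)] - x[1], y[length(y)] - y[1])
  nv <- c(-ch[2], ch[1]) / sqrt(sum(ch^2))
  sag <- (x - x[1]) * nv[1] + (y - y[1]) * nv[2]
  side <- sign(sag[which.max(abs(sag))])
  if (max(abs(sag)) < straight_tol) {
    return(list(R = straight_cap, theta = l / straight_cap, center = c(NA, NA),
                straight = TRUE, concave_side = side))
  }
  tb <- taubin_circle(x, y)
  list(R = tb$R, theta = l / tb$R, center = tb$center,
       straight = FALSE, concave_side = side)
}

taubin_circle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  X <- x - mx; Y <- y - my
  Z <- X^2 + Y^2
  Mxx <- mean(X^2); Myy <- mean(Y^2); Mxy <- mean(X * Y)
  Mxz <- mean(X * Z); Myz <- mean(Y * Z); Mzz <- mean(Z^2)
  Mz <- Mxx + Myy
  Cov_xy <- Mxx * Myy - Mxy^2
  Var_z <- Mzz - Mz^2
  A3 <- 4 * Mz
  A2 <- -3 * Mz^2 - Mzz
  A1 <- Var_z * Mz + 4 * Cov_xy * Mz - Mxz^2 - Myz^2
  A0 <- Mxz^2 * Myy + Myz^2 * Mxx - Mzz * Cov_xy - 2 * Mxz * Myz * Mxy +
    Mz^2 * Cov_xy
  # Newton from 0 on the Taubin characteristic polynomial
  t <- 0
  for (i in 1:50) {
    ft <- A0 + t * (A1 + t * (A2 + t * A3))
    fp <- A1 + t * (2 * A2 + 3 * t * A3)
    if (abs(fp) < 1e-300) break
    t_new <- t - ft / fp
    if (!is.finite(t_new) || abs(t_new - t) < 1e-14 * (1 + abs(t))) {
      t <- t_new; break
    }
    t <- t_new
  }
  det <- Cov_xy - t * (Mxx + Myy - t) - (-t) * 0  # guard below
  den <- 2 * (Cov_xy - t * Mz + t^2)
  # solve the 2x2 linear system for the center
  a11 <- Mxx - t; a12 <- Mxy; a22 <- Myy - t
  b1 <- Mxz / 2; b2 <- Myz / 2
  dd <- a11 * a22 - a12^2
  cx <- (b1 * a22 - b2 * a12) / dd
  cy <- (b2 * a11 - b1 * a12) / dd
  R <- sqrt(cx^2 + cy^2 + Mz + 2 * t)
  list(R = R, center = c(cx + mx, cy + my))
}

#' Width profile along the medial axis
#'
#' At each axis sample inside the cap-exclusion window
#' `u in [w/2, l - w/2]` (just inside the pole caps), the rib is the chord
#' through the axis point perpendicular to the local axis tangent;\n#' the width is the distance
#' between the two contour intersections nearest the axis point on either
#' side (ribs crossing the contour more than twice take those two, and the
#' event is flagged).  The mean width `w_bar` is the average over the
#' window samples.
#'
#' @param contour a `cell_contour` or matrix.
#' @param axis a `medial_axis` (same units).
#' @param n_ribs number of rib positions (the axis is spline-interpolated
#'   to this resolution so narrow dips are finely sampled).
#' @return a `width_profile`: data.frame `u`, `w`, rib endpoints `x1`,
#'   `y1`, `x2`, `y2`; attributes `l`, `w_bar`, `window`, `n_multi`.
#' @export
width_profile <- function(contour, axis, n_ribs = 161) {
  P <- as.matrix(contour)[, 1:2]
  l <- attr(axis, "length")
  n0 <- nrow(axis)
  if (n_ribs > n0) {
    ui <- seq(axis$u[1], axis$u[n0], length.out = n_ribs)
    axis <- structure(data.frame(
      u = ui,
      x = stats::spline(axis$u, axis$x, xout = ui)$y,
      y = stats::spline(axis$u, axis$y, xout = ui)$y),
      length = l, class = c("medial_axis", "data.frame"))
  }
  n <- nrow(axis)
  # rib directions from the axis's global circle (or chord) fit: the
  # centerline of a toroidal-segment cell is an arc, and finite-difference
  # tangents pick up sub-pixel axis wobble that tilts the ribs -- a tilted
  # rib through a narrow invagination climbs the notch walls and
  # overstates the minimum width
  fc0 <- fit_circle(axis)
  if (fc0$straight) {
    ch <- c(axis$x[n] - axis$x[1], axis$y[n] - axis$y[1])
    tl <- sqrt(sum(ch^2))
    tx <- rep(ch[1] / tl, n); ty <- rep(ch[2] / tl, n)
  } else {
    rx <- axis$x - fc0$center[1]; ry <- axis$y - fc0$center[2]
    rl <- sqrt(rx^2 + ry^2)
    tx <- -ry / rl; ty <- rx / rl
    # orient along increasing u
    if (sum(tx * c(diff(axis$x), 0) + ty * c(diff(axis$y), 0)) < 0) {
      tx <- -tx; ty <- -ty
    }
  }
  nx <- -ty; ny <- tx
  # pass 1: rough width from mid-span ribs
  mid <- which(axis$u > 0.3 * l & axis$u < 0.7 * l)
  b0 <- rib_batch(P, axis$x[mid], axis$y[mid], nx[mid], ny[mid])
  w0 <- stats::median(b0$w, na.rm = TRUE)
  lo <- w0 / 2; hi <- l - w0 / 2
  sel <- which(axis$u >= lo & axis$u <= hi)
  b <- rib_batch(P, axis$x[sel], axis$y[sel], nx[sel], ny[sel])
  out <- data.frame(u = axis$u[sel], w = b$w, x1 = b$x1, y1 = b$y1,
                    x2 = b$x2, y2 = b$y2)
  out <- out[is.finite(out$w), , drop = FALSE]
  structure(out, l = l, w_bar = mean(out$w), window = c(lo, hi),
            n_multi = sum(b$multi, na.rm = TRUE),
            class = c("width_profile", "data.frame"))
}

rib_width <- function(P, ax, ay, nx, ny) {
  b <- rib_batch(P, ax, ay, nx, ny)
  list(w = b$w[1], p1 = c(b$x1[1], b$y1[1]), p2 = c(b$x2[1], b$y2[1]),
       multi = b$multi[1])
}

# vectorized rib casting: intersections of the lines point_i + t * normal_i
# with all polygon edges; returns, per point, the two crossings nearest the
# point on either side
rib_batch <- function(P, ax, ay, nx, ny) {
  nE <- nrow(P)
  j <- c(2:nE, 1L)
  ex <- P[j, 1] - P[, 1]; ey <- P[j, 2] - P[, 2]
  m <- length(ax)
  EX <- matrix(ex, m, nE, byrow = TRUE)
  EY <- matrix(ey, m, nE, byrow = TRUE)
  QX <- outer(-ax, P[, 1], "+")
  QY <- outer(-ay, P[, 2], "+")
  den <- nx * EY - ny * EX          # recycles nx, ny down columns
  tt <- (QX * EY - QY * EX) / den
  ss <- (QX * ny - QY * nx) / den
  valid <- is.finite(tt) & ss >= 0 & ss < 1 & abs(den) > 1e-12
  tpos <- tt; tpos[!valid | tt <= 1e-9] <- Inf
  tneg <- tt; tneg[!valid | tt >= -1e-9] <- -Inf
  tp <- apply(tpos, 1, min)
  tn <- apply(tneg, 1, max)
  npos <- rowSums(is.finite(tpos))
  nneg <- rowSums(is.finite(tneg))
  w <- tp - tn
  w[!is.finite(w)] <- NA_real_
  list(w = w,
       x1 = ax + tn * nx, y1 = ay + tn * ny,
       x2 = ax + tp * nx, y2 = ay + tp * ny,
       multi = npos + nneg > 2)
}

#' Locate the invaginations and pole maxima of a width profile
#'
#' The primary invagination is the deepest interior minimum of `w(u)`
#' (searched in `primary_window` as a fraction of `l`); its position from
#' the stalked pole is the stalked-compartment length `l_st`.  The pole
#' maxima are the largest values on either side of the primary.  Secondary
#' minima are local minima with prominence at least `prominence_min`
#' strictly between a pole maximum and the primary; the deepest per
#' compartment is reported, and `l_st2` is the position of the stalked-side
#' one.  Positions are refined by parabolic interpolation.  A profile with
#' no interior minimum is returned flagged.
#'
#' @param profile a `width_profile` (oriented: u = 0 at the stalked pole).
#' @param prominence_min minimum prominence of a secondary minimum, um.
#' @param primary_window fraction-of-length window searched for the
#'   primary minimum.
#' @param smooth_w moving-average half window (samples) applied before
#'   extremum detection; extremum heights are read from the raw profile.
#' @param baseline_extent rolling-max window, um, for the background
#'   envelope that invaginations are measured against (must exceed the
#'   longitudinal extent of an invagination).
#' @return list with `primary` (u, w), `l_st`, `pole_st`, `pole_sw`,
#'   `secondary_st`, `secondary_sw` (each (u, w) or NULL), `l_st2`,
#'   `flagged`.
#' @export
find_invaginations <- function(profile, prominence_min = 0.02,
                               primary_window = c(0.2, 0.8), smooth_w = 3,
                               baseline_extent = 0.45) {
  stopifnot(nrow(profile) >= 20)
  u <- profile$u
  w <- profile$w
  if (smooth_w > 1) {
    # light moving-average smoothing keeps shot-noise wiggles from posing
    # as invaginations; extrema values are re-read from the raw profile
    w <- as.numeric(stats::filter(w, rep(1 / smooth_w, smooth_w)))
    w[is.na(w)] <- profile$w[is.na(w)]
  }
  w_raw <- profile$w
  l <- attr(profile, "l")
  wd <- w
  win <- which(u >= primary_window[1] * l & u <= primary_window[2] * l)
  mins <- win[local_minima_idx_window(wd, win)]
  if (diff(range(wd[win])) < 0.005) mins <- integer(0)  # flat profile
  if (!length(mins)) {
    i0 <- win[which.min(w[win])]
    return(list(primary = c(u = u[i0], w = w[i0]), l_st = u[i0],
                pole_st = NULL, pole_sw = NULL,
                secondary_st = NULL, secondary_sw = NULL,
                l_st2 = NA_real_, flagged = TRUE))
  }
  # the primary is the most *prominent* interior minimum, not simply the
  # lowest: broad shelf artifacts on the sloped pole-bump background can
  # undercut a genuine invagination in raw depth but not in prominence
  prom_p <- vapply(mins, function(i) {
    lb <- if (i > win[1]) max(wd[win[1]:(i - 1)]) else -Inf
    rb <- if (i < win[length(win)]) max(wd[(i + 1):win[length(win)]]) else -Inf
    min(lb, rb) - wd[i]
  }, numeric(1))
  ip <- mins[which.max(prom_p)]
  up <- valley_centroid(u, wd, ip)
  w_at_p <- extremum_value(w_raw, ip)
  left <- seq_len(ip - 1); right <- seq(ip + 1, length(u))
  ist <- left[which.max(w[left])]
  isw <- right[which.max(w[right])]
  pole_st <- c(u = u[ist], w = w[ist])
  pole_sw <- c(u = u[isw], w = w[isw])
  sec <- function(seg) {
    if (length(seg) < 3) return(NULL)
    cand <- seg[local_minima_idx_window(wd, seg)]
    cand <- setdiff(cand, ip)
    if (!length(cand)) return(NULL)
    prom <- vapply(cand, function(i) {
      lb <- max(wd[seg[seg < i]], -Inf); rb <- max(wd[seg[seg > i]], -Inf)
      min(lb, rb) - wd[i]
    }, numeric(1))
    cand <- cand[prom >= prominence_min]
    if (!length(cand)) return(NULL)
    i <- cand[which.min(wd[cand])]
    c(u = valley_centroid(u, wd, i), w = w_raw[i])
  }
  secondary_st <- sec(seq(ist, ip))
  secondary_sw <- sec(seq(ip, isw))
  list(primary = c(u = up, w = w_at_p), l_st = up,
       pole_st = pole_st, pole_sw = pole_sw,
       secondary_st = secondary_st, secondary_sw = secondary_sw,
       l_st2 = if (is.null(secondary_st)) NA_real_ else secondary_st["u"],
       flagged = FALSE)
}


# center of a width-profile valley: intensity-weighted centroid of the
# region around the discrete minimum that stays within `depth` of it.
# Robust to the flat quantized bottoms that pixel-level dips produce,
# where a plain argmin can land anywhere on the plateau.
valley_centroid <- function(u, w, i0, depth = 0.02) {
  n <- length(w)
  cutoff <- w[i0] + depth
  a <- i0
  while (a > 1 && w[a - 1] <= cutoff) a <- a - 1
  b <- i0
  while (b < n && w[b + 1] <= cutoff) b <- b + 1
  idx <- a:b
  wt <- cutoff - w[idx]
  if (sum(wt) <= 0) return(u[i0])
  sum(u[idx] * wt) / sum(wt)
}

local_minima_idx_window <- function(w, win) {
  x <- w[win]
  local_minima_idx(x)
}

#' Kymograph of width profiles
#'
#' Stacks the width profiles of one or more consecutive generations into
#' matrices over (frame, position): one on an absolute stalked-pole-
#' anchored grid in u and one on the normalized grid u / l.  Positions a
#' profile does not cover are NA.
#'
#' @param profiles list of `width_profile` objects (oriented), in frame
#'   order.
#' @param n_u number of grid columns.
#' @return list with `absolute` and `normalized` matrices (rows = frames)
#'   and their grids `u_grid`, `rel_grid`.
#' @export
kymograph <- function(profiles, n_u = 100) {
  stopifnot(length(profiles) >= 1)
  lmax <- max(vapply(profiles, function(p) attr(p, "l"), numeric(1)))
  u_grid <- seq(0, lmax, length.out = n_u)
  rel_grid <- seq(0, 1, length.out = n_u)
  abs_m <- t(vapply(profiles, function(p)
    stats::approx(p$u, p$w, u_grid, rule = 1)$y, numeric(n_u)))
  rel_m <- t(vapply(profiles, function(p)
    stats::approx(p$u / attr(p, "l"), p$w, rel_grid, rule = 1)$y,
    numeric(n_u)))
  list(absolute = abs_m, normalized = rel_m,
       u_grid = u_grid, rel_grid = rel_grid)
}

rolling_max <- function(x, window) {
  n <- length(x)
  h <- window %/% 2
  vapply(seq_len(n), function(i) max(x[max(1, i - h):min(n, i + h)]),
         numeric(1))
}

# parabolic refinement of the extremum *value* around sample i (the grid
# rarely hits the exact bottom of a narrow dip)
extremum_value <- function(y, i) {
  lo <- max(1, i - 2); hi <- min(length(y), i + 2)
  j <- (lo:hi)[which.min(y[lo:hi])]
  if (j <= 1 || j >= length(y)) return(y[j])
  d1 <- (y[j + 1] - y[j - 1]) / 2
  d2 <- y[j + 1] - 2 * y[j] + y[j - 1]
  if (d2 <= 1e-300) return(y[j])
  y[j] - d1^2 / (2 * d2)
}

#' Export width profiles and kymographs as CSV
#'
#' `write_width_profiles()` writes a long-format table (cell, frame, u, w);
#' `write_kymograph()` writes one CSV matrix per grid (rows = frames).
#'
#' @param profiles named list of `width_profile` objects (names = frame).
#' @param path output CSV path.
#' @param cell_id id recorded in the long table.
#' @return invisibly, the path written.
#' @export
write_width_profiles <- function(profiles, path, cell_id = 1L) {
  rows <- lapply(names(profiles), function(k) {
    p <- profiles[[k]]
    data.frame(cell_id = cell_id, frame = k, u = p$u, w = p$w)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_width_profiles
#' @param ky a kymograph from [kymograph()].
#' @param prefix output path prefix (two files are written:
#'   `<prefix>_absolute.csv` and `<prefix>_normalized.csv`).
#' @export
write_kymograph <- function(ky, prefix) {
  pa <- paste0(prefix, "_absolute.csv")
  pn <- paste0(prefix, "_normalized.csv")
  utils::write.csv(as.data.frame(ky$absolute), pa, row.names = FALSE)
  utils::write.csv(as.data.frame(ky$normalized), pn, row.names = FALSE)
  invisible(c(pa, pn))
}
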