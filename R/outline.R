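#' Construct a ground-truth cell outline
#'
#' Builds a closed, simple, counter-clockwise outline of a crescent-shaped
#' cell: a circular-arc centerline of radius `R` and body arc length `l`,
#' locally perpendicular half-widths given by a width model (smooth bumps at
#' the poles, raised-cosine dips at invagination sites), and near-
#' hemispherical end caps centered on the body endpoints.  The outline is
#' assembled in a straight frame (axis along x from 0 to `l`) and bent by
#' the arc-length-preserving map onto the circle of radius `R`, so ribs stay
#' perpendicular to the centerline.  The stalked pole is at body coordinate
#' `u = 0`; the tip-to-tip medial length is `l + h(0) + h(l)`.
#'
#' @param l body arc length (centerline, between cap centers), um.
#' @param R centerline radius of curvature, um; `Inf` for a straight cell.
#' @param width_model list with `tube_width` and optionally `pole_width_st`,
#'   `pole_width_sw` (default: tube width, i.e. no bumps), and `bump_extent`.
#' @param dips optional data.frame with columns `u` (position on the body,
#'   um from the stalked cap center), `w` (target width at the dip center,
#'   um) and `extent` (longitudinal extent, um).  Dips whose target width
#'   exceeds the local width are ignored (depth clamped at zero).
#' @param n_axis,n_cap sampling densities of body sides and caps.
#' @return matrix with columns `x`, `y` (um, cell-local frame: stalked cap
#'   center at the origin, body extending toward +x before bending), with
#'   attributes `l_body`, `l_total`, `cap_st`, `cap_sw`.
#' @export
make_cell_outline <- function(l, R = Inf, width_model = list(tube_width = 0.72),
                              dips = NULL, n_axis = 240, n_cap = 30) {
  stopifnot(l > 0)
  wm <- utils::modifyList(list(tube_width = 0.72, pole_width_st = NULL,
                               pole_width_sw = NULL, bump_extent = 0.45),
                          width_model)
  if (is.null(wm$pole_width_st)) wm$pole_width_st <- wm$tube_width
  if (is.null(wm$pole_width_sw)) wm$pole_width_sw <- wm$tube_width
  if (is.finite(R)) {
    if (R <= l / pi) stop("arc spans >= pi: need R > l / pi")
    if (wm$tube_width >= 2 * R)
      stop("self-intersecting outline: width exceeds 2R")
  }

  half_width <- function(u) {
    h <- rep(wm$tube_width / 2, length(u))
    be <- wm$bump_extent
    bst <- (wm$pole_width_st - wm$tube_width) / 2
    bsw <- (wm$pole_width_sw - wm$tube_width) / 2
    sel <- u < be
    h[sel] <- h[sel] + bst * cos(pi * u[sel] / (2 * be))^2
    sel <- u > l - be
    h[sel] <- h[sel] + bsw * cos(pi * (l - u[sel]) / (2 * be))^2
    if (!is.null(dips) && nrow(dips)) {
      for (k in seq_len(nrow(dips))) {
        d <- dips[k, ]
        base_k <- half_width_nodips(d$u, wm, l)
        depth <- base_k - d$w / 2
        if (depth <= 0) next
        sel <- abs(u - d$u) < d$extent / 2
        h[sel] <- h[sel] - depth *
          (1 + cos(2 * pi * (u[sel] - d$u) / d$extent)) / 2
      }
    }
    h
  }

  u <- seq(0, l, length.out = n_axis)
  h <- half_width(u)
  if (any(h <= 0)) stop("width model gives non-positive width")
  r_st <- h[1]; r_sw <- h[n_axis]

  # straight-frame outline: side at +h, swarmer cap, side at -h, stalked cap
  ang_sw <- seq(pi / 2, -pi / 2, length.out = n_cap)
  ang_st <- seq(-pi / 2, -3 * pi / 2, length.out = n_cap)
  xs <- c(u, l + r_sw * cos(ang_sw), rev(u), r_st * cos(ang_st))
  ys <- c(h, r_sw * sin(ang_sw), -rev(h), r_st * sin(ang_st))
  # drop duplicated junction points
  keep <- c(TRUE, abs(diff(xs)) + abs(diff(ys)) > 1e-9)
  xs <- xs[keep]; ys <- ys[keep]
  if (sqrt((xs[1] - xs[length(xs)])^2 + (ys[1] - ys[length(ys)])^2) < 1e-9) {
    xs <- xs[-length(xs)]; ys <- ys[-length(ys)]
  }

  if (is.finite(R)) {
    # bend: (u, v) -> arc of radius R - v at angle u / R, curving upward
    phi <- xs / R
    rad <- R - ys
    xb <- rad * sin(phi)
    yb <- R - rad * cos(phi)
    xs <- xb; ys <- yb
  }
  out <- cbind(x = xs, y = ys)
  if (polygon_area(out) < 0) out <- out[rev(seq_len(nrow(out))), ]
  structure(out, l_body = l, l_total = l + r_st + r_sw,
            cap_st = r_st, cap_sw = r_sw)
}

half_width_nodips <- function(u, wm, l) {
  h <- wm$tube_width / 2
  be <- wm$bump_extent
  if (u < be) h <- h + (wm$pole_width_st - wm$tube_width) / 2 *
      cos(pi * u / (2 * be))^2
  if (u > l - be) h <- h + (wm$pole_width_sw - wm$tube_width) / 2 *
      cos(pi * (l - u) / (2 * be))^2
  h
}

#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise vertex order in a y-up frame.
#'
#' @param xy two-column matrix of vertices (closed implicitly).
#' @return signed area.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}
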