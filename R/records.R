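#' Shape records for a tracked cell
#'
#' Converts the per-frame contours of one track to physical units, builds
#' the medial axis of each, assigns the stalked pole, and measures every
#' shape parameter: pole-to-pole length `l`, centerline radius `R` and
#' spanning angle `theta = l / R`, mean width `w_bar`, the invagination set
#' (`w_min`, `l_st`, `l_st2`) and the pole maxima.  All px-to-um conversion
#' happens here, once, using `pixel_size`.
#'
#' Stalked-pole assignment: cells adhere by the stalk, so the stalked pole
#' is the axis endpoint whose position varies least over the track; pass
#' `stalk_xy` (um) to pin it instead (e.g. from ground truth).
#'
#' @param track a track from [track_cells()] (fields `frames`, `contours`).
#' @param pixel_size um per px.
#' @param frame_interval minutes per frame.
#' @param cell_id identifier carried into the records.
#' @param stalk_xy optional known stalk anchor, um.
#' @param prominence_min passed to [find_invaginations()].
#' @return data.frame, one row per frame, plus a list-column-free set of
#'   scalars; the width profiles are attached as attribute `profiles`.
#' @export
track_shape_records <- function(track, pixel_size = 0.064,
                                frame_interval = 1, cell_id = track$cell_id,
                                stalk_xy = NULL, prominence_min = 0.02) {
  nf <- length(track$frames)
  axes <- vector("list", nf)
  for (i in seq_len(nf)) {
    cc <- as.matrix(track$contours[[i]])[, 1:2] * pixel_size
    axes[[i]] <- medial_axis(cc)
  }
  axes <- align_axes(axes)
  if (is.null(stalk_xy)) {
    e1 <- t(vapply(axes, function(a) c(a$x[1], a$y[1]), numeric(2)))
    e2 <- t(vapply(axes, function(a) c(a$x[nrow(a)], a$y[nrow(a)]),
                   numeric(2)))
    if (sum(apply(e1, 2, stats::var)) > sum(apply(e2, 2, stats::var)))
      axes <- lapply(axes, rev_axis)
  } else {
    axes <- lapply(axes, orient_axis, stalk_xy = stalk_xy)
  }
  rows <- vector("list", nf)
  profiles <- vector("list", nf)
  for (i in seq_len(nf)) {
    cc <- as.matrix(track$contours[[i]])[, 1:2] * pixel_size
    ax <- axes[[i]]
    l <- attr(ax, "length")
    fc <- fit_circle(ax)
    wp <- width_profile(cc, ax)
    inv <- if (nrow(wp) >= 20) find_invaginations(wp, prominence_min)
           else list(primary = c(u = NA, w = NA), l_st = NA_real_,
                     pole_st = NULL, pole_sw = NULL, secondary_st = NULL,
                     l_st2 = NA_real_, flagged = TRUE)
    profiles[[i]] <- wp
    rows[[i]] <- data.frame(
      cell_id = cell_id, frame = track$frames[i],
      t = track$frames[i] * frame_interval,
      l = l, R = fc$R, theta = fc$theta, straight = fc$straight,
      w_bar = attr(wp, "w_bar"),
      w_min = unname(inv$primary["w"]),
      l_st = unname(inv$l_st), l_sw = l - unname(inv$l_st),
      l_st2 = unname(inv$l_st2),
      w_max_st = if (is.null(inv$pole_st)) NA_real_ else
        unname(inv$pole_st["w"]),
      w_max_sw = if (is.null(inv$pole_sw)) NA_real_ else
        unname(inv$pole_sw["w"]),
      flagged = inv$flagged)
  }
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- profiles
  out
}

# flip axes so that endpoint 1 stays near the previous frame's endpoint 1
align_axes <- function(axes) {
  for (i in seq_along(axes)[-1]) {
    prev <- axes[[i - 1]]; cur <- axes[[i]]
    p1 <- c(prev$x[1], prev$y[1])
    d_keep <- sum((c(cur$x[1], cur$y[1]) - p1)^2)
    d_flip <- sum((c(cur$x[nrow(cur)], cur$y[nrow(cur)]) - p1)^2)
    if (d_flip < d_keep) axes[[i]] <- rev_axis(cur)
  }
  axes
}

#' Split a cell's records into generations at detected divisions
#'
#' Runs [detect_divisions()] on the length series, assigns generation
#' indices, and marks which generations are complete (observed birth and
#' observed division).
#'
#' @param records per-frame records of one cell (from
#'   [track_shape_records()]).
#' @param drop_fraction see [detect_divisions()].
#' @return the records with columns `generation` and `complete` added.
#' @export
annotate_generations <- function(records, drop_fraction = 0.25) {
  dv <- detect_divisions(records$l, drop_fraction)
  records$generation <- dv$generation
  ng <- max(dv$generation)
  # first generation: birth not observed; last: division not observed
  records$complete <- records$generation > 1 & records$generation < ng
  records
}
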