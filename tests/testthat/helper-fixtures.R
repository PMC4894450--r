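# analytic fixtures and a shared small synthetic run, built once per session

capsule_outline <- function(l_total = 3, w = 0.8) {
  # tip-to-tip length l_total: body = l_total - w (two cap radii of w/2)
  make_cell_outline(l_total - w, Inf, list(tube_width = w))
}

torus_outline <- function(R = 4.44, theta = 0.6, w = 0.72) {
  make_cell_outline(R * theta, R, list(tube_width = w))
}

# default-shaped cell with pole bumps and a primary dip at `frac` of the
# tip-to-tip length (and optionally a secondary at frac^2)
crescent_outline <- function(l_total = 3.18, frac = 0.54, w_min = 0.5,
                             secondary = FALSE, w_sec = 0.67) {
  r_st <- 0.805 / 2; r_sw <- 0.76 / 2
  dips <- data.frame(u = frac * l_total - r_st, w = w_min, extent = 0.3)
  if (secondary)
    dips <- rbind(dips, data.frame(u = frac^2 * l_total - r_st, w = w_sec,
                                   extent = 0.3))
  make_cell_outline(l_total - r_st - r_sw, 4.44,
                    list(tube_width = 0.72, pole_width_st = 0.805,
                         pole_width_sw = 0.76),
                    dips = dips)
}

# memoised shared objects (expensive; reused across test files)
.shared <- new.env(parent = emptyenv())

shared_movie <- function() {
  if (is.null(.shared$movie))
    .shared$movie <- simulate_lineages(
      synth_config(n_cells = 2, n_generations = 4, seed = 7))
  .shared$movie
}

# records measured from the generator's own contours (no rendering), for
# tests of the geometry/ensemble layers in isolation
shared_truth_records <- function() {
  if (!is.null(.shared$truth_records)) return(.shared$truth_records)
  mv <- shared_movie()
  cfg <- mv$config
  recs <- list()
  for (cell in mv$cells) {
    tr <- list(cell_id = cell$cell_id,
               frames = as.integer(names(cell$contours)),
               contours = unname(cell$contours))
    rr <- track_shape_records(tr, pixel_size = cfg$pixel_size,
                              stalk_xy = stalk_anchor_xy(mv, cell$cell_id))
    rr <- annotate_generations(rr)
    recs[[length(recs) + 1L]] <- rr
  }
  .shared$truth_records <- do.call(rbind, recs)
  .shared$truth_records
}
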