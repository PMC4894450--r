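#' Simulate adherent cell lineages with ground truth
#'
#' Simulates `n_cells` stalked (surface-adherent) cells for `n_generations`
#' complete division cycles each, mirroring the experimental situation in
#' which the stalked daughter stays put after every division and the swarmer
#' daughter is flushed away by the medium flow.  Within a generation the
#' tip-to-tip length grows exponentially, `l(t) = l0 exp(t / tau_growth)`;
#' division triggers when `l / l0` reaches a ratio drawn around the critical
#' multiple; the primary invagination sits at an inherited fraction of the
#' length from the stalked pole and deepens according to the septal
#' kinetics; the secondary invagination is nucleated at
#' `asymmetry_fraction` of the stalked compartment during the predivisional
#' phase and becomes the stalked daughter's primary invagination at
#' division, so the inheritance of the division site is exact in the ground
#' truth.  Frame-to-frame measurement-like jitter (length and width CVs) is
#' applied to the rendered shape and logged as truth, since it is what the
#' image contains.
#'
#' All randomness comes from per-cell substreams derived by stable hashing
#' of the cell id from `config$seed`, so runs are reproducible and adding
#' cells leaves existing ones untouched.
#'
#' @param config a [synth_config()] object.
#' @return an object of class `synth_movie`: a list with `config`, `truth`
#'   (one row per cell per frame of ground-truth shape parameters),
#'   `divisions` (one row per division event, with both daughter ids and
#'   which is stalked), and `cells` (per-cell anchor, orientation and the
#'   list of per-frame contours in pixel coordinates).
#' @export
simulate_lineages <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  cells <- vector("list", cfg$n_cells)
  truth_all <- list()
  div_all <- list()
  for (ci in seq_len(cfg$n_cells)) {
    sim <- simulate_one_cell(cfg, ci)
    cells[[ci]] <- sim$cell
    truth_all[[ci]] <- sim$truth
    div_all[[ci]] <- sim$divisions
  }
  truth <- if (length(truth_all)) do.call(rbind, truth_all) else
    empty_truth()
  divisions <- if (length(div_all)) do.call(rbind, div_all) else
    empty_divisions()
  structure(list(config = cfg, truth = truth, divisions = divisions,
                 cells = cells),
            class = "synth_movie")
}

simulate_one_cell <- function(cfg, cell_id) {
  set.seed(cell_seed(cfg$seed, cell_id))
  ktc <- cfg$growth_time_constant
  r_st <- cfg$pole_width_st / 2
  r_sw <- cfg$pole_width_sw / 2
  angle <- stats::runif(1, 0, 2 * pi)
  # anchor the stalked tip so the largest possible cell stays centered
  l_max <- cfg$initial_length * cfg$division_ratio * (1 + 6 * cfg$division_ratio_cv)
  anchor <- place_anchor(cfg, angle, l_max, r_st, r_sw)

  frac_primary <- cfg$asymmetry_fraction
  l0 <- cfg$initial_length
  t0 <- 0
  rows <- list(); contours <- list(); divs <- list()
  cn <- cfg$constriction; nz <- cfg$noise
  for (g in seq_len(cfg$n_generations)) {
    # sizer anchored at the lineage setpoint: divide on reaching a noisy
    # multiple of the founding size.  This keeps birth sizes stationary
    # (a pure own-birth ratio rule with a 0.54 stalked fraction would
    # shrink the lineage by 2.8% per generation); the realized growth
    # multiple per generation is 1/asymmetry_fraction ~ 1.85.
    ratio_g <- max(1.1, cfg$division_ratio *
                     (1 + stats::rnorm(1, 0, cfg$division_ratio_cv)))
    l_target <- ratio_g * cfg$initial_length
    tau_g <- ktc * log(l_target / l0)
    f_div <- ceiling((t0 + tau_g) / cfg$frame_interval)
    frames <- seq(ceiling(t0 / cfg$frame_interval), f_div - 1L)
    for (fr in frames) {
      t <- fr * cfg$frame_interval
      phi <- (t - t0) / tau_g
      eps_l <- stats::rnorm(1, 0, nz$length_cv)
      eps_w <- stats::rnorm(1, 0, nz$width_cv)
      l_tot <- l0 * exp((t - t0) / ktc) * (1 + eps_l)
      w_tube <- cfg$tube_width * (1 + eps_w)
      w_p <- min(w_tube - cn$birth_depth,
                 w_min_trajectory(t - t0, cn$w_max, cn$kappa0, cn$kappa_d))
      u_p_tip <- frac_primary * l_tot
      depth2 <- cn$birth_depth *
        ramp01((phi - cn$onset_fraction) / max(1e-9, 1 - cn$onset_fraction))
      u_s_tip <- cfg$asymmetry_fraction * u_p_tip
      dips <- data.frame(u = u_p_tip - r_st, w = w_p, extent = cn$delta)
      if (depth2 > 1e-4)
        dips <- rbind(dips, data.frame(u = u_s_tip - r_st,
                                       w = w_tube - depth2,
                                       extent = cn$delta))
      body <- l_tot - r_st - r_sw
      out <- make_cell_outline(body, cfg$centerline_radius,
                               list(tube_width = w_tube,
                                    pole_width_st = cfg$pole_width_st,
                                    pole_width_sw = cfg$pole_width_sw,
                                    bump_extent = cfg$pole_bump_extent),
                               dips = dips)
      contours[[as.character(fr)]] <- outline_to_px(out, anchor, angle, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell_id, generation = g, frame = fr, t = t, phi = phi,
        tau_true = tau_g, l_total = l_tot, body_length = body,
        R = cfg$centerline_radius, theta = l_tot / cfg$centerline_radius,
        w_tube = w_tube, w_min = w_p,
        u_primary = u_p_tip, frac_primary = frac_primary,
        u_secondary = ifelse(depth2 > 1e-4, u_s_tip, NA_real_),
        frac_secondary_of_stalked = ifelse(depth2 > 1e-4,
                                           cfg$asymmetry_fraction, NA_real_))
    }
    # division: stalked daughter keeps the anchor and the stalked pole;
    # the secondary site becomes her primary site (fraction is exact)
    l_div <- l_target
    divs[[g]] <- data.frame(
      cell_id = cell_id, generation = g, frame = f_div,
      t = f_div * cfg$frame_interval,
      l_at_division = l_div,
      daughter_stalked = as.character(cell_id),
      daughter_swarmer = sprintf("%d.sw%d", cell_id, g),  # flushed, no frames
      stalked_fraction = frac_primary,
      inherited_fraction = cfg$asymmetry_fraction)
    l0 <- frac_primary * l_div *
      exp((f_div * cfg$frame_interval - (t0 + tau_g)) / ktc)
    frac_primary <- cfg$asymmetry_fraction
    t0 <- f_div * cfg$frame_interval
  }
  truth <- if (length(rows)) do.call(rbind, rows) else empty_truth()
  divisions <- if (length(divs)) do.call(rbind, divs) else empty_divisions()
  list(cell = list(cell_id = cell_id, anchor = anchor, angle = angle,
                   contours = contours),
       truth = truth, divisions = divisions)
}

ramp01 <- function(x) {
  x <- pmin(1, pmax(0, x))
  sin(pi * x / 2)^2
}

place_anchor <- function(cfg, angle, l_max, r_st, r_sw) {
  out <- make_cell_outline(l_max - r_st - r_sw, cfg$centerline_radius,
                           list(tube_width = cfg$tube_width,
                                pole_width_st = cfg$pole_width_st,
                                pole_width_sw = cfg$pole_width_sw,
                                bump_extent = cfg$pole_bump_extent))
  rot <- rotate_xy(out, angle)
  ctr <- c(mean(range(rot[, 1])), mean(range(rot[, 2])))
  cfg$image_shape / 2 * cfg$pixel_size - ctr
}

rotate_xy <- function(xy, angle) {
  cs <- cos(angle); sn <- sin(angle)
  cbind(xy[, 1] * cs - xy[, 2] * sn, xy[, 1] * sn + xy[, 2] * cs)
}

outline_to_px <- function(out, anchor, angle, cfg) {
  rot <- rotate_xy(out, angle)
  px <- cbind(x = (rot[, 1] + anchor[1]) / cfg$pixel_size,
              y = (rot[, 2] + anchor[2]) / cfg$pixel_size)
  attributes(px)[c("l_body", "l_total", "cap_st", "cap_sw")] <-
    attributes(out)[c("l_body", "l_total", "cap_st", "cap_sw")]
  px
}

empty_truth <- function() {
  data.frame(cell_id = integer(), generation = integer(), frame = integer(),
             t = numeric(), phi = numeric(), tau_true = numeric(),
             l_total = numeric(), body_length = numeric(), R = numeric(),
             theta = numeric(), w_tube = numeric(), w_min = numeric(),
             u_primary = numeric(), frac_primary = numeric(),
             u_secondary = numeric(), frac_secondary_of_stalked = numeric())
}

empty_divisions <- function() {
  data.frame(cell_id = integer(), generation = integer(), frame = integer(),
             t = numeric(), l_at_division = numeric(),
             daughter_stalked = character(), daughter_swarmer = character(),
             stalked_fraction = numeric(), inherited_fraction = numeric())
}

#' Export a ground-truth log as JSON and contours as CSV
#'
#' @param movie a `synth_movie` from [simulate_lineages()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_ground_truth <- function(movie, dir) {
  stopifnot(inherits(movie, "synth_movie"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(truth = movie$truth, divisions = movie$divisions),
                       p1, digits = NA, auto_unbox = TRUE)
  rows <- list()
  for (cell in movie$cells) {
    for (fr in names(cell$contours)) {
      cc <- cell$contours[[fr]]
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell$cell_id, frame = as.integer(fr),
        vertex_index = seq_len(nrow(cc)), x_px = cc[, 1], y_px = cc[, 2])
    }
  }
  p2 <- file.path(dir, "contours.csv")
  utils::write.csv(do.call(rbind, rows), p2, row.names = FALSE)
  invisible(c(p1, p2))
}
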