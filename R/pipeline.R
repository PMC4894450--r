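#' Full-run configuration
#'
#' Validated container for one end-to-end run: simulate (or load images),
#' extract, quantify, ensemble, fit, report.  Unknown keys are rejected.
#'
#' @param synth a [synth_config()] (ignored when `images_dir` is given).
#' @param images_dir optional directory/TIFF of pre-acquired frames; when
#'   set, the simulate stage is skipped.
#' @param extraction list of [detect_cells()] parameters plus
#'   `smooth_budget_px`, `n_points`.
#' @param tracking list: `max_displacement_px`, `max_gap`.
#' @param divisions list: `drop_fraction`.
#' @param filtering list: `min_generations`, `despike_window`, `despike_z`.
#' @param binning list: `n_bins`, `min_frames`.
#' @param fitting list: `phi_max` for the constriction fit.
#' @param use_truth_stalk use the generator's anchor to orient axes
#'   (synthetic runs only); FALSE uses the positional-variance rule.
#' @param seed global seed.
#' @param log_level "info" or "quiet".
#' @return a `run_config`.
#' @export
run_config <- function(synth = synth_config(), images_dir = NULL,
                       extraction = list(), tracking = list(),
                       divisions = list(), filtering = list(),
                       binning = list(), fitting = list(),
                       use_truth_stalk = FALSE,
                       seed = synth$seed, log_level = "info") {
  chk <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop("unknown ", what, " keys: ",
                          paste(bad, collapse = ", "))
    x
  }
  extraction <- utils::modifyList(
    list(smooth_sigma = 1, structuring_radius = 12,
         threshold_method = "otsu", min_area = 150,
         smooth_budget_px = 0.15, n_points = 200),
    chk(extraction, c("smooth_sigma", "structuring_radius",
                      "threshold_method", "min_area", "smooth_budget_px",
                      "n_points"), "extraction"))
  tracking <- utils::modifyList(
    list(max_displacement_px = 25, max_gap = 2),
    chk(tracking, c("max_displacement_px", "max_gap"), "tracking"))
  divisions <- utils::modifyList(
    list(drop_fraction = 0.25), chk(divisions, "drop_fraction", "divisions"))
  filtering <- utils::modifyList(
    list(min_generations = 10, despike_window = 5, despike_z = 3),
    chk(filtering, c("min_generations", "despike_window", "despike_z"),
        "filtering"))
  binning <- utils::modifyList(
    list(n_bins = 50, min_frames = 5),
    chk(binning, c("n_bins", "min_frames"), "binning"))
  fitting <- utils::modifyList(
    list(phi_max = 0.9), chk(fitting, "phi_max", "fitting"))
  structure(list(synth = synth, images_dir = images_dir,
                 extraction = extraction, tracking = tracking,
                 divisions = divisions, filtering = filtering,
                 binning = binning, fitting = fitting,
                 use_truth_stalk = isTRUE(use_truth_stalk),
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[crescentshape] %s", paste0(...)))
}

#' Process a synthetic movie through rendering and contour extraction
#'
#' For each cell (field of view) renders every frame, segments it, splines
#' the boundary, tracks the (single) cell and measures all shape records.
#' This is the expensive stage; frames are rendered and discarded one at a
#' time so memory stays flat.
#'
#' @param movie a `synth_movie`.
#' @param config a `run_config`.
#' @return per-frame records (one data.frame) for all cells.
#' @export
process_movie <- function(movie, config = run_config(synth = movie$config)) {
  ex <- config$extraction
  recs <- list()
  for (cell in movie$cells) {
    fr_names <- names(cell$contours)
    per_frame <- list()
    for (key in fr_names) {
      set.seed(cell_seed(movie$config$seed + 7L,
                         cell$cell_id * 100003L + as.integer(key)))
      img <- render_frame(cell$contours[[key]], movie$config)
      cts <- extract_contours(img, ex[c("smooth_sigma", "structuring_radius",
                                        "threshold_method", "min_area")],
                              smooth_budget_px = ex$smooth_budget_px,
                              n_points = ex$n_points)
      per_frame[[key]] <- cts
    }
    tracks <- track_cells(per_frame,
                          max_displacement_px = config$tracking$max_displacement_px,
                          max_gap = config$tracking$max_gap)
    if (!length(tracks)) next
    len <- vapply(tracks, function(tr) length(tr$frames), integer(1))
    tr <- tracks[[which.max(len)]]
    stalk <- if (config$use_truth_stalk) {
      stalk_anchor_xy(movie, cell$cell_id)
    } else NULL
    rr <- track_shape_records(tr, pixel_size = movie$config$pixel_size,
                              frame_interval = movie$config$frame_interval,
                              cell_id = cell$cell_id, stalk_xy = stalk)
    recs[[length(recs) + 1L]] <- rr
    pipe_log(config, sprintf("cell %d: %d frames measured", cell$cell_id,
                             nrow(rr)))
  }
  if (!length(recs)) return(NULL)
  do.call(rbind, recs)
}

#' Ground-truth stalk anchor position of a simulated cell
#'
#' The stalked tip position, in um image coordinates, used for
#' truth-assisted axis orientation in tests and validation runs.
#'
#' @param movie a `synth_movie`.
#' @param cell_id cell index.
#' @return numeric xy, um.
#' @export
stalk_anchor_xy <- function(movie, cell_id) {
  cell <- movie$cells[[cell_id]]
  cc <- cell$contours[[1]]
  # the stalked tip is the outline point closest to the anchor by
  # construction: outline local origin is the stalked cap center
  cfg <- movie$config
  tip_local <- c(-attr(cc, "cap_st"), 0)
  rot <- rotate_xy(matrix(tip_local, 1), cell$angle)
  c(rot[1, 1] + cell$anchor[1], rot[1, 2] + cell$anchor[2])
}

#' Run the full pipeline
#'
#' simulate (or read) -> extract -> quantify -> divisions -> filter ->
#' phase-normalize -> ensemble -> fit -> report.  Writes versioned CSV and
#' JSON artifacts plus a manifest (config hash, seed, stage durations)
#' when `out_dir` is given; a re-run with the same config reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with `records` (phase-normalized), `ensembles` (list of
#'   ensemble curves), `fits` (growth and constriction), `report`,
#'   `movie` (the simulated movie, when simulated), `qc`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  durations <- c()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    durations[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"),
                                 3)
    res
  }
  movie <- NULL
  if (is.null(config$images_dir)) {
    pipe_log(config, "simulating lineages")
    movie <- tick("simulate", simulate_lineages(config$synth))
    raw <- tick("extract", process_movie(movie, config))
  } else {
    pipe_log(config, "reading frames from ", config$images_dir)
    frames <- read_movie(config$images_dir)
    ex <- config$extraction
    per_frame <- lapply(frames, function(img)
      extract_contours(img, ex[c("smooth_sigma", "structuring_radius",
                                 "threshold_method", "min_area")],
                       smooth_budget_px = ex$smooth_budget_px,
                       n_points = ex$n_points))
    names(per_frame) <- seq_along(per_frame)
    tracks <- track_cells(per_frame,
                          config$tracking$max_displacement_px,
                          config$tracking$max_gap)
    raw <- tick("extract", {
      rl <- lapply(tracks, function(tr)
        track_shape_records(tr, pixel_size = config$synth$pixel_size,
                            frame_interval = config$synth$frame_interval))
      do.call(rbind, rl)
    })
  }
  if (is.null(raw) || !nrow(raw)) stop("no cells measured")
  pipe_log(config, "annotating divisions")
  raw <- tick("divisions", {
    parts <- lapply(split(raw, raw$cell_id), function(rc) {
      # single-frame measurement glitches must go before division
      # detection, or a spurious drop splits a generation in two
      keep <- despike_series(rc$l, config$filtering$despike_window,
                             config$filtering$despike_z)
      annotate_generations(rc[keep, , drop = FALSE],
                           drop_fraction = config$divisions$drop_fraction)
    })
    do.call(rbind, parts)
  })
  filt <- tick("filter", filter_trajectories(
    raw, min_generations = config$filtering$min_generations,
    despike_window = config$filtering$despike_window,
    despike_z = config$filtering$despike_z))
  pipe_log(config, nrow(filt$qc), " QC exclusions")
  records <- tick("phase", phase_normalize_all(
    filt$records, frame_interval = config$synth$frame_interval,
    min_frames = config$binning$min_frames))
  if (is.null(records)) stop("no complete generations after filtering")
  nb <- config$binning$n_bins
  ensembles <- tick("ensemble", list(
    l = bin_ensemble(records, "l", nb),
    R = bin_ensemble(records[!records$straight, ], "R", nb),
    w_bar = bin_ensemble(records, "w_bar", nb),
    w_min = bin_ensemble(records, "w_min", nb),
    lst_frac = bin_ensemble(transform(records, lst_frac = l_st / l),
                            "lst_frac", nb)))
  fits <- tick("fit", {
    el <- ensembles$l
    okb <- el$n > 0
    gf <- fit_exponential(el$phi[okb] * mean(records$tau), el$mean[okb],
                          weights = ifelse(el$sd[okb] > 0,
                                           1 / el$sd[okb]^2, NA))
    ew <- ensembles$w_min
    okw <- ew$n > 0 & is.finite(ew$mean)
    cf <- tryCatch(
      fit_constriction(ew$phi[okw], ew$mean[okw], tau = mean(records$tau),
                       phi_max = config$fitting$phi_max,
                       active_only = TRUE),
      error = function(e) NULL)
    list(growth = gf, constriction = cf)
  })
  corr <- tryCatch(pole_asymmetry_stats(records, seed = config$seed),
                   error = function(e) NULL)
  report <- summary_report(records, fits$growth, fits$constriction, corr)
  report$inheritance <- tryCatch(inheritance_continuity(records),
                                 error = function(e) NULL)
  out <- list(records = records, ensembles = ensembles, fits = fits,
              report = report, movie = movie, qc = filt$qc,
              n_raw_records = nrow(raw), durations = durations)
  if (!is.null(out_dir)) write_run_artifacts(out, config, out_dir)
  pipe_log(config, sprintf("done in %.1f s",
                           as.numeric(Sys.time() - t_start, units = "secs")))
  out
}

write_run_artifacts <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$records, file.path(out_dir, "shape_records.csv"),
                   row.names = FALSE)
  ens <- do.call(rbind, lapply(names(out$ensembles), function(q) {
    e <- out$ensembles[[q]]
    data.frame(quantity = q, phi_bin = e$phi, mean = e$mean, sd = e$sd,
               n = e$n)
  }))
  utils::write.csv(ens, file.path(out_dir, "ensemble_curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(out$report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       na = "null")
  if (nrow(out$qc))
    utils::write.csv(out$qc, file.path(out_dir, "qc_log.csv"),
                     row.names = FALSE)
  cfg_json <- jsonlite::toJSON(unclass_recursive(config), digits = NA,
                               auto_unbox = TRUE, null = "null")
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   stage_durations_s = as.list(out$durations),
                   n_records = nrow(out$records),
                   created = "run manifest")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}

unclass_recursive <- function(x) {
  if (is.list(x)) return(lapply(x, unclass_recursive))
  x
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with top-level sections matching the arguments of
#'   [run_config()] (and `synth` matching [synth_config()]).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth
  synth <- if (is.null(synth_args)) synth_config() else
    do.call(synth_config, synth_args)
  y$synth <- NULL
  do.call(run_config, c(list(synth = synth), y))
}
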