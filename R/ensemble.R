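#' Phase-normalize the records of one generation
#'
#' Adds the cell-cycle phase `phi = t / tau`, with `t = 0` at the first
#' frame after division and `tau` the interdivision time.  Generations
#' shorter than `min_frames` frames are rejected (too short to bin).
#'
#' @param records per-frame records of one complete generation, in frame
#'   order (must contain `t`).
#' @param tau interdivision time, min; default: from the frame span plus
#'   one frame interval.
#' @param frame_interval minutes per frame.
#' @param min_frames minimum generation length.
#' @return records with columns `phi` and `tau` added, or `NULL` (with a
#'   message) when the generation is too short.
#' @export
phase_normalize <- function(records, tau = NULL, frame_interval = 1,
                            min_frames = 5) {
  if (nrow(records) < min_frames) {
    message("generation with ", nrow(records), " frames excluded (< ",
            min_frames, ")")
    return(NULL)
  }
  t0 <- records$t[1]
  if (is.null(tau)) tau <- diff(range(records$t)) + frame_interval
  records$phi <- (records$t - t0) / tau
  records$tau <- tau
  records
}

#' Phase-normalize every complete generation of a record set
#'
#' For each cell, `tau` of generation g is the time between the divisions
#' bounding it (first frame of g to first frame of g + 1).
#'
#' @param records records with `cell_id`, `generation`, `complete`, `t`.
#' @param frame_interval minutes per frame.
#' @param min_frames minimum generation length in frames.
#' @return records of complete generations with `phi`, `tau` columns.
#' @export
phase_normalize_all <- function(records, frame_interval = 1, min_frames = 5) {
  out <- list()
  for (cid in unique(records$cell_id)) {
    rc <- records[records$cell_id == cid, , drop = FALSE]
    gens <- sort(unique(rc$generation))
    for (g in gens) {
      rg <- rc[rc$generation == g, , drop = FALSE]
      if (!all(rg$complete)) next
      nxt <- rc$t[rc$generation == g + 1]
      tau <- if (length(nxt)) min(nxt) - rg$t[1] else NULL
      pn <- suppressMessages(
        phase_normalize(rg, tau = tau, frame_interval = frame_interval,
                        min_frames = min_frames))
      if (!is.null(pn)) out[[length(out) + 1L]] <- pn
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Ensemble curve: bin a quantity by cell-cycle phase
#'
#' Treats all generations as members of a single ensemble and bins the
#' chosen quantity by `phi`, reporting the unweighted per-bin mean, sd and
#' count (the +/- 1 sd band is what the study's figures display).  Empty
#' bins are reported as missing, never interpolated.
#'
#' @param records phase-normalized records.
#' @param quantity column name to bin.
#' @param n_bins number of equal-width bins partitioning `[0, 1]` (or the
#'   supplied `range`).
#' @param range phase range to partition.
#' @return an `ensemble_curve`: data.frame `phi` (bin centers), `mean`,
#'   `sd`, `n`.
#' @export
bin_ensemble <- function(records, quantity, n_bins = 50, range = c(0, 1)) {
  stopifnot(quantity %in% names(records))
  phi <- records$phi
  v <- records[[quantity]]
  ok <- is.finite(phi) & is.finite(v)
  phi <- phi[ok]; v <- v[ok]
  br <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- cut(phi, br, include.lowest = TRUE, labels = FALSE)
  ctr <- (br[-1] + br[-(n_bins + 1)]) / 2
  mn <- tapply(v, factor(bin, levels = seq_len(n_bins)), mean)
  sd_ <- tapply(v, factor(bin, levels = seq_len(n_bins)), stats::sd)
  n <- tapply(v, factor(bin, levels = seq_len(n_bins)), length)
  out <- data.frame(phi = ctr, mean = as.numeric(mn), sd = as.numeric(sd_),
                    n = as.integer(ifelse(is.na(n), 0L, n)))
  class(out) <- c("ensemble_curve", "data.frame")
  attr(out, "quantity") <- quantity
  out
}

#' Two-generation series across a division
#'
#' Maps a mother generation onto negative phases (`phi - 1`, so
#' `phi = -0.2` is 80% of the way through the mother cycle) and her
#' daughter onto `[0, 1]`, concatenating a chosen quantity from each; by
#' default the mother contributes the secondary-invagination fraction of
#' the stalked compartment (`l_st2 / l_st`) and the daughter the primary
#' fraction (`l_st / l`), which is the inheritance diagnostic.
#'
#' @param mother,daughter phase-normalized records of linked generations
#'   (same `cell_id`, consecutive `generation`).
#' @param q_mother,q_daughter expressions (as functions of the record
#'   data.frame) evaluated on each side.
#' @return data.frame `phi`, `value`, `side` ("mother"/"daughter").
#' @export
two_generation_series <- function(mother, daughter,
                                  q_mother = function(r) r$l_st2 / r$l_st,
                                  q_daughter = function(r) r$l_st / r$l) {
  if (!nrow(mother) || !nrow(daughter))
    stop("empty generation records")
  if (mother$cell_id[1] != daughter$cell_id[1] ||
      daughter$generation[1] != mother$generation[1] + 1)
    stop("generations are not linked (same cell, consecutive)")
  rbind(data.frame(phi = mother$phi - 1, value = q_mother(mother),
                   side = "mother"),
        data.frame(phi = daughter$phi, value = q_daughter(daughter),
                   side = "daughter"))
}

#' Inheritance continuity of the division site
#'
#' Compares the median secondary-invagination fraction of the stalked
#' compartment just before division with the median primary fraction just
#' after, pooled over all linked generation pairs.  Medians are used
#' because occasional misidentified minima contaminate the ratios.
#'
#' @param records phase-normalized records (with `l_st2`, `l_st`, `l`).
#' @param window phase window on either side of division.
#' @return list with `pre` (median l_st2/l_st in `[-window, 0)`), `post`
#'   (median l_st/l in `(0, window]`), `gap` (absolute difference),
#'   `n_pre`, `n_post`.
#' @export
inheritance_continuity <- function(records, window = 0.25) {
  pre_v <- c(); post_v <- c()
  for (cid in unique(records$cell_id)) {
    rc <- records[records$cell_id == cid, , drop = FALSE]
    gens <- sort(unique(rc$generation))
    for (g in gens) {
      rg <- rc[rc$generation == g, , drop = FALSE]
      if ((g + 1) %in% gens) {   # rg is a mother
        sel <- rg$phi >= 1 - window
        pre_v <- c(pre_v, (rg$l_st2 / rg$l_st)[sel])
      }
      if ((g - 1) %in% gens) {   # rg is a daughter
        sel <- rg$phi <= window
        post_v <- c(post_v, (rg$l_st / rg$l)[sel])
      }
    }
  }
  # medians: a small fraction of frames misidentify the primary minimum
  # (typically swapping it with the secondary), and those gross outliers
  # would dominate a mean of the ratio
  pre <- stats::median(pre_v, na.rm = TRUE)
  post <- stats::median(post_v, na.rm = TRUE)
  list(pre = pre, post = post, gap = abs(pre - post),
       n_pre = sum(is.finite(pre_v)), n_post = sum(is.finite(post_v)))
}

#' Pole asymmetry versus compartment asymmetry
#'
#' Pearson correlation between the pole-width ratio
#' `w_max_st / w_max_sw` and the compartment-length ratio `l_st / l_sw`
#' over records in an early-cycle phase window, with a seeded bootstrap
#' confidence interval.
#'
#' @param records phase-normalized records.
#' @param phi_window phase window (default early cycle).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return list with `r`, `ci` (length 2), `n`, `defined` (FALSE when a
#'   ratio is degenerate).
#' @export
pole_asymmetry_stats <- function(records, phi_window = c(0, 0.1),
                                 n_boot = 1000, seed = 1, conf = 0.95) {
  sel <- records$phi >= phi_window[1] & records$phi <= phi_window[2]
  x <- (records$w_max_st / records$w_max_sw)[sel]
  y <- (records$l_st / records$l_sw)[sel]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10)
    stop("need >= 10 paired observations in the phase window")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    return(list(r = NA_real_, ci = c(NA_real_, NA_real_), n = length(x),
                defined = FALSE))
  r <- stats::cor(x, y)
  set.seed(seed)
  rb <- replicate(n_boot, {
    i <- sample.int(length(x), replace = TRUE)
    if (stats::sd(x[i]) < 1e-12 || stats::sd(y[i]) < 1e-12) NA_real_
    else stats::cor(x[i], y[i])
  })
  a <- (1 - conf) / 2
  list(r = r, ci = unname(stats::quantile(rb, c(a, 1 - a), na.rm = TRUE)),
       n = length(x), defined = TRUE)
}
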