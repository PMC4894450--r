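#' Configuration for the synthetic movie generator
#'
#' Bundles every knob of the ground-truthed generator.  The defaults are the
#' study conditions the analysis is meant to operate under: crescent-shaped
#' cells of centerline radius ~4.44 um and tube width ~0.72 um imaged at
#' 0.064 um/px and 1 frame/min, growing exponentially in length with time
#' constant 125 min, dividing on reaching ~1.8x their birth length, with the
#' primary invagination at 0.54 of the length from the stalked pole, a
#' secondary invagination at the same fraction of the stalked compartment,
#' and septal constriction following the initiation-plus-autocatalysis
#' kinetics (see [septal_growth()]).
#'
#' @param n_cells number of cells (one per field of view).
#' @param n_generations complete generations simulated per cell.
#' @param frame_interval minutes between frames.
#' @param pixel_size um per pixel.
#' @param image_shape integer c(width, height) of each field, px.
#' @param growth_time_constant 1/kappa, min.
#' @param division_ratio critical multiple of birth length triggering division.
#' @param division_ratio_cv coefficient of variation of that multiple.
#' @param centerline_radius um.
#' @param tube_width cell body diameter, um.
#' @param pole_width_st,pole_width_sw pole cap diameters, um.
#' @param pole_bump_extent longitudinal extent of the pole width maxima, um.
#' @param asymmetry_fraction primary invagination position as a fraction of
#'   cell length from the stalked pole; also the fraction of the stalked
#'   compartment at which the secondary invagination is nucleated.
#' @param initial_length birth length of the founding cell, um.
#' @param constriction list: `w_max` (um), `kappa0` (um^2/min), `kappa_d`
#'   (1/min), `delta` (longitudinal extent of an invagination, um),
#'   `birth_depth` (depth of the inherited invagination at birth, um),
#'   `onset_fraction` (phase at which the secondary invagination starts to
#'   deepen).
#' @param noise list: `length_cv`, `width_cv` (frame-to-frame fractional
#'   jitter of rendered length and width), `photon_noise_sd` (additive
#'   Gaussian intensity noise), `psf_sigma_px` (Gaussian blur sd, px).
#' @param intensities list: `background`, `cell` grayscale levels in [0, 1]
#'   (cells dark on a bright background, as in phase contrast).
#' @param seed integer seed; per-cell substreams are derived from it by
#'   stable hashing of the cell id.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_cells = 1,
                         n_generations = 1,
                         frame_interval = 1,
                         pixel_size = 0.064,
                         image_shape = c(128L, 128L),
                         growth_time_constant = 125,
                         division_ratio = 1.8,
                         division_ratio_cv = 0.05,
                         centerline_radius = 4.44,
                         tube_width = 0.72,
                         pole_width_st = 0.805,
                         pole_width_sw = 0.76,
                         pole_bump_extent = 0.45,
                         asymmetry_fraction = 0.54,
                         initial_length = 2.4,
                         constriction = list(),
                         noise = list(),
                         intensities = list(),
                         seed = 1L) {
  constriction <- utils::modifyList(
    list(w_max = 0.805, kappa0 = 0.016, kappa_d = 1 / 125,
         delta = 0.3, birth_depth = 0.05, onset_fraction = 0.6),
    constriction)
  noise <- utils::modifyList(
    list(length_cv = 0.02, width_cv = 0.02,
         photon_noise_sd = 0.02, psf_sigma_px = 1),
    noise)
  intensities <- utils::modifyList(list(background = 0.85, cell = 0.35),
                                   intensities)
  cfg <- list(n_cells = as.integer(n_cells),
              n_generations = as.integer(n_generations),
              frame_interval = frame_interval, pixel_size = pixel_size,
              image_shape = as.integer(image_shape),
              growth_time_constant = growth_time_constant,
              division_ratio = division_ratio,
              division_ratio_cv = division_ratio_cv,
              centerline_radius = centerline_radius,
              tube_width = tube_width,
              pole_width_st = pole_width_st, pole_width_sw = pole_width_sw,
              pole_bump_extent = pole_bump_extent,
              asymmetry_fraction = asymmetry_fraction,
              initial_length = initial_length,
              constriction = constriction, noise = noise,
              intensities = intensities, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_cells >= 0, n_generations >= 0,
              frame_interval > 0, pixel_size > 0,
              length(image_shape) == 2, all(image_shape > 0),
              growth_time_constant > 0,
              division_ratio > 1, division_ratio_cv >= 0,
              centerline_radius > 0, tube_width > 0,
              pole_width_st > 0, pole_width_sw > 0, pole_bump_extent > 0,
              asymmetry_fraction > 0, asymmetry_fraction < 1,
              initial_length > 0,
              constriction$w_max > 0, constriction$kappa0 >= 0,
              constriction$kappa_d >= 0, constriction$delta > 0,
              constriction$birth_depth >= 0,
              noise$length_cv >= 0, noise$width_cv >= 0,
              noise$photon_noise_sd >= 0, noise$psf_sigma_px >= 0)
  })
  invisible(cfg)
}

# deterministic per-cell seed derived from the global one by stable hashing,
# so adding cells does not perturb existing ones
cell_seed <- function(seed, cell_id) {
  as.integer((as.double(seed) * 1000003 + as.double(cell_id) * 7919 + 17) %%
               2147483647)
}
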