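#' Render a phase-contrast-like frame from cell contours
#'
#' Rasterizes each contour (dark interior on a bright background plateau),
#' applies a Gaussian point-spread blur and additive Gaussian intensity
#' noise, and clips to [0, 1].  Conventions, fixed across the package:
#' images are indexed `[x, y]` with the origin at the top-left, pixel
#' centers at integer coordinates starting at 1, intensities in [0, 1],
#' cells dark on bright (so segmentation thresholds the *bottom-hat* of the
#' image).
#'
#' @param contours a single contour (two-column matrix, px) or list of them.
#' @param config a [synth_config()] object (supplies image shape, PSF,
#'   noise and intensity levels).
#' @param noise logical; set `FALSE` for a noise-free render (blur kept).
#' @param blur logical; set `FALSE` to skip the PSF blur.
#' @return an [EBImage::Image] in grayscale.
#' @export
render_frame <- function(contours, config, noise = TRUE, blur = TRUE) {
  cfg <- config
  if (is.matrix(contours)) contours <- list(contours)
  W <- cfg$image_shape[1]; H <- cfg$image_shape[2]
  img <- matrix(cfg$intensities$background, W, H)
  for (cc in contours) {
    if (is.null(cc)) next
    if (any(cc[, 1] < 1 | cc[, 1] > W | cc[, 2] < 1 | cc[, 2] > H))
      warning("contour leaves the frame; rendering clipped")
    img <- fill_polygon(img, cc, cfg$intensities$cell)
  }
  if (blur && cfg$noise$psf_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = cfg$noise$psf_sigma_px))
  if (noise && cfg$noise$photon_noise_sd > 0)
    img <- img + matrix(stats::rnorm(W * H, 0, cfg$noise$photon_noise_sd),
                        W, H)
  EBImage::Image(pmin(pmax(img, 0), 1))  # arg order keeps the dim attribute
}

# even-odd scanline fill of a closed polygon onto matrix `img` (indexed
# [x, y], pixel centers at integers); returns the modified matrix
fill_polygon <- function(img, poly, value) {
  W <- nrow(img); H <- ncol(img)
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  y0 <- pmax(1L, ceiling(min(y))); y1 <- pmin(H, floor(max(y)))
  if (y0 > y1) return(img)
  for (yy in y0:y1) {
    up <- (y <= yy & y[j] > yy) | (y[j] <= yy & y > yy)
    if (!any(up)) next
    xi <- x[up] + (yy - y[up]) * (x[j][up] - x[up]) / (y[j][up] - y[up])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      a <- ceiling(xi[k] - 1e-9); b <- floor(xi[k + 1] + 1e-9)
      a <- max(1L, a); b <- min(W, b)
      if (a <= b) img[a:b, yy] <- value
    }
  }
  img
}

#' Render all frames of a simulated movie
#'
#' One field of view per cell.  Frame noise is drawn from a stream seeded
#' per cell and frame, so any frame can be rendered independently and
#' reproducibly.
#'
#' @param movie a `synth_movie` from [simulate_lineages()].
#' @param cell_id which cell (field of view) to render.
#' @param frames integer frame indices (default: all frames of that cell).
#' @param noise,blur see [render_frame()].
#' @return named list of [EBImage::Image] frames.
#' @export
render_movie <- function(movie, cell_id = 1, frames = NULL,
                         noise = TRUE, blur = TRUE) {
  cell <- movie$cells[[cell_id]]
  all_fr <- as.integer(names(cell$contours))
  if (is.null(frames)) frames <- all_fr
  out <- list()
  for (fr in frames) {
    key <- as.character(fr)
    if (!key %in% names(cell$contours)) next
    set.seed(cell_seed(movie$config$seed + 7L, cell$cell_id * 100003L + fr))
    out[[key]] <- render_frame(cell$contours[[key]], movie$config,
                               noise = noise, blur = blur)
  }
  out
}

#' Write rendered frames to disk
#'
#' @param frames named list of images (from [render_movie()]).
#' @param dir output directory.
#' @param format `"tiff"` (one multi-page stack) or `"png"` (one file per
#'   frame).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_frames <- function(frames, dir, format = c("tiff", "png"),
                         prefix = "field") {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required for TIFF output")
    path <- file.path(dir, paste0(prefix, ".tif"))
    tiff::writeTIFF(lapply(frames, function(im) t(as.matrix(im))), path)
    return(invisible(path))
  }
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG output")
  paths <- character(0)
  for (key in names(frames)) {
    p <- file.path(dir, sprintf("%s_%05d.png", prefix, as.integer(key)))
    png::writePNG(t(as.matrix(frames[[key]])), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a movie from disk
#'
#' Accepts a multi-page TIFF stack or a directory of PNG/TIFF frames
#' (sorted by name).  Images are returned in the package's `[x, y]`
#' convention.
#'
#' @param path TIFF file or directory.
#' @return list of image matrices.
#' @export
read_movie <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", path)
    return(lapply(files, read_frame_file))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) t(gray_matrix(m)))
}

read_frame_file <- function(f) {
  m <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
       else tiff::readTIFF(f)
  t(gray_matrix(m))
}

gray_matrix <- function(m) {
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}
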