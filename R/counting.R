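#' Configuration of the five-step particle-counting chain
#'
#' All free parameters of the DAB-counting algorithm: color deconvolution ->
#' minimum filter -> robust automatic threshold selection (RATS) ->
#' watershed -> particle count.
#'
#' @param vectors A [stain_vectors()] object.
#' @param min_filter_radius Radius (pixels) of the grayscale minimum filter
#'   applied to the DAB signal image; 0 disables it.
#' @param rats_lambda Noise floor of the RATS gradient weighting, in the
#'   units of the DAB signal image (0-255). See [estimate_rats_lambda()] for
#'   a principled value tied to the rendering noise.
#' @param rats_power Exponent of the gradient weighting (default 2, the
#'   classical statistic).
#' @param min_area,max_area Particle area bounds in px^2; particles outside
#'   are discarded.
#' @param watershed_tolerance Minimum distance-transform depth (pixels)
#'   separating two seeds; shallower maxima are merged to avoid
#'   over-segmentation.
#' @param fill_holes Fill holes in the binarized mask before watershed
#'   (ring-like staining artifacts).
#' @return A list of class `counting_config`.
#' @export
counting_config <- function(vectors = stain_vectors(),
                            min_filter_radius = 1L,
                            rats_lambda = 15,
                            rats_power = 2,
                            min_area = 30,
                            max_area = 5000,
                            watershed_tolerance = 1,
                            fill_holes = TRUE) {
  stopifnot(inherits(vectors, "stain_vectors"), min_filter_radius >= 0,
            rats_lambda >= 0, min_area < max_area, watershed_tolerance >= 0)
  structure(list(vectors = vectors,
                 min_filter_radius = as.integer(min_filter_radius),
                 rats_lambda = rats_lambda, rats_power = rats_power,
                 min_area = min_area, max_area = max_area,
                 watershed_tolerance = watershed_tolerance,
                 fill_holes = isTRUE(fill_holes)),
            class = "counting_config")
}

#' Color deconvolution of an RGB raster into stain concentrations
#'
#' Converts each channel to optical density against its background intensity
#' (`-log10(max(I, 1)/I0)`) and solves the 3x3 stain-vector system, giving
#' per-pixel concentrations of hematoxylin, DAB and the residual channel.
#' Concentrations are returned unclipped (small negatives arise from noise).
#'
#' @param rgb A height x width x 3 array of 8-bit intensities (0-255).
#' @param vectors A [stain_vectors()] object.
#' @param bg_intensity Per-channel background intensity I0 (default 255).
#' @return A list of three height x width matrices: `hematoxylin`, `dab`,
#'   `residual`.
#' @export
color_deconvolve <- function(rgb, vectors = stain_vectors(), bg_intensity = c(255, 255, 255)) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("invalid parameter: rgb must be a height x width x 3 array", call. = FALSE)
  }
  if (length(bg_intensity) == 1L) bg_intensity <- rep(bg_intensity, 3)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  od <- vapply(1:3, function(c) as.numeric(intensity_to_od(rgb[, , c], bg_intensity[c])),
               numeric(h * w))
  conc <- od %*% solve(vectors$matrix)  # od = conc %*% M
  list(hematoxylin = matrix(conc[, 1], h, w),
       dab = matrix(conc[, 2], h, w),
       residual = matrix(conc[, 3], h, w))
}

#' Grayscale minimum filter (erosion over a disc)
#'
#' Each pixel is replaced by the minimum over a disc of the given radius
#' (radius 0 is the identity). Smooths background speckle before
#' thresholding.
#'
#' @param raster A numeric matrix.
#' @param radius Disc radius in pixels (>= 0).
#' @return A matrix of the same size.
#' @export
minimum_filter <- function(raster, radius) {
  if (radius < 0) stop("invalid parameter: radius must be >= 0", call. = FALSE)
  if (radius == 0) return(raster)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  lo <- min(raster); hi <- max(raster)
  if (hi == lo) return(raster)
  # EBImage grayscale morphology expects [0,1]; erosion commutes with the
  # positive affine rescale. EBImage works in (x, y); transpose in and out.
  scaled <- (raster - lo) / (hi - lo)
  t(EBImage::erode(t(scaled), brush)) * (hi - lo) + lo
}

min_filter_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

sobel_magnitude <- function(raster) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- t(EBImage::filter2(t(raster), kx, boundary = "replicate"))
  gy <- t(EBImage::filter2(t(raster), t(kx), boundary = "replicate"))
  sqrt(gx^2 + gy^2)
}

#' Robust automatic threshold selection (RATS)
#'
#' The gradient-weighted mean intensity: `t = sum(w * I) / sum(w)` with
#' `w = max(|grad I|^power - lambda^power, 0)` and `|grad I|` the Sobel
#' gradient magnitude. Pixels near edges dominate, so `t` lands between
#' background and signal levels; `lambda` suppresses gradient noise in flat
#' regions. Binarization keeps pixels with value > t.
#'
#' @param raster A numeric matrix (signal bright).
#' @param config A [counting_config()] (uses `rats_lambda`, `rats_power`).
#' @return The threshold value.
#' @export
rats_threshold <- function(raster, config = counting_config()) {
  g <- sobel_magnitude(raster)
  w <- pmax(g^config$rats_power - config$rats_lambda^config$rats_power, 0)
  sw <- sum(w)
  if (sw == 0) {
    stop(no_signal_error("RATS: no gradient weight above the noise floor (flat image)"))
  }
  sum(w * raster) / sw
}

no_signal_error <- function(msg) {
  structure(class = c("no_signal_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Estimate the RATS noise floor from the rendering noise
#'
#' Renders a blank (nucleus-free) field under the given noise model, builds
#' the DAB signal image the counting chain sees, and returns 3x the standard
#' deviation of its Sobel gradient magnitude — a floor below which gradients
#' are indistinguishable from read noise.
#'
#' @param rconfig A [render_config()] (only noise and background are used).
#' @param vectors A [stain_vectors()] object.
#' @param seed Seed for the probe render.
#' @return A scalar lambda.
#' @export
estimate_rats_lambda <- function(rconfig = render_config(), vectors = stain_vectors(),
                                 seed = 1L) {
  probe <- rconfig
  probe$width <- 128L; probe$height <- 128L
  set.seed(seed)
  blank <- render_field(empty_nuclei(), "MIB1", vectors, probe)
  conc <- color_deconvolve(blank$rgb, vectors, probe$bg_intensity)
  s <- dab_signal_image(conc$dab)
  3 * stats::sd(sobel_magnitude(s))
}

empty_nuclei <- function() {
  data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0), b = numeric(0),
             theta = numeric(0), mib1_pos = logical(0), phh3_pos = logical(0),
             mitotically_visible = logical(0), dna_content = numeric(0))
}

# Signal-bright 8-bit DAB image: 0 where no stain, -> 255 as OD grows.
dab_signal_image <- function(dab_conc) {
  255 * (1 - 10^(-pmax(dab_conc, 0)))
}

#' Split touching particles with a distance-transform watershed
#'
#' Labels the foreground of a binary mask by flooding the negated Euclidean
#' distance transform from its regional maxima; maxima shallower than
#' `watershed_tolerance` are merged. Components that do not touch keep a
#' single label each.
#'
#' @param mask A logical/0-1 matrix.
#' @param config A [counting_config()].
#' @return An integer label matrix (0 = background).
#' @export
watershed_split <- function(mask, config = counting_config()) {
  m <- (mask > 0) * 1
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(t(m))
  lab <- EBImage::watershed(d, tolerance = config$watershed_tolerance, ext = 1L)
  matrix(as.integer(t(lab)), nrow(mask), ncol(mask))
}

#' Filter labelled particles by area and tabulate them
#'
#' @param labels An integer label matrix.
#' @param min_area,max_area Inclusive area bounds in px^2.
#' @return A list of class `particle_set`: `count`, `records` (data.frame
#'   with `label`, `area`, `cx`, `cy`) and `labels` (raster with
#'   out-of-bounds particles zeroed).
#' @export
count_particles <- function(labels, min_area = 0, max_area = Inf) {
  labs <- as.integer(labels)
  nmax <- max(labs, 0L)
  if (nmax == 0L) {
    return(structure(list(count = 0L,
                          records = data.frame(label = integer(0), area = numeric(0),
                                               cx = numeric(0), cy = numeric(0)),
                          labels = labels * 0L),
                     class = "particle_set"))
  }
  areas <- tabulate(labs, nbins = nmax)
  keep <- which(areas >= min_area & areas <= max_area)
  idx <- which(labels %in% keep)
  rc <- arrayInd(idx, dim(labels))
  lab_at <- factor(labels[idx], levels = keep)
  cx <- tapply(rc[, 2], lab_at, mean)
  cy <- tapply(rc[, 1], lab_at, mean)
  out <- labels
  out[!(labels %in% keep)] <- 0L
  structure(list(count = length(keep),
                 records = data.frame(label = keep, area = areas[keep],
                                      cx = as.numeric(cx), cy = as.numeric(cy)),
                 labels = out),
            class = "particle_set")
}

#' Count stained particles in one field (full five-step chain)
#'
#' Runs color deconvolution, extracts the DAB signal image, applies the
#' minimum filter, thresholds with RATS, optionally fills holes, splits
#' touching nuclei by watershed, and counts particles within the area
#' bounds. A field with no detectable signal (flat DAB image) counts 0.
#'
#' @param rgb A height x width x 3 array (0-255).
#' @param config A [counting_config()].
#' @param bg_intensity Per-channel background intensity.
#' @param details If `TRUE`, return the full [count_particles()] result
#'   instead of the bare count.
#' @return Integer count (or a `particle_set` when `details = TRUE`).
#' @export
count_field <- function(rgb, config = counting_config(),
                        bg_intensity = c(245, 245, 245), details = FALSE) {
  conc <- color_deconvolve(rgb, config$vectors, bg_intensity)
  s <- dab_signal_image(conc$dab)
  s <- minimum_filter(s, config$min_filter_radius)
  t_val <- tryCatch(rats_threshold(s, config), no_signal_error = function(e) NULL)
  if (is.null(t_val)) {
    message("count_field: no DAB signal detected; recording count 0")
    ps <- count_particles(matrix(0L, nrow(s), ncol(s)))
    return(if (details) ps else 0L)
  }
  binary <- s > t_val
  if (config$fill_holes) {
    binary <- t(EBImage::fillHull(t(binary * 1))) > 0
  }
  labels <- watershed_split(binary, config)
  ps <- count_particles(labels, config$min_area, config$max_area)
  if (details) ps else ps$count
}

#' Average per-field counts
#'
#' @param counts Numeric vector of per-field counts (length >= 1).
#' @return The arithmetic mean.
#' @export
average_counts <- function(counts) {
  if (length(counts) == 0L) stop("invalid parameter: no fields to average", call. = FALSE)
  mean(counts)
}
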