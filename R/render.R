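#' Rendering configuration for synthetic microscope fields
#'
#' Geometry and stain-physics parameters of the forward model that turns
#' nucleus records into an RGB field. Defaults match a 10x objective on a
#' 2560x1920 colour camera; tests and the bundled analyses render smaller
#' crops by overriding `width`/`height` (the physics is per-pixel, so field
#' size only scales how many nuclei fit).
#'
#' @param width,height Field size in pixels.
#' @param hpf_width,hpf_height High-power (40x) crop size; defaults to a
#'   quarter of the field in each dimension (16x smaller area).
#' @param bg_intensity Background (unstained) intensity per channel, 8-bit.
#' @param radius_range Min/max nucleus semi-major axis, pixels.
#' @param eccentricity_range Min/max ratio of major to minor axis (>= 1).
#' @param hematoxylin_amp Hematoxylin optical density contributed by a fully
#'   covered pixel per unit relative DNA content.
#' @param dab_amp DAB optical density at full coverage for a marker-positive
#'   nucleus.
#' @param noise_sd Gaussian read-noise sd in 8-bit intensity units.
#' @param min_spacing Minimum centre-to-centre distance between placed
#'   nuclei, pixels; `NULL` means 2.2x the maximum radius (non-touching).
#' @param max_place_tries Rejection-sampling attempts per nucleus before
#'   [place_nuclei()] declares the packing infeasible.
#' @return A list of class `render_config`.
#' @export
render_config <- function(width = 2560L, height = 1920L,
                          hpf_width = NULL, hpf_height = NULL,
                          bg_intensity = c(245, 245, 245),
                          radius_range = c(10, 16),
                          eccentricity_range = c(1, 1.6),
                          hematoxylin_amp = 0.25,
                          dab_amp = 0.8,
                          noise_sd = 2,
                          min_spacing = NULL,
                          max_place_tries = 200L) {
  if (is.null(hpf_width)) hpf_width <- as.integer(round(width / 4))
  if (is.null(hpf_height)) hpf_height <- as.integer(round(height / 4))
  if (length(bg_intensity) == 1L) bg_intensity <- rep(bg_intensity, 3)
  cfg <- list(width = as.integer(width), height = as.integer(height),
              hpf_width = hpf_width, hpf_height = hpf_height,
              bg_intensity = bg_intensity,
              radius_range = radius_range,
              eccentricity_range = eccentricity_range,
              hematoxylin_amp = hematoxylin_amp, dab_amp = dab_amp,
              noise_sd = noise_sd,
              min_spacing = if (is.null(min_spacing)) 2.2 * max(radius_range) else min_spacing,
              max_place_tries = as.integer(max_place_tries))
  stopifnot(cfg$width > 0, cfg$height > 0, cfg$hematoxylin_amp >= 0,
            cfg$dab_amp >= 0, cfg$noise_sd >= 0,
            all(cfg$radius_range > 0), diff(cfg$radius_range) >= 0,
            all(cfg$eccentricity_range >= 1))
  class(cfg) <- "render_config"
  cfg
}

#' Place nucleus ellipses in a field
#'
#' Rejection-samples `n` ellipse geometries fully inside the frame with all
#' pairwise centre distances at least `config$min_spacing`. Set a small
#' `min_spacing` (or 0) to allow touching/overlapping nuclei.
#'
#' @param n Number of nuclei (>= 0).
#' @param config A [render_config()].
#' @return A data.frame with columns `cx`, `cy` (pixel centres), `a`, `b`
#'   (semi-axes), `theta` (orientation, radians).
#' @export
place_nuclei <- function(n, config) {
  if (n < 0) stop("invalid parameter: n must be >= 0", call. = FALSE)
  geom <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                     b = numeric(0), theta = numeric(0))
  if (n == 0L) return(geom)
  rmax <- max(config$radius_range)
  cx <- numeric(n); cy <- numeric(n)
  a <- stats::runif(n, config$radius_range[1], config$radius_range[2])
  ecc <- stats::runif(n, config$eccentricity_range[1], config$eccentricity_range[2])
  b <- a / ecc
  theta <- stats::runif(n, 0, pi)
  sp2 <- config$min_spacing^2
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(config$max_place_tries)) {
      x <- stats::runif(1, rmax + 1, config$width - rmax - 1)
      y <- stats::runif(1, rmax + 1, config$height - rmax - 1)
      if (k == 1L || all((cx[seq_len(k - 1)] - x)^2 + (cy[seq_len(k - 1)] - y)^2 >= sp2)) {
        cx[k] <- x; cy[k] <- y; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop("infeasible packing: could not place nucleus ", k, " of ", n,
           " at spacing ", config$min_spacing, call. = FALSE)
    }
  }
  data.frame(cx = cx, cy = cy, a = a, b = b, theta = theta)
}

# Fractional pixel coverage of one ellipse over the pixel grid, by 4x4
# subsampling inside the bounding box. Returns list(rows, cols, cov matrix).
ellipse_coverage <- function(cx, cy, a, b, theta, width, height, sub = 4L) {
  rmax <- max(a, b)
  x0 <- max(1L, floor(cx - rmax)); x1 <- min(width, ceiling(cx + rmax))
  y0 <- max(1L, floor(cy - rmax)); y1 <- min(height, ceiling(cy + rmax))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  off <- (seq_len(sub) - 0.5) / sub - 0.5
  cov <- matrix(0, nrow = length(ys), ncol = length(xs))
  ct <- cos(theta); st <- sin(theta)
  for (oy in off) {
    dy <- ys + oy - cy
    for (ox in off) {
      dx <- xs + ox - cx
      # rotated ellipse membership over the (row = y, col = x) grid
      u <- outer(dy * st, dx * ct, "+")
      v <- outer(dy * ct, -dx * st, "+")
      cov <- cov + ((u / a)^2 + (v / b)^2 <= 1)
    }
  }
  list(rows = ys, cols = xs, cov = cov / sub^2)
}

#' Render a synthetic stained field
#'
#' Forward model: every nucleus deposits hematoxylin optical density
#' proportional to its relative DNA content times its pixel coverage;
#' marker-positive nuclei additionally deposit DAB (for the stain mode's
#' marker; none in H&E mode). Channel intensities follow Beer-Lambert decay
#' of the background along the stain vectors, with clipped Gaussian read
#' noise. Nucleus edges are anti-aliased by area coverage.
#'
#' @param nuclei A data.frame with the geometry columns of [place_nuclei()]
#'   plus `mib1_pos`, `phh3_pos`, `mitotically_visible` (logical) and
#'   `dna_content` (numeric) — e.g. geometry cbind'ed with
#'   [sample_cell_snapshot()] rows.
#' @param stain_mode `"MIB1"`, `"PHH3"` or `"HE"`.
#' @param vectors A [stain_vectors()] object.
#' @param config A [render_config()].
#' @return A list of class `synthetic_field`: `rgb` (height x width x 3
#'   array, 0-255), `mask` (height x width integer label raster, 0 =
#'   background, labels follow row order of `nuclei`), `nuclei` (the input
#'   records with a `label` column), `stain_mode`, `config`.
#' @export
render_field <- function(nuclei, stain_mode = c("MIB1", "PHH3", "HE"),
                         vectors = stain_vectors(), config = render_config()) {
  stain_mode <- match.arg(stain_mode)
  w <- config$width; h <- config$height
  od_h <- matrix(0, nrow = h, ncol = w)
  od_d <- matrix(0, nrow = h, ncol = w)
  mask <- matrix(0L, nrow = h, ncol = w)
  n <- nrow(nuclei)
  positive <- marker_status(nuclei, stain_mode)
  if (n > 0) {
    for (k in seq_len(n)) {
      cvg <- ellipse_coverage(nuclei$cx[k], nuclei$cy[k], nuclei$a[k],
                              nuclei$b[k], nuclei$theta[k], w, h)
      if (is.null(cvg)) next
      od_h[cvg$rows, cvg$cols] <- od_h[cvg$rows, cvg$cols] +
        config$hematoxylin_amp * nuclei$dna_content[k] * cvg$cov
      if (positive[k]) {
        od_d[cvg$rows, cvg$cols] <- od_d[cvg$rows, cvg$cols] + config$dab_amp * cvg$cov
      }
      blk <- mask[cvg$rows, cvg$cols]
      take <- cvg$cov >= 0.5 & blk == 0L
      blk[take] <- k
      mask[cvg$rows, cvg$cols] <- blk
    }
  }
  rgb <- array(0, dim = c(h, w, 3))
  for (c in 1:3) {
    od_c <- od_h * vectors$hematoxylin[c] + od_d * vectors$dab[c]
    plane <- od_to_intensity(od_c, config$bg_intensity[c])
    if (config$noise_sd > 0) {
      plane <- plane + stats::rnorm(length(plane), 0, config$noise_sd)
    }
    rgb[, , c] <- pmin(pmax(round(plane), 0), 255)
  }
  recs <- nuclei
  recs$label <- if (n > 0) seq_len(n) else integer(0)
  structure(list(rgb = rgb, mask = mask, nuclei = recs,
                 stain_mode = stain_mode, config = config),
            class = "synthetic_field")
}

marker_status <- function(nuclei, stain_mode) {
  if (nrow(nuclei) == 0L) return(logical(0))
  switch(stain_mode,
         MIB1 = nuclei$mib1_pos,
         PHH3 = nuclei$phh3_pos,
         HE = rep(FALSE, nrow(nuclei)))
}

#' Ground-truth positive-nucleus count of a synthetic field
#'
#' Counts the nucleus records positive for the given stain readout: DAB
#' positives for MIB1/PHH3 fields, recognisable mitotic figures for HE.
#'
#' @param field A [render_field()] result.
#' @param stain_mode Readout; defaults to the field's own stain mode.
#' @return Integer count.
#' @export
ground_truth_counts <- function(field, stain_mode = field$stain_mode) {
  nuc <- field$nuclei
  if (nrow(nuc) == 0L) return(0L)
  if (stain_mode == "HE") return(sum(nuc$mitotically_visible))
  sum(marker_status(nuc, stain_mode))
}

#' Simulate and render one field of a tumor
#'
#' Draws the number of visible tumor nuclei (Poisson, scaled from
#' `nuclei_per_field` by the rendered-to-full field-area ratio), samples
#' their cell states, places them, and renders the requested stain.
#'
#' @param spec A [sample_tumor_spec()] result.
#' @param config A [cohort_config()].
#' @param rconfig A [render_config()].
#' @param stain_mode `"MIB1"`, `"PHH3"` or `"HE"`.
#' @param vectors A [stain_vectors()] object.
#' @return A [render_field()] result.
#' @export
simulate_field <- function(spec, config, rconfig = render_config(),
                           stain_mode = "MIB1", vectors = stain_vectors()) {
  area_scale <- (rconfig$width * rconfig$height) / (2560 * 1920)
  n <- stats::rpois(1L, spec$nuclei_per_field * area_scale)
  geom <- place_nuclei(n, rconfig)
  snap <- sample_cell_snapshot(spec, config, n = n)
  render_field(cbind(geom, snap), stain_mode, vectors, rconfig)
}

#' Write a synthetic field to disk (TIFF raster + JSON nucleus records)
#'
#' @param field A [render_field()] result.
#' @param path Base path without extension; writes `<path>.tif`,
#'   `<path>_mask.tif` (16-bit labels) and `<path>.json`.
#' @return Invisibly, the three paths.
#' @export
write_field <- function(field, path) {
  tiff::writeTIFF(field$rgb / 255, paste0(path, ".tif"))
  tiff::writeTIFF(field$mask / 65535, paste0(path, "_mask.tif"), bits.per.sample = 16L)
  side <- list(stain_mode = field$stain_mode,
               width = field$config$width, height = field$config$height,
               nuclei = field$nuclei)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, c(".tif", "_mask.tif", ".json")))
}

#' Read a synthetic field written by [write_field()]
#'
#' @param path Base path used in [write_field()].
#' @return A list with `rgb` (0-255 array), `mask` (integer labels),
#'   `nuclei` (data.frame), `stain_mode`.
#' @export
read_field <- function(path) {
  rgb <- tiff::readTIFF(paste0(path, ".tif")) * 255
  mask <- round(tiff::readTIFF(paste0(path, "_mask.tif")) * 65535)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(rgb = rgb, mask = mask, nuclei = as.data.frame(side$nuclei),
                 stain_mode = side$stain_mode),
            class = "synthetic_field")
}
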