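#' Nuclear area and integrated optical density of one nucleus
#'
#' Sums the deconvolved hematoxylin optical density (floored at 0) over the
#' pixels of a delineated nucleus. The hematoxylin IOD of a nucleus is a
#' (rough) proxy for its DNA content.
#'
#' @param rgb A height x width x 3 array (0-255).
#' @param mask A logical/0-1 matrix of the same height/width marking the
#'   nucleus pixels.
#' @param vectors A [stain_vectors()] object.
#' @param bg_intensity Per-channel background intensity.
#' @return A list of class `nucleus_measurement`: `area` (px^2) and `iod`
#'   (summed OD, arbitrary units).
#' @export
nucleus_iod <- function(rgb, mask, vectors = stain_vectors(),
                        bg_intensity = c(245, 245, 245)) {
  m <- mask > 0
  if (!any(m)) stop("invalid parameter: empty nucleus mask", call. = FALSE)
  if (!all(dim(m) == dim(rgb)[1:2])) {
    stop("invalid parameter: mask does not match raster dimensions", call. = FALSE)
  }
  conc <- color_deconvolve(rgb, vectors, bg_intensity)
  hem <- pmax(conc$hematoxylin, 0)
  structure(list(area = sum(m), iod = sum(hem[m])), class = "nucleus_measurement")
}

#' Per-tumor nuclear IOD summary over delineated nuclei
#'
#' Measures each delineated nucleus with [nucleus_iod()] and summarises; the
#' conventional per-tumor value is the mean over 15 nuclei.
#'
#' @param rgb A height x width x 3 array, or a list of such arrays (one per
#'   mask) when nuclei come from several fields.
#' @param masks A list of binary nucleus masks.
#' @param vectors A [stain_vectors()] object.
#' @param bg_intensity Per-channel background intensity.
#' @param expected_n Expected number of delineated nuclei (warn if
#'   different).
#' @param summary `"mean"` (default) or `"median"`.
#' @return The summary IOD (scalar), with the per-nucleus data.frame
#'   attached as attribute `"nuclei"`.
#' @export
tumor_iod <- function(rgb, masks, vectors = stain_vectors(),
                      bg_intensity = c(245, 245, 245),
                      expected_n = 15L, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (length(masks) == 0L) stop("invalid parameter: no nucleus masks", call. = FALSE)
  if (length(masks) != expected_n) {
    warning("expected ", expected_n, " nucleus masks, got ", length(masks),
            "; proceeding", call. = FALSE)
  }
  rasters <- if (is.list(rgb) && !is.array(rgb)) rgb else rep(list(rgb), length(masks))
  per <- lapply(seq_along(masks), function(i) {
    nucleus_iod(rasters[[i]], masks[[i]], vectors, bg_intensity)
  })
  vals <- vapply(per, `[[`, numeric(1), "iod")
  out <- if (summary == "mean") mean(vals) else stats::median(vals)
  attr(out, "nuclei") <- data.frame(nucleus_id = seq_along(vals),
                                    area_px2 = vapply(per, `[[`, numeric(1), "area"),
                                    iod = vals)
  out
}

#' Randomly select ground-truth nucleus masks from a synthetic field
#'
#' Surrogate for manual delineation: draws `n` distinct nuclei uniformly at
#' random from the field's label mask and returns their binary masks.
#'
#' @param field A [render_field()] result.
#' @param n Number of nuclei to select.
#' @return A list of `n` binary masks; the chosen labels are attached as
#'   attribute `"labels"`.
#' @export
sample_nuclei_masks <- function(field, n) {
  labs <- field$nuclei$label
  labs <- labs[labs %in% unique(as.integer(field$mask))]
  if (length(labs) < n) {
    stop("invalid parameter: field has ", length(labs),
         " delineable nuclei, need ", n, call. = FALSE)
  }
  chosen <- sample(labs, n)
  masks <- lapply(chosen, function(l) field$mask == l)
  attr(masks, "labels") <- chosen
  masks
}
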