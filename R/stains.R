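#' Stain optical-density direction vectors
#'
#' The three unit vectors over (R,G,B) optical density along which
#' hematoxylin, DAB and a residual channel absorb. Defaults are the standard
#' H-DAB pair (Ruifrok-style), with the residual taken as their normalized
#' cross product so the 3x3 matrix is always invertible.
#'
#' @param hematoxylin,dab Non-negative length-3 numeric vectors (any scale;
#'   normalized internally). Defaults are the standard H-DAB pair.
#' @param residual Optional third vector. The default, used with the default
#'   stain pair, is the standard published H-DAB complement; for a custom
#'   stain pair the cross product of the two stain vectors is used instead.
#'   Unlike the stains it may have negative components (it is a mathematical
#'   complement, not a physical stain) — what matters is that it points well
#'   out of the stain plane so the matrix stays well conditioned.
#' @return A list of class `stain_vectors` with unit-norm `hematoxylin`,
#'   `dab`, `residual` and the stacked 3x3 `matrix` (rows = stains).
#' @export
stain_vectors <- function(hematoxylin = c(0.650, 0.704, 0.286),
                          dab = c(0.268, 0.570, 0.776),
                          residual = NULL) {
  unitize <- function(v, nm, allow_negative = FALSE) {
    if (length(v) != 3L || any(!is.finite(v)) || (!allow_negative && any(v < 0)) ||
        sum(v^2) < 1e-12) {
      stop("configuration error: ", nm, " vector must be non-negative, nonzero, length 3",
           call. = FALSE)
    }
    v / sqrt(sum(v^2))
  }
  h <- unitize(hematoxylin, "hematoxylin")
  d <- unitize(dab, "dab")
  if (is.null(residual)) {
    default_pair <- identical(hematoxylin, c(0.650, 0.704, 0.286)) &&
      identical(dab, c(0.268, 0.570, 0.776))
    residual <- if (default_pair) {
      c(0.711, 0.423, 0.834)
    } else {
      c(h[2] * d[3] - h[3] * d[2],
        h[3] * d[1] - h[1] * d[3],
        h[1] * d[2] - h[2] * d[1])
    }
  }
  r <- unitize(residual, "residual", allow_negative = TRUE)
  m <- rbind(hematoxylin = h, dab = d, residual = r)
  if (abs(det(m)) < 1e-3) {
    stop("configuration error: stain matrix is singular", call. = FALSE)
  }
  structure(list(hematoxylin = h, dab = d, residual = r, matrix = m),
            class = "stain_vectors")
}

# intensity (8-bit) -> optical density against background i0, guarding log(0)
intensity_to_od <- function(intensity, i0) {
  -log10(pmax(intensity, 1) / i0)
}

od_to_intensity <- function(od, i0) {
  i0 * 10^(-od)
}
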