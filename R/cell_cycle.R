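#' Cell-cycle phase durations
#'
#' Container for the four phase durations of a proliferating cell, in hours.
#' Interphase (`t_i = t_g1 + t_s + t_g2`) and total cycle time
#' (`t_c = t_i + t_m`) are derived on construction.
#'
#' @param t_g1,t_s,t_g2 Durations of G1, S and G2, in hours (>= 0).
#' @param t_m Duration of mitosis, in hours (> 0).
#' @return An object of class `cell_cycle_durations`: a list with elements
#'   `t_g1`, `t_s`, `t_g2`, `t_m`, `t_i`, `t_c`.
#' @examples
#' d <- cell_cycle_durations(t_g1 = 11, t_s = 8, t_g2 = 4, t_m = 1)
#' d$t_c  # 24
#' phh3_mib1_ratio(d)
#' @export
cell_cycle_durations <- function(t_g1, t_s, t_g2, t_m) {
  for (nm in c("t_g1", "t_s", "t_g2", "t_m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("invalid parameter: ", nm, " must be a finite number", call. = FALSE)
    }
  }
  if (t_g1 < 0 || t_s < 0 || t_g2 < 0) {
    stop("invalid parameter: phase durations must be >= 0", call. = FALSE)
  }
  if (t_m <= 0) {
    stop("invalid parameter: t_m must be > 0", call. = FALSE)
  }
  structure(
    list(t_g1 = t_g1, t_s = t_s, t_g2 = t_g2, t_m = t_m,
         t_i = t_g1 + t_s + t_g2, t_c = t_g1 + t_s + t_g2 + t_m),
    class = "cell_cycle_durations"
  )
}

#' @export
print.cell_cycle_durations <- function(x, ...) {
  cat(sprintf("Cell-cycle durations (h): G1=%g S=%g G2=%g M=%g | interphase=%g cycle=%g\n",
              x$t_g1, x$t_s, x$t_g2, x$t_m, x$t_i, x$t_c))
  invisible(x)
}

as_durations <- function(d) {
  if (inherits(d, "cell_cycle_durations")) return(d)
  stop("invalid parameter: expected a cell_cycle_durations object", call. = FALSE)
}

#' Expected PhH3/MIB-1 ratio under the phase-occupancy model
#'
#' In an asynchronously cycling population the fraction of cycling cells
#' observed in mitosis equals the fraction of the cycle spent there,
#' `t_m / (t_m + t_i)`. Since MIB-1 marks the whole cycle and PhH3 marks
#' mitosis, this is the expected PhH3/MIB-1 count ratio. The ratio falls as
#' interphase lengthens (e.g. S-phase lengthening in aneuploid tumors), which
#' decouples whole-cycle from mitosis-phase marker counts.
#'
#' @param d A [cell_cycle_durations()] object.
#' @return The ratio, a fraction in (0, 1].
#' @examples
#' phh3_mib1_ratio(cell_cycle_durations(11, 8, 4, 1))    # 1/24
#' @export
phh3_mib1_ratio <- function(d) {
  d <- as_durations(d)
  d$t_m / (d$t_m + d$t_i)
}

#' Relative change in PhH3/MIB-1 ratio between two duration sets
#'
#' Returns `1 - ratio(d_new)/ratio(d_ref)`; positive values are a relative
#' decrease in expected PhH3 staining relative to MIB-1.
#'
#' @param d_ref,d_new Reference and comparison [cell_cycle_durations()].
#' @return A signed fraction (positive = decrease).
#' @export
relative_ratio_change <- function(d_ref, d_new) {
  1 - phh3_mib1_ratio(d_new) / phh3_mib1_ratio(d_ref)
}

#' Decoupling curve: ratio as a function of interphase duration
#'
#' Evaluates the phase-occupancy ratio over a grid of interphase durations at
#' fixed mitosis duration.
#'
#' @param t_m Mitosis duration in hours (> 0).
#' @param t_i_grid Numeric vector of interphase durations in hours (>= 0).
#' @return A data.frame with columns `t_i_hours` and `ratio`.
#' @export
decoupling_curve <- function(t_m, t_i_grid) {
  if (length(t_i_grid) == 0L) {
    stop("invalid parameter: t_i_grid must be nonempty", call. = FALSE)
  }
  if (!is.numeric(t_i_grid) || any(!is.finite(t_i_grid)) || any(t_i_grid < 0)) {
    stop("invalid parameter: t_i_grid values must be finite and >= 0", call. = FALSE)
  }
  ratio <- vapply(t_i_grid, function(ti) {
    phh3_mib1_ratio(cell_cycle_durations(ti, 0, 0, t_m))
  }, numeric(1))
  data.frame(t_i_hours = t_i_grid, ratio = ratio)
}

#' Tumor growth parameters
#'
#' @param n0 Initial cell count (> 0).
#' @param p Fraction of proliferating cells, in \[0, 1\].
#' @param delta_t Elapsed time in hours (>= 0).
#' @param t_c Cell-cycle duration in hours (> 0).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(n0, p, delta_t, t_c) {
  stopifnot(is.numeric(n0), is.numeric(p), is.numeric(delta_t), is.numeric(t_c))
  if (!is.finite(n0) || n0 <= 0) stop("invalid parameter: n0 must be > 0", call. = FALSE)
  if (!is.finite(p) || p < 0 || p > 1) stop("invalid parameter: p must be in [0,1]", call. = FALSE)
  if (!is.finite(delta_t) || delta_t < 0) stop("invalid parameter: delta_t must be >= 0", call. = FALSE)
  if (!is.finite(t_c) || t_c <= 0) stop("invalid parameter: t_c must be > 0", call. = FALSE)
  structure(list(n0 = n0, p = p, delta_t = delta_t, t_c = t_c), class = "growth_params")
}

#' Expected cell count after a growth interval
#'
#' Exponential growth ignoring cell death: each cycle the population is
#' multiplied by `(1 + p)` (the non-cycling fraction persists, the cycling
#' fraction doubles), so after `delta_t` hours
#' `N = n0 * (1 + p)^(delta_t / t_c)`. Because `t_c` sits in the exponent, a
#' short cycle can outweigh a much larger proliferating fraction.
#'
#' @param g A [growth_params()] object.
#' @return Expected cell count (real, >= n0 when p > 0).
#' @examples
#' # a high-P slow-cycling tumor vs a low-P fast-cycling one, 10 days
#' grow(growth_params(1e6, 0.6, 240, 72))
#' grow(growth_params(1e6, 0.2, 240, 24))
#' @export
grow <- function(g) {
  if (!inherits(g, "growth_params")) stop("invalid parameter: expected growth_params", call. = FALSE)
  g$n0 * (1 + g$p)^(g$delta_t / g$t_c)
}

#' Expected marker-positive fractions of all cells
#'
#' Composes the proliferating fraction with the phase-occupancy model:
#' MIB-1 marks all cycling cells (up to antibody sensitivity), PhH3 marks
#' cells within a staining window at the end of the cycle (mitosis, by
#' default, optionally extending into late G2), and mitotic figures are
#' recognisable on H&E for a (typically shorter) visibility window.
#'
#' @param d A [cell_cycle_durations()] object.
#' @param p Proliferating fraction in \[0, 1\].
#' @param mib1_sensitivity Probability a cycling cell stains MIB-1 positive.
#' @param phh3_window Hours of the cycle staining PhH3-positive (default `t_m`).
#' @param mitvis_window Hours of the cycle with a recognisable mitotic figure
#'   (default `t_m`).
#' @return A list with `f_mib1`, `f_phh3`, `f_mitotic` — expected fractions of
#'   all cells (cycling and quiescent) positive for each readout.
#' @export
expected_marker_fractions <- function(d, p, mib1_sensitivity = 1,
                                      phh3_window = NULL, mitvis_window = NULL) {
  d <- as_durations(d)
  if (!is.finite(p) || p < 0 || p > 1) stop("invalid parameter: p must be in [0,1]", call. = FALSE)
  if (!is.finite(mib1_sensitivity) || mib1_sensitivity < 0 || mib1_sensitivity > 1) {
    stop("invalid parameter: mib1_sensitivity must be in [0,1]", call. = FALSE)
  }
  if (is.null(phh3_window)) phh3_window <- d$t_m
  if (is.null(mitvis_window)) mitvis_window <- d$t_m
  if (phh3_window > d$t_c || mitvis_window > d$t_c) {
    stop("invalid parameter: staining window cannot exceed the cycle duration", call. = FALSE)
  }
  if (phh3_window < 0 || mitvis_window < 0) {
    stop("invalid parameter: staining windows must be >= 0", call. = FALSE)
  }
  list(
    f_mib1 = p * mib1_sensitivity,
    f_phh3 = p * phh3_window / d$t_c,
    f_mitotic = p * mitvis_window / d$t_c
  )
}
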