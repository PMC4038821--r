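#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("invalid parameter: need two vectors of equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

cohort_variables <- c("mitoses_per_10hpf", "mib1_per_field", "phh3_per_field", "iod")

#' Pearson correlation matrix of the four cohort variables
#'
#' @param table A cohort table with columns `mitoses_per_10hpf`,
#'   `mib1_per_field`, `phh3_per_field`, `iod`.
#' @return A symmetric 4x4 matrix with unit diagonal.
#' @export
correlation_matrix <- function(table) {
  missing_cols <- setdiff(cohort_variables, names(table))
  if (length(missing_cols)) {
    stop("invalid parameter: missing columns ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(table[, cohort_variables])
  if (any(apply(m, 2, stats::sd) == 0)) {
    stop("undefined correlation: constant variable", call. = FALSE)
  }
  stats::cor(m)
}

#' Least-squares regression of MIB-1 on PhH3
#'
#' @param phh3,mib1 Numeric vectors (n >= 3, `phh3` nonconstant).
#' @return A list of class `regression_fit`: `slope`, `intercept`,
#'   `pearson_r`.
#' @export
ols_fit <- function(phh3, mib1) {
  if (length(phh3) != length(mib1) || length(phh3) < 2L) {
    stop("invalid parameter: need two vectors of equal length >= 2", call. = FALSE)
  }
  if (stats::sd(phh3) == 0) stop("invalid parameter: constant predictor", call. = FALSE)
  fit <- stats::lm(mib1 ~ phh3)
  r <- if (length(phh3) >= 3L && stats::sd(mib1) > 0) stats::cor(phh3, mib1) else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = r),
            class = "regression_fit")
}

#' Classify tumors above the regression line, by grade group
#'
#' A tumor is "above the line" when its MIB-1 count strictly exceeds the
#' fitted value at its PhH3 count (on-line points count as not above).
#' Grades 1-2 are pooled against grade 3 in the 2x2 contingency table.
#'
#' @param table A cohort table with `grade`, `mib1_per_field`,
#'   `phh3_per_field`.
#' @param fit An [ols_fit()] result.
#' @return A list: `above` (logical per tumor) and `contingency`
#'   (2x2 matrix, rows = grade group 1-2 / 3, cols = above / not above).
#' @export
classify_above_line <- function(table, fit) {
  above <- table$mib1_per_field > fit$slope * table$phh3_per_field + fit$intercept
  low <- table$grade %in% c(1, 2)
  contingency <- matrix(
    c(sum(above & low), sum(!above & low),
      sum(above & !low), sum(!above & !low)),
    nrow = 2, byrow = TRUE,
    dimnames = list(grade_group = c("1-2", "3"), c("above", "not_above"))
  )
  list(above = above, contingency = contingency)
}

#' Fisher's exact test for a 2x2 table (full enumeration)
#'
#' Enumerates every table with the observed margins under the hypergeometric
#' null and sums the probabilities of those no more likely than the observed
#' one (point-probability two-sided rule, with a 1e-7 relative tolerance for
#' ties).
#'
#' @param tab A 2x2 matrix of non-negative counts `rbind(c(a, b), c(c, d))`.
#' @return The two-sided p-value in (0, 1\].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    stop("invalid parameter: need a 2x2 matrix of non-negative integers", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (sum(tab) == 0) stop("invalid parameter: empty table", call. = FALSE)
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1.0)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1.0)
}

#' Pooled-variance two-sample t test (grades 1-2 vs grade 3)
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @param welch Use the Welch unequal-variance form instead of the pooled
#'   Student form.
#' @return A list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("invalid parameter: each group needs n >= 2", call. = FALSE)
  }
  if (!welch && stats::var(x) + stats::var(y) == 0) {
    stop("degenerate input: zero pooled variance", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Per-grade and overall mean +/- sd of the four cohort variables
#'
#' @param table A cohort table.
#' @return A data.frame with one row per grade plus `overall`, and
#'   `<var>_mean` / `<var>_sd` columns (sd is `NA` for single-tumor grades).
#' @export
grade_summary <- function(table) {
  groups <- c(split(seq_len(nrow(table)), table$grade),
              list(overall = seq_len(nrow(table))))
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    stats <- lapply(cohort_variables, function(v) {
      vals <- table[[v]][idx]
      c(mean = mean(vals), sd = if (length(vals) >= 2) stats::sd(vals) else NA_real_)
    })
    out <- data.frame(group = g, n = length(idx))
    for (i in seq_along(cohort_variables)) {
      out[[paste0(cohort_variables[i], "_mean")]] <- stats[[i]]["mean"]
      out[[paste0(cohort_variables[i], "_sd")]] <- stats[[i]]["sd"]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
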