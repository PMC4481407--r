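#' Chi-square goodness of fit against fixed null frequencies
#'
#' Compares observed per-category FT counts with expectations derived from
#' the sample's own total (`E_c = N * freq_c`), with `df = k - 1` since the
#' null frequencies are fixed a priori by the karyotype, not estimated.
#'
#' @param observed named count vector or a [count_table()].
#' @param expected_freq named null frequencies over the same categories,
#'   summing to 1 (see [expected_involvement_frequencies()]).
#' @return A `chisq_gof` object: `statistic`, `df`, `p_value`, `observed`,
#'   `expected`, `per_category_contributions`, `low_expected_warning` (TRUE
#'   if any expected count is below 5).
#' @export
chisq_gof <- function(observed, expected_freq) {
  if (inherits(observed, "count_table")) {
    observed <- observed$counts
  }
  if (is.null(names(observed)) || is.null(names(expected_freq))) {
    stop("observed and expected_freq must be named", call. = FALSE)
  }
  if (!setequal(names(observed), names(expected_freq))) {
    stop("category mismatch between observed and expected_freq", call. = FALSE)
  }
  expected_freq <- expected_freq[names(observed)]
  if (abs(sum(expected_freq) - 1) > 1e-8) {
    stop("expected_freq must sum to 1", call. = FALSE)
  }
  if (any(expected_freq <= 0 & observed > 0)) {
    stop("zero expected frequency in a category with nonzero observed count",
      call. = FALSE)
  }
  N <- sum(observed)
  if (N <= 0) {
    stop("observed counts must sum to a positive total", call. = FALSE)
  }
  E <- N * expected_freq
  contrib <- (observed - E)^2 / E
  statistic <- sum(contrib)
  df <- length(observed) - 1L
  p <- if (statistic == 0) 1 else stats::pchisq(statistic, df, lower.tail = FALSE)
  structure(
    list(
      statistic = statistic, df = df, p_value = p,
      observed = observed, expected = E,
      per_category_contributions = contrib,
      low_expected_warning = any(E < 5)
    ),
    class = "chisq_gof"
  )
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat(sprintf(
    "Chi-square goodness of fit: X2 = %.4g, df = %d, p = %.4g%s\n",
    x$statistic, x$df, x$p_value,
    if (x$low_expected_warning) "  [warning: expected count < 5]" else ""
  ))
  invisible(x)
}

#' Aggregate FT counts into euchromatic and heterochromatic groups
#'
#' Eu = A + XL; Het = XR + 4th + Y. Works on counts or on frequencies
#' (anything nonnegative named by the standard categories); totals are
#' preserved.
#'
#' @param counts a [count_table()] or named nonnegative vector over (a subset
#'   of) the standard categories.
#' @return Named vector `c(Eu = ..., Het = ...)`.
#' @export
aggregate_eu_het <- function(counts) {
  if (inherits(counts, "count_table")) {
    counts <- counts$counts
  }
  unknown <- setdiff(names(counts), CATEGORY_LEVELS)
  if (length(unknown) > 0) {
    stop("unknown categories: ", paste(unknown, collapse = ", "),
      call. = FALSE)
  }
  c(
    Eu = sum(counts[names(counts) %in% EU_CATEGORIES]),
    Het = sum(counts[names(counts) %in% HET_CATEGORIES])
  )
}

#' Exact binomial test for ring-Y excess
#'
#' Upper-tail exact binomial test of the observed number of ring-forming
#' fused Y telomeres against the null fraction (1/15 given any Y-involving
#' fusion, or 1/6 given a heterochromatic partner; see [ring_probability()]).
#'
#' @param y_fusion_count number of fused Y telomeres (trials).
#' @param y_ring_count number of those whose partner was the other arm of the
#'   same Y (successes).
#' @param null_fraction null ring probability per fusing Y telomere.
#' @return A `ring_test` object: `p_value`, `observed_fraction`,
#'   `expected_fraction`, `y_fusion_count`, `y_ring_count`, `degenerate`
#'   (TRUE when there are no Y fusions, in which case `p_value = 1`).
#' @export
ring_excess_test <- function(y_fusion_count, y_ring_count, null_fraction) {
  if (y_fusion_count < 0 || y_ring_count < 0 ||
      y_ring_count > y_fusion_count) {
    stop("need 0 <= y_ring_count <= y_fusion_count", call. = FALSE)
  }
  if (null_fraction < 0 || null_fraction > 1) {
    stop("null_fraction must lie in [0, 1]", call. = FALSE)
  }
  degenerate <- y_fusion_count == 0
  p <- if (degenerate) {
    1
  } else {
    stats::pbinom(y_ring_count - 1, y_fusion_count, null_fraction,
      lower.tail = FALSE)
  }
  structure(
    list(
      p_value = p,
      observed_fraction = if (degenerate) NA_real_ else
        y_ring_count / y_fusion_count,
      expected_fraction = null_fraction,
      y_fusion_count = y_fusion_count, y_ring_count = y_ring_count,
      degenerate = degenerate
    ),
    class = "ring_test"
  )
}

#' @export
print.ring_test <- function(x, ...) {
  if (x$degenerate) {
    cat("Ring-Y excess test: no Y fusions observed (degenerate), p = 1\n")
  } else {
    cat(sprintf(
      "Ring-Y excess test: %d/%d rings (%.4f observed vs %.4f expected), exact binomial p = %.4g\n",
      x$y_ring_count, x$y_fusion_count, x$observed_fraction,
      x$expected_fraction, x$p_value
    ))
  }
  invisible(x)
}
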