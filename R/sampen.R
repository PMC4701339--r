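#' Sample entropy of a time series
#'
#' Sample entropy (SampEn) is the negative natural logarithm of the
#' conditional probability that two sequences that match for `m` points
#' within a tolerance `r` (Chebyshev distance, self-matches excluded)
#' remain within `r` at the next point.  Lower values indicate a more
#' regular signal.  The series is expected to be standardized (zero mean,
#' unit variance) beforehand, so `r` is a tolerance in units of the
#' series' standard deviation; see [standardize_series()].
#'
#' Both the `m`-point count `B` and the `(m+1)`-point count `A` use the
#' same `N - m` templates, counted over ordered pairs `(i, j)`, `i != j`.
#' SampEn is `-log(A / B)`; when either count is zero the value is
#' undefined and `NA` is returned.
#'
#' @param x Numeric series of length at least `m + 2`.
#' @param m Embedding (template) length; the reference analysis uses 2.
#' @param r Match tolerance, in SDs of the standardized series; the
#'   reference analysis uses 0.25.
#' @return A single non-negative number, or `NA` when no template pair
#'   matches at length `m` or `m + 1`.
#' @seealso [sample_entropy_counts()] for the raw pair counts.
#' @examples
#' x <- standardize_series(sin(2 * pi * (1:300) / 40))
#' sample_entropy(x, m = 2, r = 0.25)
#' @export
sample_entropy <- function(x, m = 2, r = 0.25) {
  cnt <- sample_entropy_counts(x, m = m, r = r)
  if (cnt$A == 0 || cnt$B == 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

#' Template-pair counts behind sample entropy
#'
#' @inheritParams sample_entropy
#' @return A list with elements `A` (ordered template pairs matching over
#'   `m + 1` points) and `B` (over `m` points).
#' @export
sample_entropy_counts <- function(x, m = 2, r = 0.25) {
  if (!is.numeric(x)) stop_param("`x` must be a numeric series")
  m <- check_count(m, "m", min = 1L)
  r <- check_number(r, "r")
  if (r <= 0) stop_param("`r` must be > 0")
  if (length(x) < m + 2L) {
    stop_param(sprintf("series of length %d is too short for m = %d (need >= m + 2)",
                       length(x), m))
  }
  if (anyNA(x)) stop_param("`x` must not contain missing values")
  sampen_counts_cpp(as.numeric(x), m, r)
}

#' Standardize a series to zero mean and unit variance
#'
#' Uses the population standard deviation (divisor `N`), the convention in
#' the entropy literature, so results are exactly reproducible against
#' direct pair-count implementations.
#'
#' @param x Numeric series with at least 2 samples and nonzero variance.
#' @return The standardized series.
#' @export
standardize_series <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop_param("`x` must be a numeric series with at least 2 samples")
  }
  if (anyNA(x)) stop_param("`x` must not contain missing values")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (!is.finite(s) || s == 0) {
    stop_degenerate("cannot standardize a zero-variance series")
  }
  (x - mu) / s
}

#' Normalize a force series by body weight
#'
#' Divides every sample by `weight_kg * g`, expressing ground reaction
#' force in units of body weight.  Because standardization follows in the
#' feature pipeline, this step never changes a sample-entropy value; it is
#' kept for interpretable intermediate output.
#'
#' @param x Numeric force series, in newtons.
#' @param weight_kg Body weight in kilograms (positive).
#' @param g Gravitational acceleration, m/s^2.
#' @return The series in body-weight units.
#' @export
normalize_by_weight <- function(x, weight_kg, g = 9.81) {
  if (!is.numeric(x)) stop_param("`x` must be a numeric series")
  weight_kg <- check_number(weight_kg, "weight_kg")
  if (weight_kg <= 0) stop_param("`weight_kg` must be > 0")
  x / (weight_kg * g)
}
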