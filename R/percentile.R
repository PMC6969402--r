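#' Nearest-rank percentile threshold
#'
#' Returns the value at rank `ceiling(q * n)` of the ascending sort of
#' `values`. Selection downstream always uses `>= threshold`, so every tie at
#' the threshold is included. This estimator is deterministic and free of the
#' interpolation choices that differ between quantile algorithms, which makes
#' percentile-based selections reproducible across platforms.
#'
#' @param values numeric vector, non-empty, no NA.
#' @param q quantile in (0, 1).
#' @return the threshold, an attained value of `values`.
#' @examples
#' nearest_rank_percentile(1:100, 0.95) # 95
#' @export
nearest_rank_percentile <- function(values, q) {
  if (length(values) == 0) {
    abort("`values` must be non-empty for a nearest-rank percentile.")
  }
  if (anyNA(values)) {
    abort("`values` must not contain NA.")
  }
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort("`q` must be a single number strictly between 0 and 1.")
  }
  sort(values)[ceiling(q * length(values))]
}

#' Select elements at or above a nearest-rank percentile
#'
#' Convenience wrapper: returns a logical vector marking `values >= threshold`
#' where the threshold is [nearest_rank_percentile()] of `values`. Ties at the
#' threshold are all selected.
#'
#' @inheritParams nearest_rank_percentile
#' @return logical vector the length of `values`.
#' @export
percentile_select <- function(values, q) {
  values >= nearest_rank_percentile(values, q)
}
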