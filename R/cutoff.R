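#' Reference-interval percentile cutoff
#'
#' Computes the diagnostic cutoff as a percentile of the reference (healthy
#' control) biomarker values using rank-based linear interpolation with the
#' exclusive convention: on the ascending order statistics `X(1..n)` the
#' interpolation rank r equals `p * (n + 1)`, and the cutoff is
#' `X(floor(r)) + (r - floor(r)) * (X(floor(r) + 1) - X(floor(r)))`.
#' At the default `p = 0.95` this is the upper bound of the reference
#' interval in unaffected subjects.
#'
#' @param values Numeric reference values (at least 2).
#' @param p Percentile as a fraction in `(1/(n+1), n/(n+1))` (default 0.95).
#' @return A `cutoff_model` list: `reference_values` (sorted),
#'   `percentile`, `interpolation_rank`, `cutoff` (full precision), and
#'   `cutoff_2dp` (the reported value, rounded to 2 decimals).
#' @export
#' @examples
#' percentile_cutoff(1:19)$cutoff  # rank 19, no interpolation
percentile_cutoff <- function(values, p = 0.95) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("`values` must be free of NA", call. = FALSE)
  n <- length(values)
  if (n < 2L) stop("need at least 2 reference values", call. = FALSE)
  r <- p * (n + 1)
  if (r < 1 || r > n) {
    stop(sprintf(
      "insufficient reference size: rank %.2f outside [1, %d] at p = %g",
      r, n, p), call. = FALSE)
  }
  x <- sort(values)
  k <- floor(r)
  f <- r - k
  cutoff <- if (k >= n) x[n] else x[k] + f * (x[k + 1] - x[k])
  structure(
    list(reference_values = x, percentile = p, interpolation_rank = r,
         cutoff = cutoff, cutoff_2dp = round(cutoff, 2)),
    class = "cutoff_model"
  )
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat(sprintf(
    "<cutoff_model: %gth percentile of %d reference values, rank %.2f, cutoff %.2f>\n",
    100 * x$percentile, length(x$reference_values), x$interpolation_rank,
    x$cutoff_2dp))
  invisible(x)
}

#' Classify a biomarker score against the cutoff
#'
#' A sample is called AD when its plate-level `Ln(A/N)` is strictly above
#' the cutoff (AD fibroblasts form fewer, larger aggregates, so their mean
#' area per aggregate — hence `Ln(A/N)` — is higher). A score exactly at the
#' cutoff is called non-AD: the cutoff is the upper bound of the normal
#' reference interval, so values at it are still within normal limits.
#'
#' @param score Numeric score(s), finite.
#' @param cutoff A [percentile_cutoff()] model or a plain numeric cutoff.
#' @return Character vector of `"AD"` / `"nonAD"` calls.
#' @export
#' @examples
#' classify_score(c(8.39, 4.6, 6.98), 6.98)
classify_score <- function(score, cutoff) {
  if (inherits(cutoff, "cutoff_model")) cutoff <- cutoff$cutoff_2dp
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    stop("`cutoff` must be a single finite number or a cutoff_model",
         call. = FALSE)
  }
  if (any(!is.finite(score))) stop("`score` must be finite", call. = FALSE)
  ifelse(score > cutoff, "AD", "nonAD")
}
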