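#' Per-image biomarker score
#'
#' The image-level biomarker is `ln(A/N)`: the natural log of the mean
#' aggregate area divided by the aggregate count. Images with no aggregates
#' (`N == 0`) or non-positive area carry no defined score and return `NA`;
#' such images are excluded upstream by QC.
#'
#' @param A Mean aggregate area per image (pixels^2).
#' @param N Aggregate count per image.
#' @return `ln(A/N)` (vectorised), `NA` where undefined.
#' @export
#' @examples
#' image_score(400, 2)   # ln(200)
#' image_score(1, 1)     # 0
image_score <- function(A, N) {
  if (length(A) != length(N)) stop("`A` and `N` must match in length",
                                   call. = FALSE)
  out <- rep(NA_real_, length(A))
  ok <- !is.na(A) & !is.na(N) & N >= 1 & A > 0
  out[ok] <- log(A[ok] / N[ok])
  out
}

#' Per-well biomarker score
#'
#' Unweighted arithmetic mean of the qualified per-image scores of one
#' well. Non-finite scores (excluded images) never contribute; a well with
#' no qualified image is ineligible.
#'
#' @param image_scores Numeric vector of per-image `ln(A/N)` values.
#' @param well_id Optional identifier carried along.
#' @return A `well_score` list: `well_id`, `image_scores` (qualified only),
#'   `well_mean`, `eligible`.
#' @export
#' @examples
#' well_score(c(5, 7))$well_mean  # 6
well_score <- function(image_scores, well_id = NA_character_) {
  qualified <- image_scores[is.finite(image_scores)]
  structure(
    list(well_id = as.character(well_id),
         image_scores = qualified,
         well_mean = if (length(qualified)) mean(qualified) else NA_real_,
         eligible = length(qualified) > 0L),
    class = "well_score"
  )
}

#' Per-plate biomarker score
#'
#' The plate-level `Ln(A/N)` is the unweighted mean of the eligible wells'
#' means (wells are not weighted by how many qualified images they
#' contributed). The dispersion reported alongside is the sample standard
#' deviation over all contributing per-image scores pooled across wells —
#' the plate's technical-replicate spread.
#'
#' @param wells List of [well_score()] records.
#' @param sample_id Sample (patient / cell line) identifier.
#' @param min_wells Minimum eligible wells for a valid plate (default 3,
#'   matching the plate QC gate).
#' @return A `plate_score` list: `sample_id`, `well_means`, `ln_a_over_n`,
#'   `sd`, `n_images`, `n_wells`.
#' @export
#' @examples
#' ws <- lapply(list(c(5, 7), 6, c(6, 6)), well_score)
#' plate_score(ws, "S1")$ln_a_over_n
plate_score <- function(wells, sample_id = NA_character_, min_wells = 3L) {
  eligible <- Filter(function(w) isTRUE(w$eligible), wells)
  if (length(eligible) < min_wells) {
    stop(structure(
      class = c("mi_plate_rejected", "error", "condition"),
      list(message = sprintf(
        "plate rejected: %d eligible wells, need at least %d",
        length(eligible), min_wells), call = sys.call())))
  }
  well_means <- vapply(eligible, function(w) w$well_mean, numeric(1))
  pooled <- unlist(lapply(eligible, function(w) w$image_scores))
  structure(
    list(sample_id = as.character(sample_id),
         well_means = well_means,
         ln_a_over_n = mean(well_means),
         sd = if (length(pooled) > 1) sd(pooled) else NA_real_,
         n_images = length(pooled),
         n_wells = length(eligible)),
    class = "plate_score"
  )
}

#' @export
print.plate_score <- function(x, ...) {
  cat(sprintf("<plate_score %s: Ln(A/N) = %.3f (sd %.3f, %d images, %d wells)>\n",
              x$sample_id, x$ln_a_over_n, x$sd, x$n_images, x$n_wells))
  invisible(x)
}
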