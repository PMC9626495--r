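#' Iterative intermeans (IsoData) threshold
#'
#' Ridler-Calvard iterative intermeans: starting from the global mean, the
#' threshold is repeatedly replaced by the midpoint of the means of the two
#' classes it induces, until it stabilises. This is the default automatic
#' global threshold of the assay's image chain.
#'
#' The iteration runs on a 256-bin intensity histogram (the class means are
#' computed from bin centres), matching the histogram-based convention of
#' interactive image-analysis tools.
#'
#' @param px Numeric matrix or vector of intensities.
#' @param bins Number of histogram bins (default 256).
#' @return The threshold value, or `NA` for a constant input (no foreground
#'   can be separated).
#' @export
#' @examples
#' isodata_threshold(c(rep(10, 90), rep(200, 10)))
isodata_threshold <- function(px, bins = 256L) {
  v <- as.numeric(px)
  rng <- range(v)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  cnt <- tabulate(idx, nbins = bins)
  ctr <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w <- cnt * ctr
  t0 <- sum(w) / sum(cnt)
  for (iter in 1:200) {
    lo <- ctr <= t0
    n_lo <- sum(cnt[lo])
    n_hi <- sum(cnt[!lo])
    if (n_lo == 0L || n_hi == 0L) break
    t1 <- (sum(w[lo]) / n_lo + sum(w[!lo]) / n_hi) / 2
    if (abs(t1 - t0) < 1e-8 * diff(rng)) {
      t0 <- t1
      break
    }
    t0 <- t1
  }
  t0
}

#' Binarise an image with an automatic global threshold
#'
#' Foreground is every pixel strictly above the iterative-intermeans
#' threshold. A constant image yields an empty (all-background) mask rather
#' than an error. An automatic global threshold always splits *something*,
#' even pure noise, so a separation guard declares the mask empty unless
#' the two intensity classes are genuinely distinct: the class-mean gap
#' must reach `min_separation` times the summed within-class spreads.
#' Fields with objects separate at 4-5 on this ratio, noise-only fields at
#' about 1.5, so the default 2.5 sits between the regimes.
#'
#' @param img A [field_image()] or numeric matrix.
#' @param min_separation Minimum `(mu_fg - mu_bg) / (sd_bg + sd_fg)` ratio
#'   for a non-empty mask (default 2.5).
#' @return Logical matrix, `TRUE` = foreground.
#' @export
#' @examples
#' m <- matrix(c(10, 200), 8, 8)
#' sum(binarize(m))  # the 200-valued pixels
binarize <- function(img, min_separation = 2.5) {
  px <- as_pixels(img)
  thr <- isodata_threshold(px)
  if (is.na(thr)) {
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  lo <- px[px <= thr]
  hi <- px[px > thr]
  sd_lo <- if (length(lo) > 1) sd(lo) else 0
  sd_hi <- if (length(hi) > 1) sd(hi) else 0
  if ((mean(hi) - mean(lo)) < min_separation * (sd_lo + sd_hi)) {
    return(matrix(FALSE, nrow(px), ncol(px)))
  }
  px > thr
}

#' Particle analysis of a binary mask
#'
#' Labels 8-connected foreground components and retains those with pixel
#' area at or above `min_size` (inclusive lower bound). Surviving particles
#' are relabelled 1..k in order of first encounter.
#'
#' @param mask Logical matrix (foreground `TRUE`).
#' @param min_size Minimum particle area in pixels^2 (default 180, the chain
#'   setting).
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `particle_set`: list with `particle_areas`
#'   (integer vector), `particle_count`, and `label_image` (integer matrix,
#'   0 = background).
#' @export
#' @examples
#' m <- matrix(FALSE, 30, 30); m[2:16, 2:16] <- TRUE
#' analyze_particles(m)$particle_count
analyze_particles <- function(mask, min_size = 180, connectivity = 8L) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  if (!is.logical(mask)) {
    mask <- mask > 0
  }
  lab <- cpp_label_components(mask, as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) {
    return(structure(list(particle_areas = integer(0), particle_count = 0L,
                          label_image = lab),
                     class = "particle_set"))
  }
  areas <- tabulate(lab, nbins = k)
  keep <- which(areas >= min_size)
  remap <- integer(k)
  remap[keep] <- seq_along(keep)
  out <- lab
  nz <- lab != 0L
  out[nz] <- remap[lab[nz]]
  structure(
    list(particle_areas = areas[keep], particle_count = length(keep),
         label_image = out),
    class = "particle_set"
  )
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set: %d particles, mean area %.1f px^2>\n",
              x$particle_count,
              if (x$particle_count > 0) mean(x$particle_areas) else NA_real_))
  invisible(x)
}

# The shared filter chain: despeckle x3, minimum filter x3, rolling-ball
# background subtraction, binarise, particle analysis.
run_chain <- function(img, params = mi_defaults(), min_size) {
  px <- as_pixels(img)
  for (i in seq_len(params$filter$despeckle_repeats)) px <- cpp_median3x3(px)
  fp <- rank_footprint(params$filter$min_filter_radius)
  storage.mode(fp) <- "integer"
  for (i in seq_len(params$filter$min_filter_repeats)) {
    px <- cpp_min_filter(px, fp)
  }
  bg <- cpp_rolling_background(px, params$filter$rolling_radius)
  px <- pmax(px - bg, 0)
  mask <- binarize(px)
  analyze_particles(mask, min_size = min_size)
}

#' Count cells in an attachment-phase field
#'
#' Runs the full plug-in chain — despeckle three times, minimum filter
#' (radius 0.5) three times, rolling-ball background subtraction (radius
#' 20), automatic binarisation, then particle analysis with a 180 px^2
#' floor — and returns the particle count. Degenerate (e.g. constant) images
#' yield 0.
#'
#' @param img A [field_image()] or numeric matrix.
#' @param params Parameter list from [mi_defaults()].
#' @return Integer cell count.
#' @export
#' @examples
#' f <- generate_field(field_spec("attachment", n_objects = 20,
#'                                image_shape = c(300, 300), seed = 1))
#' count_cells(f$image)
count_cells <- function(img, params = mi_defaults()) {
  run_chain(img, params, min_size = params$particles$min_cell_area)$particle_count
}

#' Measure aggregates in a 48-hour field
#'
#' Applies the same chain as [count_cells()] with the aggregate-phase
#' minimum particle size, and returns the mean aggregate area `A`, the
#' aggregate count `N`, and the per-image score `ln(A/N)`. An image with no
#' detected aggregates is flagged unusable (`usable = FALSE`, score `NA`)
#' rather than raising an error; the QC layer drops it.
#'
#' @param img A [field_image()] or numeric matrix.
#' @param params Parameter list from [mi_defaults()].
#' @return List with `A` (mean particle area, px^2), `N` (count),
#'   `ln_a_over_n`, and `usable`.
#' @export
measure_aggregates <- function(img, params = mi_defaults()) {
  ps <- run_chain(img, params, min_size = params$particles$min_aggregate_area)
  if (ps$particle_count == 0L) {
    return(list(A = NA_real_, N = 0L, ln_a_over_n = NA_real_, usable = FALSE))
  }
  A <- mean(ps$particle_areas)
  N <- ps$particle_count
  list(A = A, N = N, ln_a_over_n = log(A / N), usable = TRUE)
}
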