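#' Specification for one synthetic microscopy field
#'
#' Describes a field to be rendered by [generate_field()]: bright
#' Gaussian-blurred discs (cells at attachment, aggregates at 48 h) on a
#' noisy background with a low-order illumination gradient. Three regimes
#' are supported: `attachment` (many non-overlapping cell-sized objects),
#' `aggregated_AD_like` (few large aggregates, as in AD fibroblast
#' cultures), and `aggregated_nonAD_like` (many small aggregates). Regime
#' defaults are chosen so that, under the canonical 1000 x 1000 8-bit
#' geometry, AD-like fields score `ln(A/N)` above ~7 and non-AD-like fields
#' well below 6.5, straddling the reference cutoff by construction.
#'
#' @param regime One of `"attachment"`, `"aggregated_AD_like"`,
#'   `"aggregated_nonAD_like"`.
#' @param n_objects Number of objects to place (regime default when `NULL`).
#' @param radius_mean,radius_sd Object radius distribution in px (normal,
#'   truncated at 2 sd); regime defaults when `NULL`.
#' @param foreground,background Object and background intensity levels
#'   (8-bit scale); foreground must exceed background.
#' @param noise_sd Additive Gaussian read-noise sd (Poisson shot noise is
#'   always applied on top of the clean intensity).
#' @param gradient_amp Peak-to-peak amplitude of the additive illumination
#'   plane.
#' @param image_shape Integer `(rows, cols)` in px.
#' @param blur_sigma Gaussian point-spread sigma in px.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   field and ground truth.
#' @return An object of class `field_spec`.
#' @export
#' @examples
#' field_spec("attachment", n_objects = 50, image_shape = c(400, 400), seed = 1)
field_spec <- function(regime = c("attachment", "aggregated_AD_like",
                                  "aggregated_nonAD_like"),
                       n_objects = NULL, radius_mean = NULL, radius_sd = NULL,
                       foreground = 150, background = 30, noise_sd = 6,
                       gradient_amp = 12, image_shape = c(1000L, 1000L),
                       blur_sigma = 1.5, seed = 1L) {
  regime <- match.arg(regime)
  reg_defaults <- switch(regime,
    attachment            = list(n = 417L, rm = 13, rs = 1),
    aggregated_AD_like    = list(n = 5L,   rm = 48, rs = 3),
    aggregated_nonAD_like = list(n = 60L,  rm = 13, rs = 1)
  )
  if (is.null(n_objects)) n_objects <- reg_defaults$n
  if (is.null(radius_mean)) radius_mean <- reg_defaults$rm
  if (is.null(radius_sd)) radius_sd <- reg_defaults$rs
  n_objects <- as.integer(n_objects)
  if (is.na(n_objects) || n_objects < 0) stop("`n_objects` must be >= 0",
                                              call. = FALSE)
  if (radius_mean <= 0 || radius_sd < 0) stop("radii must be positive",
                                              call. = FALSE)
  if (foreground <= background) {
    stop("`foreground` must exceed `background`", call. = FALSE)
  }
  if (length(image_shape) != 2L || any(image_shape < 8)) {
    stop("`image_shape` must be (rows, cols), each >= 8", call. = FALSE)
  }
  structure(
    list(regime = regime, n_objects = n_objects,
         radius_mean = radius_mean, radius_sd = radius_sd,
         foreground = foreground, background = background,
         noise_sd = noise_sd, gradient_amp = gradient_amp,
         image_shape = as.integer(image_shape), blur_sigma = blur_sigma,
         seed = as.integer(seed)),
    class = "field_spec"
  )
}

# Fill the union of discs into a logical matrix. Centres are (row, col),
# radii in px; discs may extend to (but not beyond) the image bounds.
render_disc_mask <- function(shape, centres, radii) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (length(radii) == 0L) return(mask)
  for (k in seq_along(radii)) {
    r <- radii[k]
    ci <- centres[k, 1]
    cj <- centres[k, 2]
    i0 <- max(1L, floor(ci - r))
    i1 <- min(shape[1], ceiling(ci + r))
    j0 <- max(1L, floor(cj - r))
    j1 <- min(shape[2], ceiling(cj + r))
    ii <- i0:i1
    jj <- j0:j1
    d2 <- outer((ii - ci)^2, (jj - cj)^2, `+`)
    mask[ii, jj] <- mask[ii, jj] | (d2 <= r^2)
  }
  mask
}

# Non-overlapping placement on a jittered grid. Guarantees a minimum 2 px
# edge-to-edge gap between neighbours; fails deterministically (rather than
# by exhausting rejection samples) when the geometry cannot host n objects.
place_non_overlapping <- function(shape, n, r_max) {
  margin <- r_max + 2
  g <- ceiling(sqrt(n))
  cell <- (shape - 2 * margin) / g
  if (any(cell < 2 * (r_max + 1))) {
    stop(sprintf(paste0(
      "cannot place %d non-overlapping objects of radius up to %.1f px in a ",
      "%d x %d image: grid cell %.1f px is below the %.1f px required; ",
      "reduce `n_objects` or `radius_mean`, or enlarge `image_shape`"),
      n, r_max, shape[1], shape[2], min(cell), 2 * (r_max + 1)),
      call. = FALSE)
  }
  cells <- sample.int(g * g, n)
  gi <- (cells - 1) %% g
  gj <- (cells - 1) %/% g
  jit <- cell / 2 - r_max - 1
  ci <- margin + (gi + 0.5) * cell[1] + runif(n, -jit[1], jit[1])
  cj <- margin + (gj + 0.5) * cell[2] + runif(n, -jit[2], jit[2])
  cbind(ci, cj)
}

#' Render a synthetic field with known ground truth
#'
#' Renders the field described by a [field_spec()] and returns both the
#' image and its ground truth. Objects are discs with normally distributed
#' radii, blurred by a Gaussian point spread, on a background carrying an
#' illumination plane, Poisson shot noise, and Gaussian read noise, rounded
#' to the 8-bit range. In the attachment regime objects never overlap (so
#' the ground-truth count equals `n_objects`); in the aggregated regimes
#' objects are placed uniformly at random and may merge, and the ground
#' truth reflects the 8-connected components after merging, not the seeds
#' placed.
#'
#' @param spec A [field_spec()].
#' @param well_id,field_index,time_point Metadata for the returned
#'   [field_image()]; `time_point` defaults to `"attachment"` or `"48h"`
#'   according to the regime.
#' @return List with `image` (a [field_image()]) and `truth` (class
#'   `ground_truth`: `object_count`, `object_areas`, `mean_area`).
#' @export
#' @examples
#' f <- generate_field(field_spec("attachment", n_objects = 12,
#'                                image_shape = c(300, 300), seed = 42))
#' f$truth$object_count
generate_field <- function(spec, well_id = "W1", field_index = 1L,
                           time_point = NULL) {
  stopifnot(inherits(spec, "field_spec"))
  if (is.null(time_point)) {
    time_point <- if (spec$regime == "attachment") "attachment" else "48h"
  }
  shape <- spec$image_shape
  with_local_seed(spec$seed, {
    n <- spec$n_objects
    radii <- if (n > 0) {
      pmin(pmax(rnorm(n, spec$radius_mean, spec$radius_sd),
                spec$radius_mean - 2 * spec$radius_sd),
           spec$radius_mean + 2 * spec$radius_sd)
    } else {
      numeric(0)
    }
    centres <- if (n == 0) {
      matrix(numeric(0), 0, 2)
    } else if (spec$regime == "attachment") {
      place_non_overlapping(shape, n, spec$radius_mean + 2 * spec$radius_sd)
    } else {
      margin <- radii + 2
      cbind(runif(n, margin, shape[1] - margin),
            runif(n, margin, shape[2] - margin))
    }
    mask <- render_disc_mask(shape, centres, radii)

    clean <- spec$background + (spec$foreground - spec$background) * mask
    clean <- gaussian_blur(clean, spec$blur_sigma)
    rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    grad <- spec$gradient_amp *
      ((rows / shape[1] + cols / shape[2]) / 2 - 0.5)
    clean <- pmax(clean + grad, 0)

    px <- matrix(rpois(length(clean), clean), shape[1], shape[2]) +
      rnorm(length(clean), 0, spec$noise_sd)
    px <- round(pmin(pmax(px, 0), 255))

    lab <- cpp_label_components(mask, 8L)
    k <- max(lab)
    areas <- if (k > 0) tabulate(lab, nbins = k) else integer(0)
    list(
      image = field_image(px, well_id = well_id, field_index = field_index,
                          time_point = time_point, bit_depth = 8L),
      truth = structure(
        list(object_count = k, object_areas = areas,
             mean_area = if (k > 0) mean(areas) else NA_real_),
        class = "ground_truth")
    )
  })
}

#' Simulate and score a whole assay plate
#'
#' End-to-end run of the assay on synthetic data: for each of 4 wells,
#' renders attachment-phase fields (target 417 cells per field with
#' realistic seeding spread), counts them with the image chain, applies the
#' field/well/plate QC gates, then renders 48-hour aggregate fields in the
#' requested morphology regime, measures `(A, N)` per image, and averages
#' the qualified image scores to well and plate level.
#'
#' @param regime `"aggregated_AD_like"` or `"aggregated_nonAD_like"` — the
#'   48-hour morphology of the simulated sample.
#' @param seed Root seed; per-field streams are derived from it with
#'   [derive_seed()], so results do not depend on generation order.
#' @param sample_id Identifier for the simulated sample.
#' @param params Assay parameters from [mi_defaults()].
#' @param seeding_sd Standard deviation of the per-field true cell count
#'   around the 417-cell target (plating/pipetting spread; default 25).
#' @param image_shape Field geometry (default the canonical 1000 x 1000).
#' @return List with `plate_qc` (a [plate_passes()] record), `score` (a
#'   [plate_score()] record, or `NULL` if the plate failed QC), and
#'   `fields` (per-field data frame: well, field, phase, true object count,
#'   measured count or `(A, N, score)`).
#' @export
run_plate <- function(regime = c("aggregated_AD_like", "aggregated_nonAD_like"),
                      seed = 1L, sample_id = "SIM-1",
                      params = mi_defaults(), seeding_sd = 25,
                      image_shape = params$image$shape) {
  regime <- match.arg(regime)
  qc <- params$qc
  rows <- list()
  well_qcs <- vector("list", qc$n_wells)
  well_scores <- vector("list", qc$n_wells)

  for (w in seq_len(qc$n_wells)) {
    wid <- paste0("W", w)
    fqs <- vector("list", qc$n_fields)
    for (f in seq_len(qc$n_fields)) {
      n_true <- with_local_seed(derive_seed(seed, wid, f, "seeding"),
                                max(0L, round(rnorm(1, params$target_cells,
                                                    seeding_sd))))
      fld <- generate_field(
        field_spec("attachment", n_objects = n_true,
                   image_shape = image_shape,
                   seed = derive_seed(seed, wid, f, "attachment")),
        well_id = wid, field_index = f)
      cnt <- count_cells(fld$image, params)
      fqs[[f]] <- field_passes(cnt, qc$ln_window, field_index = f)
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = wid, field_index = f, phase = "attachment",
        n_true = n_true, n_measured = cnt,
        A = NA_real_, score = NA_real_, passed = fqs[[f]]$passed)
    }
    well_qcs[[w]] <- well_passes(fqs, qc$min_pass_fields, qc$n_fields,
                                 well_id = wid)

    img_scores <- numeric(0)
    for (f in seq_len(qc$n_fields)) {
      fld <- generate_field(
        field_spec(regime, image_shape = image_shape,
                   seed = derive_seed(seed, wid, f, "aggregate")),
        well_id = wid, field_index = f)
      m <- measure_aggregates(fld$image, params)
      img_scores <- c(img_scores, m$ln_a_over_n)
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = wid, field_index = f, phase = "48h",
        n_true = fld$truth$object_count, n_measured = m$N,
        A = m$A, score = m$ln_a_over_n, passed = m$usable)
    }
    well_scores[[w]] <- well_score(img_scores, well_id = wid)
  }

  plate_qc <- plate_passes(well_qcs, qc$min_pass_wells, qc$n_wells)
  score <- NULL
  if (plate_qc$passed) {
    passing <- vapply(well_qcs, function(w) w$passed, logical(1))
    score <- plate_score(well_scores[passing], sample_id = sample_id,
                         min_wells = qc$min_pass_wells)
  }
  list(plate_qc = plate_qc, score = score,
       fields = do.call(rbind, rows))
}
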