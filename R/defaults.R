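#' Assay parameter defaults
#'
#' One list holding every tunable of the pipeline, QC gates, scoring, and
#' cutoff, at the published assay settings. Pass a modified copy to the
#' functions that accept `params` to change behaviour; the defaults
#' reproduce the assay exactly.
#'
#' Components:
#' \describe{
#'   \item{filter}{`despeckle_repeats` (3), `min_filter_repeats` (3),
#'     `min_filter_radius` (0.5 px), `rolling_radius` (20 px).}
#'   \item{particles}{`min_cell_area` (180 px^2),
#'     `min_aggregate_area` (180 px^2; the assay defines the floor only for
#'     the counting step, so the same value is used at 48 h).}
#'   \item{qc}{`ln_window` (5.811, 6.214) on the natural-log cell count,
#'     `n_fields` (9 per well), `min_pass_fields` (5), `n_wells` (4),
#'     `min_pass_wells` (3).}
#'   \item{cutoff}{`percentile` (0.95).}
#'   \item{image}{canonical synthetic geometry: `shape` (1000 x 1000 px),
#'     `bit_depth` (8).}
#'   \item{target_cells}{417 cells per 10x field (ln 417 = 6.033).}
#' }
#'
#' @return Named list of parameter groups.
#' @export
#' @examples
#' p <- mi_defaults()
#' p$qc$ln_window
mi_defaults <- function() {
  list(
    filter = list(
      despeckle_repeats = 3L,
      min_filter_repeats = 3L,
      min_filter_radius = 0.5,
      rolling_radius = 20
    ),
    particles = list(
      min_cell_area = 180,
      min_aggregate_area = 180
    ),
    qc = list(
      ln_window = c(5.811, 6.214),
      n_fields = 9L,
      min_pass_fields = 5L,
      n_wells = 4L,
      min_pass_wells = 3L
    ),
    cutoff = list(percentile = 0.95),
    image = list(shape = c(1000L, 1000L), bit_depth = 8L),
    target_cells = 417L
  )
}
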