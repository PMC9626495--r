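#' Field-level density QC
#'
#' A field passes when the natural log of its cell count falls inside the
#' acceptance window (bounds inclusive). The window corresponds to the
#' target density of 417 cells per 10x field (ln 417 = 6.033) with the
#' assay's tolerated range, translating to roughly 330-500 cells; the ln
#' window, not the rounded count range, is the authoritative gate. A count
#' of zero always fails.
#'
#' @param cell_count Non-negative integer cell count.
#' @param window Length-2 numeric, inclusive (lo, hi) on ln(count).
#' @param field_index Optional 1-based field index carried into the record.
#' @return A `field_qc` list: `field_index`, `cell_count`, `ln_count`,
#'   `passed`.
#' @export
#' @examples
#' field_passes(417)$passed  # TRUE: ln 417 = 6.033 inside the window
#' field_passes(300)$passed  # FALSE: ln 300 = 5.704 below it
field_passes <- function(cell_count, window = mi_defaults()$qc$ln_window,
                         field_index = NA_integer_) {
  if (length(cell_count) != 1L || is.na(cell_count) || cell_count < 0) {
    stop("`cell_count` must be a single non-negative count", call. = FALSE)
  }
  if (length(window) != 2L || window[1] > window[2]) {
    stop("`window` must be an increasing (lo, hi) pair", call. = FALSE)
  }
  ln_count <- if (cell_count > 0) log(cell_count) else -Inf
  structure(
    list(field_index = as.integer(field_index),
         cell_count = as.integer(cell_count),
         ln_count = ln_count,
         passed = is.finite(ln_count) &&
           ln_count >= window[1] && ln_count <= window[2]),
    class = "field_qc"
  )
}

#' Well-level QC
#'
#' A well passes when at least `min_pass` of its `n_fields` fields passed
#' the density gate. Supplying a different number of field records than
#' `n_fields` is a configuration error.
#'
#' @param field_qcs List of [field_passes()] records.
#' @param min_pass Minimum number of passing fields (default 5).
#' @param n_fields Expected fields per well (default 9).
#' @param well_id Optional well identifier carried into the record.
#' @return A `well_qc` list: `well_id`, `field_qcs`, `n_passed`, `passed`.
#' @export
well_passes <- function(field_qcs, min_pass = 5L, n_fields = 9L,
                        well_id = NA_character_) {
  if (length(field_qcs) != n_fields) {
    stop(sprintf("expected %d field QC records per well, got %d",
                 n_fields, length(field_qcs)), call. = FALSE)
  }
  n_passed <- sum(vapply(field_qcs, function(f) isTRUE(f$passed), logical(1)))
  structure(
    list(well_id = as.character(well_id), field_qcs = field_qcs,
         n_passed = n_passed, passed = n_passed >= min_pass),
    class = "well_qc"
  )
}

#' Plate-level QC
#'
#' A plate continues to analysis when at least 3 of its 4 wells passed;
#' otherwise the assay must be repeated (`repeat_required`). A plate is
#' always 4 wells; anything else is a configuration error.
#'
#' @param well_qcs List of exactly 4 [well_passes()] records.
#' @param min_pass_wells Minimum passing wells (default 3).
#' @param n_wells Expected wells per plate (default 4).
#' @return A `plate_qc` list: `well_qcs`, `n_passed`, `passed`,
#'   `repeat_required`.
#' @export
plate_passes <- function(well_qcs, min_pass_wells = 3L, n_wells = 4L) {
  if (length(well_qcs) != n_wells) {
    stop(sprintf("expected %d well QC records per plate, got %d",
                 n_wells, length(well_qcs)), call. = FALSE)
  }
  n_passed <- sum(vapply(well_qcs, function(w) isTRUE(w$passed), logical(1)))
  passed <- n_passed >= min_pass_wells
  structure(
    list(well_qcs = well_qcs, n_passed = n_passed, passed = passed,
         repeat_required = !passed),
    class = "plate_qc"
  )
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf("<plate_qc: %d/%d wells passed -> %s%s>\n",
              x$n_passed, length(x$well_qcs),
              if (x$passed) "PASS" else "FAIL",
              if (x$repeat_required) " (repeat required)" else ""))
  invisible(x)
}

#' Serialise a plate QC verdict as JSON
#'
#' Emits per-field, per-well, and plate verdicts, naming the gate that was
#' applied at each level.
#'
#' @param plate_qc A [plate_passes()] record.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @param window The ln-count window used at field level (recorded in the
#'   report).
#' @return JSON string (invisibly when written to `path`).
#' @export
qc_report <- function(plate_qc, path = NULL,
                      window = mi_defaults()$qc$ln_window) {
  stopifnot(inherits(plate_qc, "plate_qc"))
  wells <- lapply(plate_qc$well_qcs, function(w) {
    list(
      well_id = w$well_id,
      passed = w$passed,
      n_passed_fields = w$n_passed,
      gate = "min 5 of 9 fields within ln-count window",
      fields = lapply(w$field_qcs, function(f) {
        list(field_index = f$field_index, cell_count = f$cell_count,
             ln_count = round(f$ln_count, 4), passed = f$passed,
             gate = sprintf("ln(count) in [%.3f, %.3f]", window[1], window[2]))
      })
    )
  })
  rep <- list(
    plate = list(passed = plate_qc$passed,
                 repeat_required = plate_qc$repeat_required,
                 n_passed_wells = plate_qc$n_passed,
                 gate = "min 3 of 4 wells passing"),
    wells = wells
  )
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
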