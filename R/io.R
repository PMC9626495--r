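#' Write a field image as an 8-bit single-channel TIFF
#'
#' @param img A [field_image()] or numeric matrix with values in
#'   `[0, 2^bit_depth - 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("writing TIFF requires the `tiff` package", call. = FALSE)
  }
  px <- as_pixels(img)
  bits <- if (inherits(img, "field_image")) img$bit_depth else 8L
  tiff::writeTIFF(px / (2^bits - 1), path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read a single-channel TIFF or PNG as a field image
#'
#' @param path Input file (`.tif`/`.tiff` or `.png`).
#' @param well_id,field_index,time_point,bit_depth Metadata for the
#'   returned [field_image()].
#' @return A [field_image()] with intensities rescaled to
#'   `[0, 2^bit_depth - 1]`.
#' @export
read_field_image <- function(path, well_id = "W1", field_index = 1L,
                             time_point = "attachment", bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the `tiff` package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the `png` package", call. = FALSE)
    }
    png::readPNG(path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(px)) == 3L) px <- px[, , 1]  # first channel of grey RGB
  field_image(round(px * (2^bit_depth - 1)), well_id = well_id,
              field_index = field_index, time_point = time_point,
              bit_depth = bit_depth)
}

#' Write ground truth as a sidecar JSON file
#'
#' @param truth A `ground_truth` record from [generate_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  js <- jsonlite::toJSON(
    list(object_count = truth$object_count,
         object_areas = truth$object_areas,
         mean_area = truth$mean_area),
    auto_unbox = TRUE, digits = NA)
  writeLines(js, path)
  invisible(path)
}
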