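#' Construct a microscopy field image
#'
#' A `field_image` bundles one grayscale field (pixel matrix, row-major
#' top-left origin, intensities in `[0, 2^bit_depth - 1]`) with its
#' acquisition metadata: well, 1-based field index within the well, and the
#' time point in the assay schedule.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param well_id Well identifier, e.g. `"W1"`.
#' @param field_index 1-based index of the field within its well.
#' @param time_point One of `"attachment"`, `"3h"`, `"5h"`, `"24h"`, `"48h"`.
#' @param bit_depth Integer bit depth of the acquisition (default 8).
#' @return An object of class `field_image`.
#' @export
#' @examples
#' img <- field_image(matrix(0, 16, 16), well_id = "W1", field_index = 1)
#' dim(img$pixels)
field_image <- function(pixels, well_id = "W1", field_index = 1L,
                        time_point = c("attachment", "3h", "5h", "24h", "48h"),
                        bit_depth = 8L) {
  time_point <- match.arg(time_point)
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) == 0L)) {
    stop("`pixels` must be a non-empty numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0)) {
    stop("`pixels` must be non-negative and free of NA", call. = FALSE)
  }
  field_index <- as.integer(field_index)
  if (is.na(field_index) || field_index < 1L) {
    stop("`field_index` must be >= 1", call. = FALSE)
  }
  structure(
    list(pixels = pixels, well_id = as.character(well_id),
         field_index = field_index, time_point = time_point,
         bit_depth = as.integer(bit_depth)),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image %dx%d px, well %s, field %d, %s, %d-bit>\n",
              nrow(x$pixels), ncol(x$pixels), x$well_id, x$field_index,
              x$time_point, x$bit_depth))
  invisible(x)
}

# Accept either a bare matrix or a field_image; return the pixel matrix.
as_pixels <- function(img) {
  if (inherits(img, "field_image")) img$pixels
  else if (is.matrix(img) && is.numeric(img)) img
  else stop("expected a `field_image` or a numeric matrix", call. = FALSE)
}

# Put a processed pixel matrix back into the same container as the input.
rewrap <- function(img, pixels) {
  if (inherits(img, "field_image")) {
    img$pixels <- pixels
    img
  } else {
    pixels
  }
}
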