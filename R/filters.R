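#' Despeckle (3x3 median) filter
#'
#' One application of a 3x3 sliding-window median, the "Despeckle" step of
#' the assay's image chain. Isolated bright or dark single pixels (shot
#' noise) are removed; edges are handled by replicating the border pixel.
#' The chain applies this three times in a row (see [count_cells()]).
#'
#' @param img A [field_image()] or numeric matrix.
#' @return Filtered image of the same class and shape as the input.
#' @export
#' @examples
#' m <- matrix(10, 9, 9); m[5, 5] <- 200
#' despeckle(m)[5, 5]  # speckle removed
despeckle <- function(img) {
  rewrap(img, cpp_median3x3(as_pixels(img)))
}

# Footprint offsets (dr, dc) for a rank filter of the given radius. Radius
# below 1 gives the 5-pixel cross (centre + 4 edge neighbours), the kernel
# the chain uses for its radius-0.5 minimum filter; otherwise the Euclidean
# disc dr^2 + dc^2 <= r^2.
rank_footprint <- function(radius) {
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  if (radius < 1) {
    return(cbind(dr = c(0L, -1L, 1L, 0L, 0L), dc = c(0L, 0L, 0L, -1L, 1L)))
  }
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Minimum (grayscale erosion) filter
#'
#' One application of a rank minimum filter. At the default radius 0.5 the
#' footprint is the 4-connected cross, so each pixel is replaced by the
#' minimum over itself and its 4 edge neighbours. Borders are edge-replicated.
#'
#' @param img A [field_image()] or numeric matrix.
#' @param radius Footprint radius in pixels (default 0.5, the chain setting).
#' @return Filtered image of the same class and shape as the input.
#' @export
#' @examples
#' m <- matrix(10, 9, 9); m[5, 5] <- 200
#' max(min_filter(m))  # bright pixel eroded away
min_filter <- function(img, radius = 0.5) {
  fp <- rank_footprint(radius)
  storage.mode(fp) <- "integer"
  rewrap(img, cpp_min_filter(as_pixels(img), fp))
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grey opening of the image with an
#' elliptic paraboloid osculating a ball of the given radius (the
#' paraboloid-approximation variant of the rolling-ball algorithm), then
#' subtracts it and clips at zero. Bright features whose spatial scale is
#' well below the ball radius are preserved essentially unchanged; smooth
#' illumination gradients and the flat baseline are removed.
#'
#' @param img A [field_image()] or numeric matrix.
#' @param rolling_radius Ball radius in pixels (default 20, the chain
#'   setting).
#' @return Background-subtracted image, same class and shape, minimum 0.
#' @export
#' @examples
#' m <- matrix(50, 32, 32)
#' range(subtract_background(m))  # flat image -> all zero
subtract_background <- function(img, rolling_radius = 20) {
  if (rolling_radius <= 0) stop("`rolling_radius` must be > 0", call. = FALSE)
  px <- as_pixels(img)
  bg <- cpp_rolling_background(px, rolling_radius)
  rewrap(img, pmax(px - bg, 0))
}

# Separable Gaussian blur with edge-replicated borders, used by the synthetic
# field renderer. Kernel truncated at 3 sigma.
gaussian_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  blur_1d <- function(m, along_rows) {
    n <- if (along_rows) ncol(m) else nrow(m)
    acc <- 0
    for (k in seq_along(w)) {
      off <- k - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      acc <- acc + w[k] * (if (along_rows) m[, idx, drop = FALSE]
                           else m[idx, , drop = FALSE])
    }
    acc
  }
  blur_1d(blur_1d(px, TRUE), FALSE)
}
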