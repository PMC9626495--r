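#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' generators are reproducible without clobbering the session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-stream seed
#'
#' Mixes a root seed with labels (well, field, phase, ...) into a new seed,
#' so every field of a simulated plate has its own stream regardless of the
#' order in which fields are generated. Plain multiplicative integer mixing
#' over the Mersenne prime 2^31 - 1; collisions across the handful of labels
#' used per plate are not a concern.
#'
#' @param seed Root integer seed.
#' @param ... Additional labels (coerced to character).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "W1", 3, "attachment")
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "|"),
                         character(1)), collapse = "/")
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  bytes <- utf8ToInt(labels)
  for (b in bytes) {
    h <- (h * 48271 + b + 1) %% m
  }
  h <- (h * 48271 + 1) %% m
  as.integer(h %% (m - 1) + 1)
}
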