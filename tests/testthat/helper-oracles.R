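# Brute-force reference implementations, written independently of the
# package's filter code paths, used to validate the optimised filters.

shift_clamp <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[pmin(pmax(seq_len(nr) + dr, 1L), nr),
    pmin(pmax(seq_len(nc) + dc, 1L), nc), drop = FALSE]
}

# 3x3 sliding-window median with edge replication, via apply over windows.
oracle_median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- pmin(pmax((i - 1):(i + 1), 1L), nr)
      jj <- pmin(pmax((j - 1):(j + 1), 1L), nc)
      out[i, j] <- median(m[ii, jj])
    }
  }
  out
}

# Minimum over an offset footprint with edge replication.
oracle_min_filter <- function(m, offsets) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- vapply(seq_len(nrow(offsets)), function(o) {
        m[pmin(pmax(i + offsets[o, 1], 1L), nr),
          pmin(pmax(j + offsets[o, 2], 1L), nc)]
      }, numeric(1))
      out[i, j] <- min(vals)
    }
  }
  out
}

# Flood-fill connected-component labelling (stack-based), independent of the
# compiled labeller.
oracle_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j] || lab[i, j] != 0L) next
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (o in seq_len(nrow(nb))) {
          ii <- p[1] + nb[o, 1]; jj <- p[2] + nb[o, 2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Exact binomial interval by direct inversion of the binomial tails
# (independent of the beta-quantile route used in the package).
oracle_clopper <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lo <- if (x == 0) 0 else {
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  }
  hi <- if (x == n) 1 else {
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  }
  c(lo, hi)
}

# Random logical blob mask: thresholded smoothed noise.
random_blob_mask <- function(nr, nc, seed, fill = 0.4) {
  set.seed(seed)
  m <- matrix(runif(nr * nc), nr, nc)
  for (k in 1:2) {
    m <- (shift_clamp(m, 1, 0) + shift_clamp(m, -1, 0) +
            shift_clamp(m, 0, 1) + shift_clamp(m, 0, -1) + m) / 5
  }
  m > quantile(m, 1 - fill)
}
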