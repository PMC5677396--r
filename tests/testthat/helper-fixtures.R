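# Small configurations and fixtures shared across test files.
# Everything is generated in code; nothing is read from disk.

tiny_config <- function(...) {
  synthetic_config(
    n_per_class = c(paddy = 8L, red = 7L, seashore_saline = 6L),
    n_bands = 40L,
    roi_size = 16L,
    ...
  )
}

tiny_dataset <- function(seed = 1, ...) {
  simulate_soil_dataset(tiny_config(...), seed = seed)
}

# cube with deterministic, distinguishable values per (row, col, band)
fixture_cube <- function(rows = 2, cols = 2, bands = 3) {
  wl <- seq(1000, by = 50, length.out = bands)
  vals <- array(seq_len(rows * cols * bands), dim = c(rows, cols, bands))
  hsi_cube(vals, wl)
}

# brute-force QR-based SPA oracle: at each step, explicitly refactorise the
# selected columns and pick the unselected column with the largest residual
# norm after projection onto their orthogonal complement (ties -> lowest
# index). Independent of the deflation-based implementation.
spa_chain_oracle <- function(X, start, k) {
  p <- ncol(X)
  chain <- as.integer(start)
  for (step in seq_len(min(k, p) - 1L)) {
    S <- X[, chain, drop = FALSE]
    qs <- qr(S)
    Q <- qr.Q(qs)[, seq_len(qs$rank), drop = FALSE]
    resid_norms <- vapply(seq_len(p), function(j) {
      if (j %in% chain) return(-Inf)
      r <- X[, j] - Q %*% crossprod(Q, X[, j])
      sum(r^2)
    }, numeric(1))
    if (max(resid_norms) <= max(colSums(X^2)) * 1e-12) break
    chain <- c(chain, which.max(resid_norms))
  }
  chain
}

# per-fold explicit-refit LOOCV oracle via normal equations
loocv_oracle <- function(X, y) {
  n <- nrow(X)
  errs <- vapply(seq_len(n), function(i) {
    Xi <- cbind(1, X[-i, , drop = FALSE])
    b <- solve(crossprod(Xi), crossprod(Xi, y[-i]))
    y[i] - c(1, X[i, ]) %*% b
  }, numeric(1))
  sqrt(mean(errs^2))
}
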