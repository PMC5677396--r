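# SIMPLS (de Jong 1993) for a univariate response.
# Returns score/loading/weight matrices and per-component regression
# coefficients on the centered scale. Components are truncated when the
# deflated covariance collapses (rank exhausted).
simpls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  x_center <- colMeans(X)
  y_center <- mean(y)
  X0 <- sweep(X, 2, x_center)
  y0 <- y - y_center
  A <- min(ncomp, n - 1L, p)
  R <- matrix(0, p, A) # X-weights
  P <- matrix(0, p, A) # X-loadings
  Q <- numeric(A)      # y-loadings
  V <- matrix(0, p, A) # orthonormal basis for loading space
  s <- crossprod(X0, y0)
  a_used <- 0L
  for (a in seq_len(A)) {
    r <- s
    t_scores <- X0 %*% r
    t_scores <- t_scores - mean(t_scores)
    tt <- sum(t_scores^2)
    if (tt < .Machine$double.eps * n) break
    normt <- sqrt(tt)
    t_scores <- t_scores / normt
    r <- r / normt
    p_load <- crossprod(X0, t_scores)
    q_load <- sum(y0 * t_scores)
    v <- p_load
    if (a > 1) {
      v <- v - V[, seq_len(a - 1L), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1L), drop = FALSE], p_load)
    }
    nv <- sqrt(sum(v^2))
    if (nv < .Machine$double.eps) break
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
    P[, a] <- p_load
    Q[a] <- q_load
    V[, a] <- v
    a_used <- a
  }
  if (a_used == 0L) abort("PLSR failed: predictor matrix has no usable variance.")
  A <- a_used
  R <- R[, seq_len(A), drop = FALSE]
  Q <- Q[seq_len(A)]
  # coefficients for every component count 1..A
  coefs <- sapply(seq_len(A), function(a) {
    R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
  })
  list(coefs = matrix(coefs, nrow = p), x_center = x_center,
       y_center = y_center, ncomp = A)
}

simpls_predict <- function(fit, X, ncomp) {
  X0 <- sweep(as.matrix(X), 2, fit$x_center)
  as.numeric(X0 %*% fit$coefs[, ncomp]) + fit$y_center
}

#' Partial least squares regression with LOOCV component selection
#'
#' Fits a SIMPLS partial least squares regression of a single response on a
#' (typically collinear) predictor matrix. The number of latent components
#' is chosen as the minimiser of leave-one-out cross-validated RMSECV on the
#' calibration data, up to `max_components` (clipped, with a warning, to the
#' available rank).
#'
#' @param x Predictor matrix or tibble of numeric columns (preprocessed
#'   calibration spectra or effective-wavelength subset).
#' @param y Numeric response (soil TN, %).
#' @param max_components Ceiling on latent components (default 20).
#' @param select `"loocv"` (default) or `"fixed"` (use `max_components`).
#' @return Object of class `plsr_model` with the chosen component count,
#'   coefficient path, LOOCV curve and the training data summary needed for
#'   prediction via `predict()`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(30 * 8), 30, 8)
#' y <- X %*% rnorm(8)
#' m <- fit_plsr(X, y, max_components = 6)
#' m$ncomp
#' @export
fit_plsr <- function(x, y, max_components = 20L, select = c("loocv", "fixed")) {
  select <- match.arg(select)
  X <- as.matrix(x)
  n <- nrow(X)
  y <- as.numeric(y)
  if (length(y) != n) abort("`x` and `y` sizes disagree.")
  if (n <= 2) abort("Need more than 2 calibration samples.")
  rank_cap <- min(n - 1L, ncol(X))
  if (max_components > rank_cap) {
    warn(sprintf("`max_components` clipped from %d to the available rank %d.",
                 max_components, rank_cap))
    max_components <- rank_cap
  }
  full <- simpls_fit(X, y, max_components)
  A <- full$ncomp
  rmsecv <- rep(NA_real_, A)
  if (select == "loocv" && n >= 3) {
    press <- matrix(NA_real_, n, A)
    for (i in seq_len(n)) {
      f <- simpls_fit(X[-i, , drop = FALSE], y[-i], A)
      for (a in seq_len(f$ncomp)) {
        press[i, a] <- y[i] - simpls_predict(f, X[i, , drop = FALSE], a)
      }
    }
    rmsecv <- sqrt(colMeans(press^2))
    ncomp <- which.min(rmsecv)
  } else {
    ncomp <- A
  }
  structure(
    list(
      ncomp = as.integer(ncomp),
      max_components = as.integer(A),
      coefs = full$coefs,
      x_center = full$x_center,
      y_center = full$y_center,
      rmsecv = rmsecv,
      feature_names = colnames(X)
    ),
    class = "plsr_model"
  )
}

#' @export
predict.plsr_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_center)) {
    abort("`newdata` has the wrong number of predictors.")
  }
  simpls_predict(object, X, ncomp)
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> SIMPLS, %d latent component(s) (LOOCV over 1..%d)\n",
              x$ncomp, x$max_components))
  invisible(x)
}

#' @export
tidy.plsr_model <- function(x, ...) {
  nm <- x$feature_names %||% paste0("x", seq_along(x$x_center))
  tibble(term = nm, estimate = x$coefs[, x$ncomp])
}

#' @export
glance.plsr_model <- function(x, ...) {
  tibble(
    ncomp = x$ncomp,
    max_components = x$max_components,
    rmsecv = if (all(is.na(x$rmsecv))) NA_real_ else x$rmsecv[x$ncomp]
  )
}
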