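#' Successive projections algorithm chain from one start variable
#'
#' Greedy forward construction of a low-collinearity variable subset: at each
#' step every unselected column is projected onto the orthogonal complement
#' of the span of the already-selected columns, and the column with the
#' largest projected norm is appended. Ties are broken by lowest column
#' index; the chain stops early (with a warning) once all remaining projected
#' norms are numerically zero, i.e. the selected set spans the column space.
#'
#' @param X Numeric matrix `n x p` (preprocessed calibration spectra).
#' @param start Index of the first selected column.
#' @param k Requested chain length (`<= p`).
#' @return Integer vector of selected column indices, length `<= k`.
#' @seealso [select_effective_wavelengths()]
#' @export
spa_chain <- function(X, start, k) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (start < 1 || start > p) abort("`start` out of range.")
  if (k < 1) abort("`k` must be >= 1.")
  k <- min(k, p)
  tol <- max(colSums(X^2)) * 1e-12
  D <- X
  chain <- integer(k)
  chain[1] <- as.integer(start)
  for (step in seq_len(k - 1L)) {
    v <- D[, chain[step]]
    nv <- sum(v^2)
    if (nv <= tol) {
      warn("SPA chain stopped early: selected columns span the column space.")
      return(chain[seq_len(step)])
    }
    # deflate: remove the component along the newest selected direction
    D <- D - v %*% (crossprod(v, D) / nv)
    norms <- colSums(D^2)
    norms[chain[seq_len(step)]] <- -Inf
    if (max(norms) <= tol) {
      warn("SPA chain stopped early: selected columns span the column space.")
      return(chain[seq_len(step)])
    }
    chain[step + 1L] <- which.max(norms)
  }
  chain
}

#' Leave-one-out RMSECV of a multiple linear regression
#'
#' Fits ordinary least squares with intercept of `y` on the selected columns
#' and returns the leave-one-out cross-validation root mean square error,
#' computed exactly from the single full fit through the PRESS identity
#' `e_i / (1 - h_ii)`.
#'
#' @param X Numeric matrix `n x m` of predictors (a candidate subset).
#' @param y Numeric response of length `n` (TN in %, or category codes 1/2/3
#'   when wavelengths are selected for classification).
#' @return RMSECV (same units as `y`).
#' @export
mlr_loocv_rmsecv <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) abort("`X` and `y` sizes disagree.")
  if (n <= ncol(X) + 1L) abort("Need n > number of predictors + 1 for LOOCV.")
  Xd <- cbind(1, X)
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) abort("Rank-deficient predictor subset.")
  Q <- qr.Q(qr_x)
  h <- rowSums(Q^2)
  if (any(h >= 1 - 1e-10)) abort("A leverage of 1 makes LOOCV undefined for this subset.")
  e <- y - Xd %*% qr.coef(qr_x, y)
  sqrt(mean((e / (1 - h))^2))
}

# LOOCV RMSECV for every prefix of a chain, by incremental Gram-Schmidt.
# Columns (intercept first, then X[, chain] in order) are orthonormalised
# with one re-orthogonalisation pass; at each prefix size the PRESS identity
# gives the exact LOOCV error of the OLS fit. Rank-deficient additions give
# NA for that and later sizes.
chain_rmsecv <- function(X, y, chain) {
  n <- nrow(X)
  k <- length(chain)
  Q <- matrix(0, n, k + 1L)
  Q[, 1] <- 1 / sqrt(n)
  qty <- numeric(k + 1L)
  qty[1] <- sum(Q[, 1] * y)
  fitted <- Q[, 1] * qty[1]
  h <- Q[, 1]^2
  out <- rep(NA_real_, k)
  r <- 1L
  for (j in seq_len(k)) {
    v <- X[, chain[j]]
    nv0 <- sqrt(sum(v^2))
    for (pass in 1:2) {
      v <- v - Q[, seq_len(r), drop = FALSE] %*%
        crossprod(Q[, seq_len(r), drop = FALSE], v)
    }
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || nv <= nv0 * 1e-10 + 1e-300) {
      break # collinear with the prefix: this and longer subsets are rank-deficient
    }
    r <- r + 1L
    Q[, r] <- v / nv
    qy <- sum(Q[, r] * y)
    fitted <- fitted + Q[, r] * qy
    h <- h + Q[, r]^2
    if (n > j + 1L && all(h < 1 - 1e-10)) {
      e <- y - fitted
      out[j] <- sqrt(mean((e / (1 - h))^2))
    }
  }
  out
}

#' Select effective wavelengths by SPA with the F-test size criterion
#'
#' Three phases. (1) A projection chain is grown from every candidate start
#' variable ([spa_chain()]). (2) Every chain prefix of size
#' `m = 1..max_vars` is scored by MLR leave-one-out RMSECV on the
#' calibration set; the best subset per size forms the RMSECV curve and the
#' overall best subset attains `rmsecv_min`. (3) Variable elimination: the
#' variables of the best subset are ranked by relevance (predictor SD times
#' absolute regression coefficient), nested relevance-ordered subsets are
#' rescored, and the final size is the smallest `k` whose squared RMSECV is
#' not significantly larger than the scan minimum under an F-test at level
#' `alpha`: `RMSECV(k)^2 <= F(1 - alpha; n, n) * RMSECV_min^2`. This keeps
#' the model parsimonious: informative variables carry large relevance, and
#' dropping the uninformative tail never fails the F-test.
#'
#' @param x Calibration spectra: a spectra tibble (see [spectra_format]) or a
#'   numeric matrix. Preprocess (SNV + z-score) before selection.
#' @param y Response: TN (%) for regression-oriented selection, or soil-type
#'   category codes 1/2/3 (used as a single continuous response) for
#'   classification-oriented selection. When `x` is a spectra tibble, `y`
#'   may be `"tn"` or `"class"` to pull the column from the table.
#' @param max_vars Largest subset size scored; default
#'   `min(30, n - 2, n_bands)`.
#' @param alpha F-test significance level (default 0.25); smaller `alpha`
#'   (larger F critical value) admits subsets further above the minimum and
#'   so never selects more variables.
#' @param wavelengths Band wavelengths in nm (parsed from the tibble's
#'   columns automatically).
#' @return Object of class `spa_result`: list with `curve` (tibble of
#'   `size`, `rmsecv`, `start` from phase 2), `elimination` (tibble of
#'   `size`, `rmsecv` over the relevance-ordered scan), `best_size`,
#'   `selected_indices`, `selected_wavelengths_nm`, `rmsecv_selected`,
#'   `rmsecv_min` (phase-2 minimum), `f_critical`, `alpha`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 12), 40, 12)
#' y <- 2 * X[, 3] - X[, 9] # depends on exactly two variables
#' res <- select_effective_wavelengths(X, y, max_vars = 6)
#' res$best_size
#' sort(res$selected_indices)
#' @export
select_effective_wavelengths <- function(x, y, max_vars = NULL, alpha = 0.25,
                                         wavelengths = NULL) {
  if (is.data.frame(x)) {
    if (is.character(y) && length(y) == 1) {
      y <- switch(y,
        tn = x$tn_percent,
        class = soil_type_code(x$soil_type),
        abort("`y` must be \"tn\", \"class\", or a numeric vector.")
      )
    }
    wavelengths <- spectra_wavelengths(x)
    x <- spectra_matrix(x)
  }
  X <- as.matrix(x)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort("`x` and `y` sizes disagree.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (all(apply(X, 2, sd) == 0)) abort("All-constant predictor matrix.")
  if (is.null(max_vars)) max_vars <- min(30L, n - 2L, p)
  max_vars <- as.integer(max_vars)
  if (max_vars < 1 || max_vars > min(n - 2L, p)) {
    abort("`max_vars` must be in [1, min(n - 2, n_bands)].")
  }

  best_rmsecv <- rep(Inf, max_vars)
  best_chain <- vector("list", max_vars)
  best_start <- rep(NA_integer_, max_vars)
  for (s in seq_len(p)) {
    chain <- suppressWarnings(spa_chain(X, s, max_vars))
    rc <- chain_rmsecv(X, y, chain)
    for (m in seq_along(rc)) {
      if (!is.na(rc[m]) && rc[m] < best_rmsecv[m]) {
        best_rmsecv[m] <- rc[m]
        best_chain[[m]] <- chain[seq_len(m)]
        best_start[m] <- s
      }
    }
  }
  scored <- is.finite(best_rmsecv)
  if (!any(scored)) abort("No scorable SPA subset (rank-deficient inputs).")
  m_star <- which.min(replace(best_rmsecv, !scored, Inf))
  rmsecv_min <- best_rmsecv[m_star]
  subset_star <- best_chain[[m_star]]

  # phase 3: relevance-ordered elimination scan over the best subset
  Xs <- X[, subset_star, drop = FALSE]
  qr_s <- qr(cbind(1, Xs))
  coef_s <- qr.coef(qr_s, y)[-1]
  relevance <- apply(Xs, 2, sd) * abs(coef_s)
  ord <- subset_star[order(relevance, decreasing = TRUE)]
  scan <- chain_rmsecv(X, y, ord)
  f_critical <- qf(1 - alpha, n, n)
  scan_min <- min(scan, na.rm = TRUE)
  # numerically-zero RMSECVs (exact fits) count as reaching the minimum;
  # the scan minimiser itself always qualifies (ratio 1)
  tol_zero <- 1e-8 * max(sd(y), .Machine$double.eps)
  ok <- !is.na(scan) & (scan^2 <= f_critical * scan_min^2 * (1 + 1e-12) + 1e-300 |
                          scan <= scan_min * (1 + 1e-12) |
                          scan <= tol_zero)
  best_size <- which(ok)[1]
  selected <- ord[seq_len(best_size)]
  structure(
    list(
      curve = tibble(
        size = seq_len(max_vars)[scored],
        rmsecv = best_rmsecv[scored],
        start = best_start[scored]
      ),
      elimination = tibble(size = seq_along(scan), rmsecv = scan),
      best_size = best_size,
      selected_indices = selected,
      selected_wavelengths_nm =
        if (!is.null(wavelengths)) wavelengths[selected] else NULL,
      rmsecv_selected = scan[best_size],
      rmsecv_min = rmsecv_min,
      f_critical = f_critical,
      alpha = alpha,
      n_cal = n
    ),
    class = "spa_result"
  )
}

#' @export
print.spa_result <- function(x, ...) {
  cat(sprintf(
    "<spa_result> %d effective wavelength(s) of %d sizes scored; RMSECV %.4g (min %.4g), F-crit %.3f (alpha %.2f)\n",
    x$best_size, nrow(x$curve), x$rmsecv_selected,
    x$rmsecv_min, x$f_critical, x$alpha))
  if (!is.null(x$selected_wavelengths_nm)) {
    cat("  selected:", paste(sprintf("%.1f", sort(x$selected_wavelengths_nm)),
                             collapse = ", "), "nm\n")
  } else {
    cat("  selected indices:", paste(sort(x$selected_indices), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.spa_result <- function(x, ...) x$curve

#' @export
glance.spa_result <- function(x, ...) {
  tibble(
    best_size = x$best_size,
    rmsecv_best = x$rmsecv_selected,
    rmsecv_min = x$rmsecv_min,
    f_critical = x$f_critical,
    alpha = x$alpha,
    n_cal = x$n_cal
  )
}

#' @export
autoplot.spa_result <- function(object, ...) {
  curve <- object$curve
  best <- curve[curve$size == object$best_size, ]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$size, y = .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = best, colour = "red", size = 2.5) +
    ggplot2::geom_hline(yintercept = object$rmsecv_min, linetype = "dashed") +
    ggplot2::labs(
      x = "Number of selected variables",
      y = "RMSECV (leave-one-out)",
      title = sprintf("SPA subset-size curve (chosen size %d)", object$best_size)
    ) +
    ggplot2::theme_minimal()
}
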