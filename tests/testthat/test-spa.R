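test_that("orthogonal and duplicated columns behave as projection theory dictates", {
  # orthonormal columns with distinct scales: largest remaining norm wins
  X <- cbind(e1 = c(1, 0, 0), e2 = c(0, 2, 0), e3 = c(0, 0, 1.5))
  expect_identical(spa_chain(X, 1, 2), c(1L, 2L))
  expect_identical(spa_chain(X, 1, 3), c(1L, 2L, 3L))

  # an exact duplicate has zero projected norm and is never picked before
  # independent columns
  set.seed(1)
  Xd <- matrix(rnorm(20), 10, 2)
  Xd <- cbind(Xd, Xd[, 1])
  chain <- spa_chain(Xd, 1, 2)
  expect_identical(chain, c(1L, 2L))
  expect_warning(spa_chain(Xd, 1, 3), "span")
})

test_that("deflation chains match the QR-refactorisation oracle on random instances", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    p <- sample(2:min(8, n - 1), 1)
    X <- matrix(rnorm(n * p), n, p)
    k <- sample(seq_len(p), 1)
    for (start in seq_len(p)) {
      expect_identical(spa_chain(X, start, k), spa_chain_oracle(X, start, k))
    }
  }
})

test_that("LOOCV RMSECV matches the per-fold refit oracle and exact-fit limits", {
  set.seed(3)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- X %*% c(1, -2, 0.5) + rnorm(12, sd = 0.3)
  expect_equal(mlr_loocv_rmsecv(X, y), loocv_oracle(X, y), tolerance = 1e-10)

  # noiseless linear response -> zero cross-validation error
  y_exact <- as.numeric(X %*% c(2, 1, -1)) + 3
  expect_lt(mlr_loocv_rmsecv(X, y_exact), 1e-10)
  x1 <- matrix(c(1, 2, 3, 4, 5), 5)
  expect_lt(mlr_loocv_rmsecv(x1, 2 * x1[, 1]), 1e-10)

  expect_error(mlr_loocv_rmsecv(cbind(X, X[, 1]), y), "Rank-deficient")
})

test_that("chain prefix scoring agrees with the standalone LOOCV surface", {
  set.seed(8)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- rnorm(15)
  chain <- spa_chain(X, 2, 5)
  fast <- soilhsi:::chain_rmsecv(X, y, chain)
  for (m in seq_along(chain)) {
    expect_equal(fast[m], mlr_loocv_rmsecv(X[, chain[seq_len(m)], drop = FALSE], y),
                 tolerance = 1e-9)
  }
})

test_that("selection recovers a planted two-variable support exactly", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(25 * 20), 25, 20)
    support <- sort(sample(20, 2))
    y <- as.numeric(X[, support] %*% c(1.5, -2))
    # scan up to the full variable count so some chain surely spans the support
    res <- select_effective_wavelengths(X, y, max_vars = 20)
    expect_equal(res$best_size, 2)
    expect_setequal(res$selected_indices, support)
  }
})

test_that("the F-test criterion tightens as alpha shrinks", {
  set.seed(11)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- X %*% rnorm(12) + rnorm(30, sd = 2)
  sizes <- vapply(c(0.5, 0.25, 0.1, 0.01), function(a) {
    select_effective_wavelengths(X, y, max_vars = 8, alpha = a)$best_size
  }, numeric(1))
  # smaller alpha -> larger F critical -> never more variables
  expect_true(all(diff(sizes) <= 0))

  tiny_alpha <- select_effective_wavelengths(X, y, max_vars = 8, alpha = 1e-12)
  expect_equal(tiny_alpha$best_size, 1)
})

test_that("selection postconditions hold on the returned object", {
  set.seed(13)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rnorm(20)
  res <- select_effective_wavelengths(X, y, max_vars = 6, alpha = 0.25)
  expect_equal(length(res$selected_indices), res$best_size)
  expect_false(any(duplicated(res$selected_indices)))
  expect_equal(res$rmsecv_min, min(res$curve$rmsecv))
  scan_min <- min(res$elimination$rmsecv, na.rm = TRUE)
  expect_lte(res$rmsecv_selected^2, res$f_critical * scan_min^2 * (1 + 1e-12))
  # the selection also passes the F-test against the global curve minimum
  expect_lte(res$rmsecv_selected^2, res$f_critical * res$rmsecv_min^2 * (1 + 1e-12))
  # curve covers every size and the selected subset is well-conditioned
  expect_equal(res$curve$size, 1:6)
  G <- crossprod(X[, res$selected_indices, drop = FALSE])
  expect_true(is.finite(kappa(G)))

  expect_error(select_effective_wavelengths(matrix(1, 10, 4), rnorm(10)),
               "constant")
})

test_that("selection from a spectra tibble returns wavelengths and tidiers work", {
  ds <- tiny_dataset(seed = 5)
  pp <- preprocess_spectra(ds$spectra)
  res <- select_effective_wavelengths(pp$calibration, "class", max_vars = 5)
  expect_true(all(res$selected_wavelengths_nm >= 975 &
                    res$selected_wavelengths_nm <= 1645))
  expect_named(tidy(res), c("size", "rmsecv", "start"))
  expect_equal(glance(res)$best_size, res$best_size)
  expect_s3_class(autoplot(res), "ggplot")
})
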