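make_manifest <- function(n_per_class) {
  purrr::imap_dfr(n_per_class, function(n, cl) {
    tibble::tibble(sample_id = sprintf("%s_%03d", cl, seq_len(n)), soil_type = cl)
  })
}

test_that("stratified 2:1 split reproduces the cohort arithmetic", {
  m <- make_manifest(c(paddy = 84, red = 57, seashore_saline = 42))
  sp <- stratified_split(m, seed = 1)
  counts <- table(m$soil_type[match(sp$sample_id[sp$set == "calibration"], m$sample_id)])
  expect_equal(unname(c(counts[c("paddy", "red", "seashore_saline")])), c(56, 38, 28))
  expect_equal(sum(sp$set == "calibration"), 122)
  expect_equal(sum(sp$set == "prediction"), 61)

  pooled <- stratified_split(m, seed = 1, stratify = FALSE)
  expect_equal(sum(pooled$set == "calibration"), 122)

  three <- stratified_split(tibble::tibble(sample_id = c("a", "b", "c")),
                            seed = 1, stratify = FALSE)
  expect_equal(unname(table(three$set)["calibration"]), 2)

  expect_identical(stratified_split(m, seed = 9), stratified_split(m, seed = 9))
  expect_false(identical(stratified_split(m, seed = 9)$set,
                         stratified_split(m, seed = 10)$set))
  expect_error(stratified_split(m, ratio = 1.2), "ratio")
})

test_that("split covers every sample exactly once", {
  m <- make_manifest(c(paddy = 10, red = 7, seashore_saline = 5))
  sp <- stratified_split(m, seed = 3)
  expect_setequal(sp$sample_id, m$sample_id)
  expect_false(any(duplicated(sp$sample_id)))
})

separable_features <- function(n_per_class = c(paddy = 12, red = 12, seashore_saline = 12),
                               gap = 10, noise = 0.1, seed = 1) {
  m <- make_manifest(n_per_class)
  centers <- c(paddy = 0, red = gap, seashore_saline = 2 * gap)
  withr::with_seed(seed, {
    dplyr::mutate(m,
      f1 = centers[soil_type] + rnorm(nrow(m), sd = noise),
      f2 = centers[soil_type] + rnorm(nrow(m), sd = noise)
    )
  })
}

test_that("SVM separates far-apart classes perfectly and reports consistent accuracy", {
  feats <- separable_features()
  sp <- stratified_split(feats, seed = 2)
  rep <- fit_svm(feats, sp, svm_config(log2_cost = seq(-3, 7, 2),
                                       log2_gamma = seq(-7, 1, 2), folds = 3))
  expect_equal(unname(rep$overall["calibration"]), 1)
  expect_equal(unname(rep$overall["prediction"]), 1)
  cm <- rep$confusion$prediction
  expect_equal(unname(rep$overall["prediction"]), sum(diag(cm)) / sum(cm))
  per_class <- table(feats$soil_type)
  expect_equal(as.numeric(rowSums(cm)),
               as.numeric(per_class - floor(per_class * 2 / 3)))
})

test_that("permuted labels drive prediction accuracy to chance", {
  accs <- vapply(1:10, function(s) {
    feats <- separable_features(noise = 0.1, seed = s)
    feats$soil_type <- withr::with_seed(100 + s, sample(feats$soil_type))
    sp <- stratified_split(feats, seed = s)
    rep <- fit_svm(feats, sp, svm_config(cost = 1, gamma = 0.5))
    unname(rep$overall["prediction"])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.15)
})

test_that("SVM grid search is invariant to feature column order", {
  feats <- separable_features(gap = 3, noise = 1.5, seed = 4)
  sp <- stratified_split(feats, seed = 4)
  cfg <- svm_config(log2_cost = seq(-3, 5, 2), log2_gamma = seq(-5, 1, 2), folds = 3)
  a <- fit_svm(feats, sp, cfg)
  b <- fit_svm(feats[c("sample_id", "soil_type", "f2", "f1")], sp, cfg)
  expect_equal(a$overall, b$overall)
  expect_equal(a$cost, b$cost)
  expect_equal(a$gamma, b$gamma)
})

test_that("feature fusion concatenates blocks and enforces sample identity", {
  spectral <- tibble::tibble(sample_id = c("a", "b"), soil_type = "paddy",
                             wl_1000.00 = c(1, 2))
  texture <- tibble::tibble(sample_id = c("a", "b"), soil_type = "paddy",
                            energy_1000.00 = c(0.5, 0.6))
  fused <- fuse_features(spectral, texture)
  expect_named(fused, c("sample_id", "soil_type", "wl_1000.00", "energy_1000.00"))

  expect_identical(fuse_features(spectral, NULL), spectral)
  expect_identical(fuse_features(spectral, texture[, c("sample_id", "soil_type")]),
                   spectral)
  expect_error(fuse_features(spectral, texture[2:1, ]), "order")

  ds <- tiny_dataset(seed = 6)
  wl7 <- ds$wavelengths[seq(2, 38, length.out = 7)]
  tex <- texture_feature_table(ds, wl7)
  spec_ew <- ds$spectra[c("sample_id", "soil_type",
                          soilhsi:::wavelength_colnames(wl7))]
  fused_big <- fuse_features(spec_ew, tex)
  expect_equal(ncol(fused_big) - 2, 7 + 28)
})

test_that("PCA + Fisher LDA nails separable classes and conserves variance", {
  ds <- tiny_dataset(seed = 8, baseline_jitter_sd = 0.1, spectral_noise_sd = 0.01,
                     water_trough = list(center_nm = 1400, width_nm = 60, depth = 12,
                                         depth_scale = c(paddy = 0.5, red = 1, seashore_saline = 1.8),
                                         depth_jitter_sd = 0.005,
                                         center_offset = c(paddy = -25, red = 0, seashore_saline = 25),
                                         center_jitter_sd = 0.1),
                     slope_jitter_sd = 0.05, curvature_jitter_sd = 0.05)
  pp <- preprocess_spectra(ds$spectra)
  lda <- pca_lda_explore(pp$calibration, n_pcs = 4)
  expect_equal(lda$accuracy, 1)
  expect_equal(sum(lda$variance_explained), 1)
  expect_s3_class(autoplot(lda), "ggplot")

  # PCA score orthogonality
  X <- spectra_matrix(pp$calibration)
  pc <- prcomp(X, center = TRUE)
  cov_scores <- cov(pc$x[, 1:4])
  expect_lt(max(abs(cov_scores[upper.tri(cov_scores)])), 1e-8)
  expect_equal(sum(pc$sdev^2), sum(apply(X, 2, var)))

  expect_error(pca_lda_explore(pp$calibration, n_pcs = 100), "below")
})

test_that("regression metrics reproduce the published RPD arithmetic", {
  # printed prediction-set SD 0.042 with RMSEP 0.0166 -> RPD 2.5 (1 dp)
  expect_equal(round(0.042 / 0.0166, 1), 2.5)
  expect_equal(round(0.037 / 0.0176, 1), 2.1)

  set.seed(10)
  y <- rnorm(20, 0.16, 0.042)
  yhat <- y + rnorm(20, sd = 0.01)
  m <- regression_metrics(y, yhat)
  expect_equal(m$rmsep, sqrt(mean((y - yhat)^2)))
  expect_equal(m$r2, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  expect_equal(m$rpd, sd(y) / m$rmsep)

  perfect <- regression_metrics(y, y)
  expect_equal(perfect$rmsep, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rpd, Inf)
  expect_error(regression_metrics(rep(1, 5), rnorm(5)), "Constant")
})

test_that("every published RPD cell is consistent with SD/RMSEP at one decimal", {
  chk <- check_rpd_consistency()
  expect_equal(nrow(chk), 8)
  expect_true(all(chk$consistent))
})

test_that("SIMPLS fits exactly in the noiseless limit and matches an independent PLS", {
  set.seed(12)
  X <- matrix(rnorm(30 * 10), 30, 10)
  beta <- rnorm(10)
  y <- as.numeric(X %*% beta)
  m <- fit_plsr(X, y, max_components = 10)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)

  # rank-1 predictors reduce to univariate regression on the shared direction
  x1 <- rnorm(20)
  X1 <- outer(x1, c(1, 2, -1))
  y1 <- 3 * x1 + rnorm(20, sd = 0.01)
  expect_warning(m1 <- fit_plsr(X1, y1, max_components = 5), "clipped|rank")
  uni <- lm(y1 ~ x1)
  expect_equal(predict(m1, X1), unname(fitted(uni)), tolerance = 1e-6)

  skip_if_not_installed("mixOmics")
  colnames(X) <- paste0("b", 1:10)
  ref <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
  pred_ref <- predict(ref, X)$predict[, 1, 4]
  ours <- fit_plsr(X, y, max_components = 4, select = "fixed")
  expect_equal(unname(predict(ours, X, ncomp = 4)), unname(pred_ref),
               tolerance = 1e-6)
})

test_that("PLSR prediction R2 collapses to zero under permuted responses", {
  r2s <- vapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 15), 40, 15)
    y <- sample(rnorm(40))
    m <- fit_plsr(X[1:25, ], y[1:25], max_components = 5)
    regression_metrics(y[26:40], predict(m, X[26:40, ]))$r2
  }, numeric(1))
  expect_lt(mean(r2s), 0.2)
})
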