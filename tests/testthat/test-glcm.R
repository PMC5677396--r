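test_that("quantization follows the min-max binning rule", {
  expect_equal(quantize_gray(matrix(c(0, 0.5, 1, 1), 2), 4),
               matrix(c(0L, 2L, 3L, 3L), 2))
  expect_equal(quantize_gray(matrix(c(0, 1), 1), 2), matrix(c(0L, 1L), 1))
  expect_equal(quantize_gray(matrix(5, 3, 3), 64), matrix(0L, 3, 3))
  expect_true(all(quantize_gray(matrix(rnorm(100), 10), 16) %in% 0:15))
})

test_that("checkerboard GLCM matches the hand-enumerated pair counts", {
  img <- matrix(c(0L, 1L, 1L, 0L), 2)
  P <- glcm(img, direction = 0, levels = 2)
  expect_equal(unname(P), matrix(c(0, 0.5, 0.5, 0), 2))
  st <- glcm_stats(P)
  expect_equal(unname(st["energy"]), 0.5)
  expect_equal(unname(st["contrast"]), 1)
  expect_equal(unname(st["homogeneity"]), 0.5)
  expect_equal(unname(st["entropy"]), log(2))
})

test_that("constant and striped images populate only diagonal cells", {
  P <- glcm(matrix(2L, 4, 4), direction = 45, levels = 4)
  expect_equal(unname(P[3, 3]), 1)
  st <- glcm_stats(P)
  expect_equal(unname(st), c(1, 0, 1, 0))

  stripes <- matrix(rep(0:3, each = 4), 4, 4, byrow = TRUE) # constant rows
  P0 <- glcm(stripes, direction = 0, levels = 4)
  expect_equal(sum(diag(P0)), 1)
})

test_that("uniform co-occurrence matrix attains the entropy/energy bounds", {
  L <- 8
  P <- matrix(1 / L^2, L, L)
  st <- glcm_stats(P)
  expect_equal(unname(st["energy"]), 1 / L^2)
  expect_equal(unname(st["entropy"]), 2 * log(L))
  # general bounds for random normalised symmetric P
  set.seed(4)
  for (i in 1:20) {
    M <- matrix(runif(L^2), L)
    M <- (M + t(M)); M <- M / sum(M)
    s <- glcm_stats(M)
    expect_lte(s[["energy"]], 1)
    expect_lte(s[["homogeneity"]], 1)
    expect_gte(s[["contrast"]], 0)
    expect_lte(s[["entropy"]], 2 * log(L) + 1e-12)
  }
  expect_error(glcm_stats(matrix(1, 2, 2)), "normalised")
})

test_that("symmetric GLCM is invariant to flipping the image along the offset", {
  set.seed(6)
  img <- quantize_gray(matrix(rnorm(64), 8), 8)
  P <- glcm(img, direction = 0, levels = 8)
  P_flip <- glcm(img[, 8:1], direction = 0, levels = 8)
  expect_equal(P, P_flip)
  expect_equal(P, t(P))
  expect_equal(sum(P), 1)
  expect_error(glcm(img[, 1, drop = FALSE], direction = 0, levels = 8),
               "smaller than")
})

test_that("direction averaging matches an explicit loop and isotropy holds", {
  set.seed(7)
  img_raw <- matrix(rnorm(50 * 50), 50)
  stack <- array(img_raw, c(50, 50, 1))
  attr(stack, "wavelengths") <- 1200
  feats <- texture_features(stack, 1200, glcm_config(levels = 16))
  img <- quantize_gray(img_raw, 16)
  by_dir <- vapply(c(0, 45, 90, 135), function(d) {
    glcm_stats(glcm(img, d, levels = 16))
  }, numeric(4))
  expect_equal(feats$contrast, mean(by_dir["contrast", ]))
  expect_equal(feats$energy, mean(by_dir["energy", ]))
  # white noise is isotropic: directional contrasts agree within sampling error
  expect_lt(diff(range(by_dir["contrast", ])) / mean(by_dir["contrast", ]), 0.1)
})

test_that("feature cardinality is 4 statistics per effective wavelength", {
  ds <- tiny_dataset(seed = 2)
  wl <- ds$wavelengths[c(3, 10, 17, 24, 28, 33, 38)]
  tbl <- texture_feature_table(ds, wl)
  expect_equal(ncol(tbl) - 2, 28) # 4 stats x 7 wavelengths
  expect_equal(nrow(tbl), nrow(ds$manifest))

  one <- texture_feature_table(ds, ds$wavelengths[5])
  expect_equal(ncol(one) - 2, 4)
  expect_error(texture_feature_table(ds, 2000), "does not match")
})

test_that("smoother fields score higher energy/homogeneity and lower contrast/entropy", {
  rough_cfg <- list(corr = 1.5)
  stats_for <- function(corr_len, seed) {
    f <- withr::with_seed(seed, soilhsi:::correlated_field(32, corr_len))
    img <- quantize_gray(f, 16)
    rowMeans(vapply(c(0, 45, 90, 135), function(d) {
      glcm_stats(glcm(img, d, levels = 16))
    }, numeric(4)))
  }
  rough <- vapply(1:20, function(s) stats_for(1.5, s), numeric(4))
  smooth <- vapply(1:20, function(s) stats_for(8, 1000 + s), numeric(4))
  expect_gt(median(smooth["energy", ]), median(rough["energy", ]))
  expect_gt(median(smooth["homogeneity", ]), median(rough["homogeneity", ]))
  expect_lt(median(smooth["contrast", ]), median(rough["contrast", ]))
  expect_lt(median(smooth["entropy", ]), median(rough["entropy", ]))
})
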