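test_that("soil types are a fixed three-class code/name bijection", {
  st <- soil_types()
  expect_identical(st$code, 1:3)
  expect_identical(soil_type_code(st$name), st$code)
  expect_identical(soil_type_name(st$code), st$name)
  expect_error(soil_type_code("loam"), "Unknown soil type")
})

test_that("config validation rejects degenerate parameters", {
  expect_error(synthetic_config(n_per_class = c(paddy = 2L, red = 5L, seashore_saline = 5L)),
               "at least 3")
  expect_error(synthetic_config(tn_range = list(paddy = c(0.5, 0.2),
                                                red = c(0.1, 0.2),
                                                seashore_saline = c(0.1, 0.2))),
               "tn_range")
  expect_error(synthetic_config(roi_size = 1L), "roi_size")
  expect_error(synthetic_config(spectral_noise_sd = -1), "non-negative")
})

test_that("noise-free spectrum is exactly baseline minus water trough at tn = 0", {
  cfg <- tiny_config()
  wl <- config_wavelengths(cfg)
  s <- generate_spectrum("red", tn = 0, cfg, noise_sd = 0)
  trough <- cfg$water_trough$depth * cfg$water_trough$depth_scale[["red"]] *
    exp(-0.5 * ((wl - (cfg$water_trough$center_nm + cfg$water_trough$center_offset[["red"]])) /
                  cfg$water_trough$width_nm)^2)
  expect_equal(as.numeric(s), cfg$baseline_offset[["red"]] - trough)
})

test_that("reflectance at the N-feature center decreases monotonically in TN", {
  cfg <- tiny_config()
  wl <- config_wavelengths(cfg)
  j <- which.min(abs(wl - cfg$n_feature$center_nm))
  s1 <- generate_spectrum("paddy", 0.10, cfg, noise_sd = 0)
  s2 <- generate_spectrum("paddy", 0.25, cfg, noise_sd = 0)
  expect_lt(s2[j], s1[j])
  expect_error(generate_spectrum("paddy", 1.5, cfg), "tn")
})

test_that("seashore-saline mean reflectance sits below paddy under defaults", {
  cfg <- synthetic_config()
  sal <- generate_spectrum("seashore_saline", 0.12, cfg, noise_sd = 0)
  pad <- generate_spectrum("paddy", 0.17, cfg, noise_sd = 0)
  expect_lt(mean(sal), mean(pad))
})

test_that("roi stacks are deterministic per seed and degenerate at zero texture sd", {
  cfg <- tiny_config()
  s <- generate_spectrum("paddy", 0.2, cfg, noise_sd = 0)
  a <- generate_roi_stack("paddy", s, cfg, seed = 42)
  b <- generate_roi_stack("paddy", s, cfg, seed = 42)
  expect_identical(a, b)

  cfg0 <- tiny_config(texture = list(
    sd = c(paddy = 0, red = 0, seashore_saline = 0),
    corr_length_px = c(paddy = 2, red = 3, seashore_saline = 7)
  ))
  flat <- generate_roi_stack("paddy", generate_spectrum("paddy", 0.2, cfg0, noise_sd = 0),
                             cfg0, seed = 1)
  expect_equal(diff(range(flat[, , 1])), 0)
  P <- glcm(quantize_gray(flat[, , 1], 8), direction = 0, levels = 8)
  expect_equal(unname(glcm_stats(P)[["energy"]]), 1)
})

test_that("short-range fields have higher GLCM contrast than long-range fields", {
  contrast_at <- function(corr_len, seed) {
    f <- withr::with_seed(seed, soilhsi:::correlated_field(32, corr_len))
    mean(vapply(c(0, 45, 90, 135), function(d) {
      glcm_stats(glcm(quantize_gray(f, 16), d, levels = 16))[["contrast"]]
    }, numeric(1)))
  }
  rough <- vapply(1:20, function(s) contrast_at(1, s), numeric(1))
  smooth <- vapply(1:20, function(s) contrast_at(10, 100 + s), numeric(1))
  expect_true(all(rough > smooth))
})

test_that("dataset generation matches the configured cohort and is seed-stable", {
  ds <- tiny_dataset(seed = 7)
  expect_equal(nrow(ds$manifest), 21)
  expect_identical(ds, tiny_dataset(seed = 7))

  counts <- table(ds$manifest$soil_type)
  expect_equal(unname(c(counts[c("paddy", "red", "seashore_saline")])), c(8, 7, 6))
  for (cl in soil_types()$name) {
    rng <- ds$config$tn_range[[cl]]
    tn <- ds$manifest$tn_percent[ds$manifest$soil_type == cl]
    expect_true(all(tn >= rng[1] & tn <= rng[2]))
  }

  tiny9 <- simulate_soil_dataset(
    synthetic_config(n_per_class = c(paddy = 3L, red = 3L, seashore_saline = 3L),
                     n_bands = 10L, roi_size = 8L), seed = 1)
  expect_equal(nrow(tiny9$manifest), 9)
})

test_that("full default cohort is 183 samples with TN inside 0.038-0.312", {
  ds <- simulate_soil_dataset(synthetic_config(), seed = 2)
  expect_equal(nrow(ds$manifest), 183)
  expect_true(all(ds$manifest$tn_percent >= 0.038 & ds$manifest$tn_percent <= 0.312))
})

test_that("stored spectra equal the per-band mean of the materialised ROI stack", {
  ds <- tiny_dataset(seed = 3)
  id <- "red_002"
  stk <- roi_stack(ds, id)
  expect_equal(as.numeric(mean_roi_spectrum(stk)),
               unname(spectra_matrix(ds$spectra)[id, ]),
               tolerance = 1e-12)
})
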