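#' Configuration for the synthetic soil hyperspectral generator
#'
#' Builds the parameter set for [simulate_soil_dataset()]. The defaults
#' emulate a cohort of 183 soil samples in three classes (84 paddy, 57 red,
#' 42 seashore-saline) measured over 200 bands on 975--1645 nm, with a water
#' absorption trough near 1400 nm, a nitrogen-sensitive organics feature near
#' 1000 nm, a class-dependent reflectance baseline (seashore-saline lowest),
#' per-class total-nitrogen ranges, and class-dependent spatial texture in a
#' 50 x 50 pixel region of interest.
#'
#' Reflectance is on the 0--100 (%) scale throughout.
#'
#' @param n_per_class Named integer vector of sample counts per class
#'   (`paddy`, `red`, `seashore_saline`); each must be >= 3 so a 2:1 split
#'   is possible.
#' @param n_bands Number of spectral bands.
#' @param wavelength_range_nm Length-2 numeric, inclusive band range in nm.
#' @param baseline_offset Named numeric, mean class baseline reflectance (%).
#' @param baseline_jitter_sd SD (%) of the per-sample additive baseline shift;
#'   this is the dial that makes the classes overlap spectrally.
#' @param slope_jitter_sd,curvature_jitter_sd SDs (%) of per-sample smooth
#'   linear and quadratic deviations across the band range. They mimic the
#'   smooth scatter/particle-size variation of real soil spectra, so that
#'   between-sample variance is spectrally correlated rather than dominated
#'   by independent band noise.
#' @param water_trough List with `center_nm`, `width_nm` (Gaussian sigma),
#'   `depth` (%, base trough depth), named `depth_scale` (per-class depth
#'   multiplier: soil types hold different moisture), `depth_jitter_sd`
#'   (relative SD of the per-sample depth multiplier), named `center_offset`
#'   (per-class shift of the trough position in nm: salinity and moisture
#'   state displace the water band, a spectral *shape* cue that survives the
#'   scale-invariant SNV transform) and `center_jitter_sd` (SD in nm of the
#'   per-sample trough position, the dial controlling how much the classes
#'   overlap spectrally).
#' @param n_feature List with `center_nm`, `width_nm` and named `absorptivity`
#'   (% reflectance drop per % TN, per class): the nitrogen absorption
#'   feature. Class-distinct absorptivities are what make local calibration
#'   models outperform a pooled general model.
#' @param tn_range Named list of length-2 numeric vectors, the per-class TN
#'   range (% of dry mass) that sample TN is drawn from uniformly.
#' @param texture List with named `sd` (% reflectance, spatial field SD) and
#'   `corr_length_px` (Gaussian smoothing sigma in pixels) per class, plus
#'   `corr_length_jitter_sd` (log-normal SD of a per-sample multiplier on the
#'   correlation length, giving within-class texture variability). Longer
#'   correlation lengths give smoother images (higher GLCM energy and
#'   homogeneity, lower contrast and entropy); paddy and red defaults are
#'   close together while seashore-saline is distinctly smoother.
#' @param spectral_noise_sd SD (%) of i.i.d. per-band noise on each sample's
#'   mean spectrum.
#' @param roi_size Side length (pixels) of the square region of interest.
#' @return A validated list of class `soil_synth_config`.
#' @seealso [simulate_soil_dataset()], [generate_spectrum()],
#'   [generate_roi_stack()]
#' @export
synthetic_config <- function(n_per_class = c(paddy = 84L, red = 57L, seashore_saline = 42L),
                             n_bands = 200L,
                             wavelength_range_nm = c(975, 1645),
                             baseline_offset = c(paddy = 45, red = 48, seashore_saline = 35),
                             baseline_jitter_sd = 4,
                             slope_jitter_sd = 2,
                             curvature_jitter_sd = 1,
                             water_trough = list(
                               center_nm = 1400, width_nm = 60, depth = 12,
                               depth_scale = c(paddy = 1.0, red = 0.85, seashore_saline = 1.2),
                               depth_jitter_sd = 0.1,
                               center_offset = c(paddy = -6, red = 0, seashore_saline = 8),
                               center_jitter_sd = 2.5
                             ),
                             n_feature = list(
                               center_nm = 1000, width_nm = 30,
                               absorptivity = c(paddy = 40, red = 50, seashore_saline = 65)
                             ),
                             tn_range = list(
                               paddy = c(0.088, 0.312),
                               red = c(0.056, 0.262),
                               seashore_saline = c(0.038, 0.205)
                             ),
                             texture = list(
                               sd = c(paddy = 2.0, red = 2.5, seashore_saline = 2.2),
                               corr_length_px = c(paddy = 2, red = 2.6, seashore_saline = 7),
                               corr_length_jitter_sd = 0.18
                             ),
                             spectral_noise_sd = 0.3,
                             roi_size = 50L) {
  classes <- soil_types()$name
  need_classes <- function(x, what) {
    if (!all(classes %in% names(x))) {
      abort(paste0("`", what, "` must be named for all classes: ",
                   paste(classes, collapse = ", ")))
    }
    x[classes]
  }
  n_per_class <- need_classes(n_per_class, "n_per_class")
  if (any(n_per_class < 3)) abort("Each class needs at least 3 samples (2:1 split).")
  if (n_bands < 2) abort("`n_bands` must be at least 2.")
  if (length(wavelength_range_nm) != 2 || diff(wavelength_range_nm) <= 0) {
    abort("`wavelength_range_nm` must be an increasing length-2 range.")
  }
  baseline_offset <- need_classes(baseline_offset, "baseline_offset")
  if (baseline_jitter_sd < 0 || spectral_noise_sd < 0 ||
      slope_jitter_sd < 0 || curvature_jitter_sd < 0) {
    abort("Noise standard deviations must be non-negative.")
  }
  if (water_trough$width_nm <= 0 || n_feature$width_nm <= 0) {
    abort("Feature widths must be positive.")
  }
  water_trough$depth_scale <- need_classes(
    water_trough$depth_scale %||% c(paddy = 1, red = 1, seashore_saline = 1),
    "water_trough$depth_scale")
  water_trough$depth_jitter_sd <- water_trough$depth_jitter_sd %||% 0
  if (water_trough$depth_jitter_sd < 0) abort("`depth_jitter_sd` must be non-negative.")
  water_trough$center_offset <- need_classes(
    water_trough$center_offset %||% c(paddy = 0, red = 0, seashore_saline = 0),
    "water_trough$center_offset")
  water_trough$center_jitter_sd <- water_trough$center_jitter_sd %||% 0
  if (water_trough$center_jitter_sd < 0) abort("`center_jitter_sd` must be non-negative.")
  n_feature$absorptivity <- need_classes(n_feature$absorptivity, "n_feature$absorptivity")
  tn_range <- tn_range[classes]
  ok_rng <- vapply(tn_range, function(r) {
    length(r) == 2 && r[1] < r[2] && r[1] >= 0 && r[2] <= 1
  }, logical(1))
  if (!all(ok_rng)) abort("Each `tn_range` must be an increasing range inside [0, 1] (% TN).")
  texture$sd <- need_classes(texture$sd, "texture$sd")
  texture$corr_length_px <- need_classes(texture$corr_length_px, "texture$corr_length_px")
  texture$corr_length_jitter_sd <- texture$corr_length_jitter_sd %||% 0
  if (any(texture$sd < 0)) abort("`texture$sd` must be non-negative.")
  if (any(texture$corr_length_px <= 0)) abort("`texture$corr_length_px` must be positive.")
  if (texture$corr_length_jitter_sd < 0) abort("`corr_length_jitter_sd` must be non-negative.")
  if (roi_size < 2) abort("`roi_size` must be at least 2 (co-occurrence needs pixel pairs).")

  n_per_class <- as.integer(n_per_class)
  names(n_per_class) <- classes
  structure(
    list(
      n_per_class = n_per_class,
      n_bands = as.integer(n_bands),
      wavelength_range_nm = as.numeric(wavelength_range_nm),
      baseline_offset = baseline_offset,
      baseline_jitter_sd = baseline_jitter_sd,
      slope_jitter_sd = slope_jitter_sd,
      curvature_jitter_sd = curvature_jitter_sd,
      water_trough = water_trough,
      n_feature = n_feature,
      tn_range = tn_range,
      texture = texture,
      spectral_noise_sd = spectral_noise_sd,
      roi_size = as.integer(roi_size)
    ),
    class = "soil_synth_config"
  )
}

#' Band-center wavelengths for a generator configuration
#'
#' @param config A [synthetic_config()].
#' @return Numeric vector (nm), length `config$n_bands`, evenly spaced over
#'   the inclusive wavelength range.
#' @export
config_wavelengths <- function(config) {
  seq(config$wavelength_range_nm[1], config$wavelength_range_nm[2],
      length.out = config$n_bands)
}

gaussian_band <- function(wl, center, width) {
  exp(-0.5 * ((wl - center) / width)^2)
}

#' Generate one synthetic mean reflectance spectrum
#'
#' A sample spectrum is built as class baseline (plus an optional per-sample
#' baseline shift), minus a Gaussian water trough at 1400 nm, minus a nitrogen
#' absorption term proportional to TN at the ~1000 nm organics feature, plus
#' i.i.d. per-band noise; the result is clipped to \[0, 100\] %.
#'
#' @param soil_type Soil-type name (see [soil_types()]).
#' @param tn Total nitrogen (% of dry mass) in \[0, 1\].
#' @param config A [synthetic_config()].
#' @param baseline_shift Additive baseline offset (%) for this sample
#'   (default 0; [simulate_soil_dataset()] draws it from
#'   `N(0, baseline_jitter_sd^2)`).
#' @param trough_scale Per-sample multiplier on the class water-trough depth
#'   (default 1; [simulate_soil_dataset()] draws it from
#'   `N(1, depth_jitter_sd^2)`).
#' @param slope,curvature Per-sample smooth deviation amplitudes (%) over the
#'   band range: the linear term runs over `u` in `[-1, 1]` and the
#'   quadratic over `u^2 - 1/3` (both zero-mean across bands; default 0).
#' @param center_shift Per-sample displacement (nm) of the water-trough
#'   position (default 0; [simulate_soil_dataset()] draws it from
#'   `N(0, center_jitter_sd^2)`).
#' @param noise_sd SD of the i.i.d. band noise; set 0 for a deterministic
#'   spectrum. Defaults to `config$spectral_noise_sd`.
#' @return Numeric reflectance vector (%) of length `config$n_bands`, with
#'   the band wavelengths in attribute `"wavelengths"`.
#' @examples
#' cfg <- synthetic_config()
#' s <- generate_spectrum("paddy", tn = 0.17, cfg, noise_sd = 0)
#' plot(attr(s, "wavelengths"), s, type = "l", xlab = "nm", ylab = "R (%)")
#' @export
generate_spectrum <- function(soil_type, tn, config,
                              baseline_shift = 0,
                              trough_scale = 1,
                              slope = 0, curvature = 0,
                              center_shift = 0,
                              noise_sd = config$spectral_noise_sd) {
  stopifnot(inherits(config, "soil_synth_config"))
  soil_type <- match.arg(soil_type, soil_types()$name)
  if (!is.numeric(tn) || length(tn) != 1 || is.na(tn) || tn < 0 || tn > 1) {
    abort("`tn` must be a single value in [0, 1] (% of dry mass).")
  }
  wl <- config_wavelengths(config)
  trough_center <- config$water_trough$center_nm +
    config$water_trough$center_offset[[soil_type]] + center_shift
  trough <- config$water_trough$depth *
    config$water_trough$depth_scale[[soil_type]] * trough_scale *
    gaussian_band(wl, trough_center, config$water_trough$width_nm)
  nterm <- tn * config$n_feature$absorptivity[[soil_type]] *
    gaussian_band(wl, config$n_feature$center_nm, config$n_feature$width_nm)
  u <- 2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1
  smooth_dev <- slope * u + curvature * (u^2 - 1 / 3)
  s <- config$baseline_offset[[soil_type]] + baseline_shift + smooth_dev -
    trough - nterm
  if (noise_sd > 0) s <- s + rnorm(length(wl), sd = noise_sd)
  s <- pmin(pmax(s, 0), 100)
  attr(s, "wavelengths") <- wl
  s
}

# circular separable Gaussian smoothing; sigma in pixels
smooth_gaussian_circular <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  n <- nrow(mat)
  m <- ncol(mat)
  conv1 <- function(v, k, r) {
    nn <- length(v)
    out <- numeric(nn)
    for (j in seq_along(k)) {
      out <- out + k[j] * v[((seq_len(nn) - 1 + j - r - 1) %% nn) + 1]
    }
    out
  }
  mat <- apply(mat, 2, conv1, k = k, r = r)
  t(apply(t(mat), 2, conv1, k = k, r = r))
}

# zero-mean, unit-SD spatially correlated field (smoothed white noise)
correlated_field <- function(n, corr_length_px) {
  f <- smooth_gaussian_circular(matrix(rnorm(n * n), n, n), corr_length_px)
  f <- f - mean(f)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

#' Generate a region-of-interest image stack for one sample
#'
#' One spatially correlated Gaussian field is shared across all bands (surface
#' roughness is wavelength-coherent) and scaled in proportion to each band's
#' reflectance: band image `b` is
#' `base[b] + field * sd_class * base[b] / mean(base)`, clipped to
#' \[0, 100\] %. The field is smoothed white noise with class-specific
#' correlation length, normalised to unit SD, so `sd_class` is the realised
#' spatial SD at a band of average reflectance.
#'
#' @param soil_type Soil-type name.
#' @param base_spectrum Numeric reflectance vector (%), one value per band.
#' @param config A [synthetic_config()].
#' @param seed Optional integer; when given, the spatial field is drawn from
#'   a local RNG stream so the stack is reproducible independently of the
#'   surrounding RNG state.
#' @param field Optional pre-drawn unit-SD field matrix (used internally when
#'   a dataset stores its fields compactly).
#' @param bands Optional integer indices: materialise only these bands.
#' @return Array `roi_size x roi_size x length(bands)` of reflectance (%),
#'   with attribute `"wavelengths"` when `base_spectrum` carries one.
#' @examples
#' cfg <- synthetic_config(roi_size = 16L, n_bands = 20L)
#' s <- generate_spectrum("red", 0.15, cfg, noise_sd = 0)
#' stk <- generate_roi_stack("red", s, cfg, seed = 1)
#' dim(stk)
#' @export
generate_roi_stack <- function(soil_type, base_spectrum, config,
                               seed = NULL, field = NULL, bands = NULL) {
  stopifnot(inherits(config, "soil_synth_config"))
  soil_type <- match.arg(soil_type, soil_types()$name)
  if (length(base_spectrum) != config$n_bands) {
    abort("`base_spectrum` length must equal `config$n_bands`.")
  }
  if (config$roi_size < 2) abort("ROI must be at least 2 x 2 pixels.")
  n <- config$roi_size
  if (is.null(field)) {
    if (!is.null(seed)) {
      field <- withr::with_seed(seed, correlated_field(n, config$texture$corr_length_px[[soil_type]]))
    } else {
      field <- correlated_field(n, config$texture$corr_length_px[[soil_type]])
    }
  }
  if (is.null(bands)) bands <- seq_len(config$n_bands)
  sd_class <- config$texture$sd[[soil_type]]
  mb <- mean(base_spectrum)
  scale_b <- if (mb > 0) base_spectrum[bands] / mb else rep(1, length(bands))
  stack <- array(0, dim = c(n, n, length(bands)))
  for (j in seq_along(bands)) {
    stack[, , j] <- pmin(pmax(base_spectrum[bands[j]] + field * sd_class * scale_b[j], 0), 100)
  }
  wl <- attr(base_spectrum, "wavelengths")
  if (!is.null(wl)) attr(stack, "wavelengths") <- wl[bands]
  stack
}

#' Simulate a full synthetic soil hyperspectral dataset
#'
#' Draws per-sample total nitrogen uniformly within each class's range, builds
#' each sample's mean reflectance spectrum and its spatial texture field, and
#' returns everything the downstream pipeline needs: a manifest, the
#' samples x bands spectra table, and per-sample texture fields from which
#' ROI image stacks are materialised on demand (see [roi_stack()]).
#'
#' The mean-ROI spectrum of a sample equals its base spectrum plus the field
#' mean (zero by construction) times the band scaling, so the stored spectra
#' table is exactly the per-band mean over the ROI stack.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `soil_hsi_dataset`: a list with `manifest`
#'   (tibble: `sample_id`, `soil_type`, `tn_percent`), `spectra` (wide tibble,
#'   see [spectra_table()] format), `fields` (named list of unit-SD texture
#'   matrices), `base_spectra` (matrix), `wavelengths`, `config`, `seed`.
#' @examples
#' ds <- simulate_soil_dataset(synthetic_config(
#'   n_per_class = c(paddy = 6L, red = 5L, seashore_saline = 4L),
#'   n_bands = 30L, roi_size = 12L), seed = 1)
#' ds$manifest
#' @export
simulate_soil_dataset <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "soil_synth_config"))
  withr::with_seed(as.integer(seed), {
    classes <- soil_types()$name
    wl <- config_wavelengths(config)
    rows <- list()
    fields <- list()
    base_spectra <- list()
    for (cl in classes) {
      n_cl <- config$n_per_class[[cl]]
      for (i in seq_len(n_cl)) {
        id <- sprintf("%s_%03d", cl, i)
        tn <- runif(1, config$tn_range[[cl]][1], config$tn_range[[cl]][2])
        shift <- rnorm(1, sd = config$baseline_jitter_sd)
        tscale <- rnorm(1, mean = 1, sd = config$water_trough$depth_jitter_sd)
        slope <- rnorm(1, sd = config$slope_jitter_sd)
        curv <- rnorm(1, sd = config$curvature_jitter_sd)
        cshift <- rnorm(1, sd = config$water_trough$center_jitter_sd)
        spec <- generate_spectrum(cl, tn, config, baseline_shift = shift,
                                  trough_scale = tscale,
                                  slope = slope, curvature = curv,
                                  center_shift = cshift)
        corr_mult <- exp(rnorm(1, sd = config$texture$corr_length_jitter_sd))
        field <- correlated_field(config$roi_size,
                                  config$texture$corr_length_px[[cl]] * corr_mult)
        rows[[id]] <- tibble(sample_id = id, soil_type = cl, tn_percent = tn)
        fields[[id]] <- field
        base_spectra[[id]] <- as.numeric(spec)
      }
    }
    manifest <- dplyr::bind_rows(rows)
    X <- do.call(rbind, base_spectra)
    spectra <- dplyr::bind_cols(
      manifest,
      as_tibble(`colnames<-`(X, wavelength_colnames(wl)))
    )
    structure(
      list(
        manifest = manifest,
        spectra = spectra,
        fields = fields,
        base_spectra = X,
        wavelengths = wl,
        config = config,
        seed = as.integer(seed)
      ),
      class = "soil_hsi_dataset"
    )
  })
}

#' @export
print.soil_hsi_dataset <- function(x, ...) {
  counts <- table(x$manifest$soil_type)
  cat("<soil_hsi_dataset> ", nrow(x$manifest), " samples (",
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
      "), ", length(x$wavelengths), " bands ",
      sprintf("%.0f-%.0f nm", min(x$wavelengths), max(x$wavelengths)),
      ", ROI ", x$config$roi_size, "x", x$config$roi_size,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Materialise the ROI image stack for one dataset sample
#'
#' @param dataset A [simulate_soil_dataset()] result.
#' @param sample_id Sample identifier from the manifest.
#' @param bands Optional band indices to materialise (default all).
#' @return Array `roi_size x roi_size x n_bands` of reflectance (%).
#' @export
roi_stack <- function(dataset, sample_id, bands = NULL) {
  stopifnot(inherits(dataset, "soil_hsi_dataset"))
  if (!sample_id %in% dataset$manifest$sample_id) {
    abort(paste0("Unknown sample_id: ", sample_id))
  }
  cl <- dataset$manifest$soil_type[match(sample_id, dataset$manifest$sample_id)]
  base <- dataset$base_spectra[sample_id, ]
  attr(base, "wavelengths") <- dataset$wavelengths
  generate_roi_stack(cl, base, dataset$config,
                     field = dataset$fields[[sample_id]], bands = bands)
}

#' @export
tidy.soil_hsi_dataset <- function(x, ...) x$manifest
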