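#' GLCM configuration
#'
#' @param levels Number of gray levels `L` after quantization (default 64).
#' @param distance Pixel offset distance (default, and conventionally, 1).
#' @param directions Offset angles in degrees; the standard four.
#' @param symmetric Accumulate both pair orderings (default `TRUE`).
#' @param normalize Normalise counts to joint probabilities (default `TRUE`).
#' @return List of class `glcm_config`.
#' @export
glcm_config <- function(levels = 64L, distance = 1L,
                        directions = c(0, 45, 90, 135),
                        symmetric = TRUE, normalize = TRUE) {
  if (levels < 2) abort("`levels` must be >= 2.")
  if (distance < 1) abort("`distance` must be >= 1.")
  if (!all(directions %in% c(0, 45, 90, 135))) {
    abort("`directions` must be among 0, 45, 90, 135 degrees.")
  }
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 directions = directions, symmetric = symmetric,
                 normalize = normalize),
            class = "glcm_config")
}

#' Quantize an image to integer gray levels
#'
#' Linear min--max scaling of the image onto `[0, L - 1]`:
#' `floor((v - min) / (max - min) * L)` with the maximum clamped to `L - 1`.
#' A constant image maps to level 0.
#'
#' @param image Numeric matrix.
#' @param levels Number of gray levels `L`.
#' @return Integer matrix with values in `[0, L - 1]`.
#' @examples
#' quantize_gray(matrix(c(0, 0.5, 1, 1), 2), levels = 4)
#' @export
quantize_gray <- function(image, levels = 64L) {
  if (!all(is.finite(image))) abort("`image` must be finite.")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    return(matrix(0L, nrow(image), ncol(image)))
  }
  q <- floor((image - rng[1]) / (rng[2] - rng[1]) * levels)
  mode(q) <- "integer"
  pmin(q, as.integer(levels) - 1L)
}

# nearest-band lookup; errors when the requested wavelength is farther from
# every band center than half the band spacing
match_wavelengths <- function(target_nm, band_nm) {
  half_step <- if (length(band_nm) > 1) min(diff(sort(band_nm))) / 2 else 0.5
  vapply(target_nm, function(w) {
    j <- which.min(abs(band_nm - w))
    if (abs(band_nm[j] - w) > half_step + 1e-9) {
      abort(sprintf("Wavelength %.2f nm does not match any band.", w))
    }
    j
  }, integer(1))
}

# direction -> (row, col) offset in image coordinates
# 0 = (0,+1), 45 = (-1,+1), 90 = (-1,0), 135 = (-1,-1)
direction_offset <- function(direction, distance = 1L) {
  o <- switch(as.character(direction),
    "0" = c(0L, 1L),
    "45" = c(-1L, 1L),
    "90" = c(-1L, 0L),
    "135" = c(-1L, -1L),
    abort("`direction` must be 0, 45, 90 or 135 degrees.")
  )
  o * as.integer(distance)
}

#' Gray-level co-occurrence matrix
#'
#' Counts how often gray-level pairs co-occur at the stated offset. With
#' `symmetric = TRUE` both orderings of each pair are accumulated; with
#' `normalize = TRUE` counts are scaled to joint probabilities summing to 1.
#'
#' @param image Integer matrix of quantized levels in `[0, L - 1]` (see
#'   [quantize_gray()]).
#' @param direction Offset angle: 0, 45, 90 or 135 degrees.
#' @param distance Offset length in pixels.
#' @param levels Number of gray levels `L`.
#' @param symmetric,normalize See [glcm_config()].
#' @return `L x L` matrix `p(i, j)` (levels indexed 0..L-1 on both axes).
#' @examples
#' glcm(matrix(c(0L, 1L, 1L, 0L), 2), direction = 0, levels = 2)
#' @export
glcm <- function(image, direction, distance = 1L, levels = 64L,
                 symmetric = TRUE, normalize = TRUE) {
  off <- direction_offset(direction, distance)
  nr <- nrow(image)
  nc <- ncol(image)
  rows <- seq_len(nr)
  cols <- seq_len(nc)
  r2 <- rows + off[1]
  c2 <- cols + off[2]
  rkeep <- rows[r2 >= 1 & r2 <= nr]
  ckeep <- cols[c2 >= 1 & c2 <= nc]
  if (!length(rkeep) || !length(ckeep)) {
    abort("Image is smaller than the co-occurrence offset.")
  }
  i <- image[rkeep, ckeep, drop = FALSE]
  j <- image[rkeep + off[1], ckeep + off[2], drop = FALSE]
  L <- as.integer(levels)
  if (min(i, j) < 0 || max(i, j) >= L) {
    abort("Quantized levels outside [0, levels - 1].")
  }
  counts <- tabulate(as.vector(i) * L + as.vector(j) + 1L, nbins = L * L)
  P <- matrix(counts, L, L, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  if (normalize) P <- P / sum(P)
  dimnames(P) <- list(0:(L - 1), 0:(L - 1))
  P
}

#' Texture statistics of a normalised GLCM
#'
#' `energy = sum p^2`; `contrast = sum (i - j)^2 p`;
#' `homogeneity = sum p / (1 + (i - j)^2)` (inverse difference moment);
#' `entropy = -sum p log p` in natural log, with `0 log 0 = 0`.
#'
#' @param P Normalised `L x L` co-occurrence matrix (entries sum to 1).
#' @return Named numeric vector `energy`, `contrast`, `homogeneity`,
#'   `entropy`.
#' @examples
#' P <- glcm(matrix(c(0L, 1L, 1L, 0L), 2), direction = 0, levels = 2)
#' glcm_stats(P) # energy 0.5, contrast 1, homogeneity 0.5, entropy log(2)
#' @export
glcm_stats <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) abort("`P` must be normalised (sum to 1).")
  if (any(P < 0)) abort("`P` must be non-negative.")
  L <- nrow(P)
  d2 <- outer(seq_len(L), seq_len(L), function(i, j) (i - j)^2)
  pos <- P > 0
  c(
    energy = sum(P^2),
    contrast = sum(d2 * P),
    homogeneity = sum(P / (1 + d2)),
    entropy = -sum(P[pos] * log(P[pos]))
  )
}

#' Direction-averaged texture features at selected wavelengths
#'
#' For each requested wavelength: quantize the band image, build the GLCM at
#' each of the four directions, compute the four statistics per direction,
#' and average them over directions. With `k` wavelengths this yields
#' `4 * k` features per sample.
#'
#' @param stack ROI image array `height x width x bands` carrying a
#'   `"wavelengths"` attribute (as from [roi_stack()] or [crop_roi()]), or
#'   with `wavelengths` supplied explicitly.
#' @param effective_wavelengths_nm Wavelengths (nm) to extract; must match
#'   stack band wavelengths to the nearest 1e-6 nm.
#' @param config A [glcm_config()].
#' @param wavelengths Band wavelengths when the stack carries no attribute.
#' @return Tibble with one row per effective wavelength: `wavelength_nm`,
#'   `energy`, `contrast`, `homogeneity`, `entropy`.
#' @export
texture_features <- function(stack, effective_wavelengths_nm,
                             config = glcm_config(), wavelengths = NULL) {
  stopifnot(inherits(config, "glcm_config"))
  wl <- attr(stack, "wavelengths") %||% wavelengths
  if (is.null(wl)) abort("Stack has no wavelengths; pass `wavelengths`.")
  d <- dim(stack)
  if (length(wl) != d[3]) abort("`wavelengths` length must match stack bands.")
  idx <- match_wavelengths(effective_wavelengths_nm, wl)
  purrr::map_dfr(seq_along(idx), function(i) {
    img <- quantize_gray(stack[, , idx[i]], config$levels)
    stats_by_dir <- vapply(config$directions, function(dir) {
      glcm_stats(glcm(img, dir, config$distance, config$levels,
                      config$symmetric, config$normalize))
    }, numeric(4))
    avg <- rowMeans(stats_by_dir)
    tibble(wavelength_nm = effective_wavelengths_nm[i],
           energy = avg[["energy"]], contrast = avg[["contrast"]],
           homogeneity = avg[["homogeneity"]], entropy = avg[["entropy"]])
  })
}

#' Per-sample texture feature table for a dataset
#'
#' Materialises each sample's ROI images at the effective wavelengths only
#' and flattens the direction-averaged statistics into one wide row per
#' sample with columns `<stat>_<wavelength>`.
#'
#' @param dataset A [simulate_soil_dataset()] result.
#' @param effective_wavelengths_nm Wavelengths (nm) at which to extract
#'   texture (normally an SPA selection).
#' @param config A [glcm_config()].
#' @return Tibble: `sample_id`, `soil_type`, then `4 * k` feature columns.
#' @export
texture_feature_table <- function(dataset, effective_wavelengths_nm,
                                  config = glcm_config()) {
  stopifnot(inherits(dataset, "soil_hsi_dataset"))
  bands <- match_wavelengths(effective_wavelengths_nm, dataset$wavelengths)
  purrr::map_dfr(dataset$manifest$sample_id, function(id) {
    stk <- roi_stack(dataset, id, bands = bands)
    feats <- texture_features(stk, effective_wavelengths_nm, config,
                              wavelengths = dataset$wavelengths[bands])
    wide <- tidyr::pivot_wider(
      tidyr::pivot_longer(feats, -"wavelength_nm",
                          names_to = "stat", values_to = "value"),
      names_from = c("stat", "wavelength_nm"), values_from = "value",
      names_glue = "{stat}_{sprintf('%.2f', wavelength_nm)}"
    )
    dplyr::bind_cols(
      dataset$manifest[match(id, dataset$manifest$sample_id),
                       c("sample_id", "soil_type")],
      wide
    )
  })
}
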