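#' Spectra tables
#'
#' The pipeline's central tabular format is a wide tibble with one row per
#' sample: metadata columns `sample_id`, `soil_type`, `tn_percent`, followed
#' by one reflectance column per band named `wl_<nm>` (e.g. `wl_975.00`).
#' These helpers move between that table and the bare numeric matrix.
#'
#' @param tbl A spectra tibble.
#' @param wavelengths Numeric wavelengths (nm).
#' @name spectra_format
NULL

wavelength_colnames <- function(wavelengths) {
  sprintf("wl_%.2f", wavelengths)
}

#' @describeIn spectra_format Wavelengths parsed from the `wl_` column names.
#' @export
spectra_wavelengths <- function(tbl) {
  nm <- grep("^wl_", names(tbl), value = TRUE)
  if (!length(nm)) abort("No `wl_` spectral columns found.")
  as.numeric(sub("^wl_", "", nm))
}

#' @describeIn spectra_format The `n_samples x n_bands` reflectance matrix
#'   (rownames = sample ids).
#' @export
spectra_matrix <- function(tbl) {
  nm <- grep("^wl_", names(tbl), value = TRUE)
  if (!length(nm)) abort("No `wl_` spectral columns found.")
  X <- as.matrix(tbl[nm])
  rownames(X) <- tbl$sample_id
  X
}

# replace the spectral block of a spectra tibble
set_spectra_matrix <- function(tbl, X) {
  nm <- grep("^wl_", names(tbl), value = TRUE)
  stopifnot(ncol(X) == length(nm), nrow(X) == nrow(tbl))
  tbl[nm] <- as.data.frame(X)
  tbl
}

#' Extract the spectra table from a dataset
#'
#' @param dataset A [simulate_soil_dataset()] result.
#' @return Wide spectra tibble (see [spectra_format]).
#' @export
spectra_table <- function(dataset) {
  stopifnot(inherits(dataset, "soil_hsi_dataset"))
  dataset$spectra
}

#' Mean ROI spectrum
#'
#' Per-band arithmetic mean over all pixels of a region-of-interest image
#' stack: each sample's many pixel spectra are averaged into one.
#'
#' @param stack Array `height x width x bands` (e.g. from [crop_roi()] or
#'   [roi_stack()]).
#' @return Numeric vector, one mean reflectance per band; the stack's
#'   `"wavelengths"` attribute is carried over when present.
#' @export
mean_roi_spectrum <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) != 3 || prod(d) == 0) {
    abort("`stack` must be a non-empty height x width x bands array.")
  }
  out <- colMeans(matrix(stack, nrow = d[1] * d[2], ncol = d[3]))
  attr(out, "wavelengths") <- attr(stack, "wavelengths")
  out
}

#' Trim a spectra table to a wavelength window
#'
#' Keeps bands with `lo_nm <= wavelength <= hi_nm` (closed interval), the
#' usual step that discards the noisy ends of the detector range.
#'
#' @param tbl Spectra tibble.
#' @param lo_nm,hi_nm Window bounds in nm (`lo_nm < hi_nm`).
#' @return Spectra tibble restricted to the window.
#' @export
trim_bands <- function(tbl, lo_nm, hi_nm) {
  if (lo_nm >= hi_nm) abort("`lo_nm` must be below `hi_nm`.")
  wl <- spectra_wavelengths(tbl)
  keep <- wl >= lo_nm & wl <= hi_nm
  if (!any(keep)) abort("No bands remain inside the requested window.")
  drop_cols <- wavelength_colnames(wl)[!keep]
  tbl[setdiff(names(tbl), drop_cols)]
}

#' Standard normal variate (SNV) transform
#'
#' Row-wise centering and scaling of each spectrum:
#' `(x - mean(x)) / sd(x)` with the sample SD (n - 1). Removes additive
#' baseline offsets and multiplicative scatter per spectrum; applying it
#' twice is a no-op.
#'
#' @param tbl Spectra tibble (or bare matrix).
#' @return Object of the same shape with each spectrum at mean 0, SD 1.
#' @export
snv <- function(tbl) {
  if (is.matrix(tbl)) {
    sds <- apply(tbl, 1, sd)
    if (any(sds == 0)) {
      abort(paste0("SNV undefined for constant spectra (rows ",
                   paste(which(sds == 0), collapse = ", "), ")."))
    }
    return((tbl - rowMeans(tbl)) / sds)
  }
  X <- spectra_matrix(tbl)
  sds <- apply(X, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("SNV undefined for constant spectra: ",
                 paste(rownames(X)[sds == 0], collapse = ", ")))
  }
  X <- (X - rowMeans(X)) / sds
  set_spectra_matrix(tbl, X)
}

#' Column z-score normalisation fitted on the calibration set
#'
#' Column means and sample SDs are estimated on the calibration rows only and
#' applied to both sets, so no information flows from the prediction set into
#' the preprocessing.
#'
#' @param calibration Calibration spectra tibble (or matrix).
#' @param prediction Optional prediction spectra tibble (or matrix) scaled
#'   with the calibration statistics.
#' @return List with `calibration`, `prediction` (or `NULL`) and `state`
#'   (list of `center` and `scale` per band).
#' @export
zscore_fit_apply <- function(calibration, prediction = NULL) {
  is_mat <- is.matrix(calibration)
  Xc <- if (is_mat) calibration else spectra_matrix(calibration)
  center <- colMeans(Xc)
  scale <- apply(Xc, 2, sd)
  if (any(scale == 0)) {
    bad <- colnames(Xc)[scale == 0]
    abort(paste0("Zero-variance band(s) in the calibration set: ",
                 paste(bad, collapse = ", ")))
  }
  apply_state <- function(x) sweep(sweep(x, 2, center), 2, scale, "/")
  out_cal <- if (is_mat) apply_state(Xc) else set_spectra_matrix(calibration, apply_state(Xc))
  out_pred <- NULL
  if (!is.null(prediction)) {
    Xp <- if (is.matrix(prediction)) prediction else spectra_matrix(prediction)
    out_pred <- if (is.matrix(prediction)) apply_state(Xp) else set_spectra_matrix(prediction, apply_state(Xp))
  }
  list(calibration = out_cal, prediction = out_pred,
       state = list(center = center, scale = scale))
}

#' Preprocess calibration/prediction spectra (SNV then z-score)
#'
#' The standard preprocessing chain: SNV across each spectrum first, then
#' column z-scoring with statistics fitted on the calibration set. The order
#' matters and is fixed here.
#'
#' @inheritParams zscore_fit_apply
#' @return As [zscore_fit_apply()].
#' @export
preprocess_spectra <- function(calibration, prediction = NULL) {
  zscore_fit_apply(snv(calibration),
                   if (is.null(prediction)) NULL else snv(prediction))
}
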