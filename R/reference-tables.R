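#' Published reference statistics for soil total nitrogen
#'
#' The printed summary statistics of the Kjeldahl TN reference values for a
#' published 183-sample soil cohort: per-soil-type (local) and pooled (general)
#' calibration/prediction sets from a stratified 2:1 split. Used as inputs
#' for consistency checks (see [check_rpd_consistency()]) and to set the
#' synthetic generator's per-class TN ranges.
#'
#' @return Tibble: `property` (soil type or `"general"`), `set`, `n`,
#'   `tn_min`, `tn_max`, `tn_mean`, `tn_sd` (all TN columns in % dry mass).
#' @export
tn_reference_statistics <- function() {
  tibble(
    property = rep(c("paddy", "red", "seashore_saline", "general"), each = 2),
    set = rep(c("calibration", "prediction"), 4),
    n = c(56L, 28L, 38L, 19L, 28L, 14L, 122L, 61L),
    tn_min = c(0.088, 0.124, 0.056, 0.102, 0.038, 0.055, 0.038, 0.042),
    tn_max = c(0.312, 0.255, 0.262, 0.215, 0.205, 0.178, 0.312, 0.250),
    tn_mean = c(0.170, 0.174, 0.151, 0.179, 0.131, 0.133, 0.160, 0.156),
    tn_sd = c(0.036, 0.042, 0.041, 0.030, 0.031, 0.030, 0.041, 0.037)
  )
}

#' Published TN prediction results (local vs general PLSR)
#'
#' The printed prediction-set performance of the PLSR models for soil TN:
#' per soil type (local models) and pooled (general models), each fitted on
#' the full 200-band spectrum and on the SPA effective wavelengths.
#'
#' @return Tibble: `property`, `n`, `input` (`"full_spectrum"` / `"ew"`),
#'   `n_vars`, `rmsep`, `r2`, `rpd`.
#' @export
tn_reference_predictions <- function() {
  tibble(
    property = rep(c("paddy", "red", "seashore_saline", "general"), each = 2),
    n = rep(c(28L, 19L, 14L, 61L), each = 2),
    input = rep(c("full_spectrum", "ew"), 4),
    n_vars = c(200L, 12L, 200L, 10L, 200L, 10L, 200L, 14L),
    rmsep = c(0.0166, 0.0155, 0.0129, 0.0136, 0.0118, 0.0125, 0.0176, 0.0179),
    r2 = c(0.83, 0.85, 0.80, 0.77, 0.83, 0.81, 0.76, 0.74),
    rpd = c(2.5, 2.7, 2.3, 2.2, 2.5, 2.4, 2.1, 2.1)
  )
}

#' Check the RPD identity across the published TN tables
#'
#' Recomputes `RPD = SD(prediction-set TN) / RMSEP` for every published
#' model from the printed prediction-set SDs and RMSEPs, rounds to one
#' decimal, and compares with the printed RPD.
#'
#' @return Tibble with one row per model: `property`, `input`, `tn_sd`,
#'   `rmsep`, `rpd_printed`, `rpd_recomputed` (1 dp), `consistent`.
#' @examples
#' all(check_rpd_consistency()$consistent)
#' @export
check_rpd_consistency <- function() {
  sds <- dplyr::filter(tn_reference_statistics(), .data$set == "prediction")
  tn_reference_predictions() %>%
    dplyr::left_join(sds[c("property", "tn_sd")], by = "property") %>%
    dplyr::mutate(
      rpd_printed = .data$rpd,
      rpd_recomputed = round(.data$tn_sd / .data$rmsep, 1),
      consistent = .data$rpd_recomputed == .data$rpd_printed
    ) %>%
    dplyr::select("property", "input", "tn_sd", "rmsep",
                  "rpd_printed", "rpd_recomputed", "consistent")
}
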