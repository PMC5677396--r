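Package: soilhsi
Title: Hyperspectral Imaging Analysis of Soil Types and Total Nitrogen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for near-infrared hyperspectral imaging analysis of soil:
    white/dark reflectance correction and ENVI cube input/output, region-of-
    interest mean-spectrum extraction, standard normal variate and z-score
    preprocessing, effective-wavelength selection by the successive
    projections algorithm (SPA) with an F-test subset-size criterion,
    gray-level co-occurrence matrix (GLCM) texture features at the effective
    wavelengths, RBF support vector machine soil-type classification from
    spectral, textural and fused feature sets, and local (per-soil-type)
    versus general partial least squares regression (SIMPLS) calibration of
    soil total nitrogen with RMSEP, R-squared and RPD evaluation. Ships a
    synthetic hyperspectral soil-sample generator so the full pipeline runs
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    e1071,
    MASS
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
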