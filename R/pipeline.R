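#' Soil-type classification experiment
#'
#' End-to-end classification run: stratified 2:1 split, SNV + z-score
#' preprocessing (statistics from the calibration set), SPA effective-
#' wavelength selection with the soil-type category codes 1/2/3 as the
#' response, GLCM texture extraction at the effective wavelengths, and four
#' RBF-SVM models — full spectrum, effective wavelengths, texture, and fused
#' effective wavelengths + texture.
#'
#' @param dataset A [simulate_soil_dataset()] result (or any object with the
#'   same manifest/spectra/ROI accessors).
#' @param seed Master seed; the split uses it directly and the SVM CV folds
#'   use `seed + 100`.
#' @param spa_alpha,spa_max_vars SPA F-test level and subset-size ceiling.
#' @param glcm A [glcm_config()].
#' @param svm An [svm_config()]; its fold seed is overridden by the master
#'   seed fan-out.
#' @param inputs Which feature sets to model.
#' @return Object of class `classification_experiment`: `summary` tibble
#'   (one row per input set, set and soil type plus totals), `reports`
#'   (named list of [fit_svm()] results), `spa`, `texture`, `split`, `seed`.
#' @export
run_classification_experiment <- function(dataset, seed = 1L,
                                          spa_alpha = 0.25, spa_max_vars = 20L,
                                          glcm = glcm_config(),
                                          svm = svm_config(),
                                          inputs = c("full_spectrum",
                                                     "effective_wavelengths",
                                                     "texture", "fused")) {
  inputs <- match.arg(inputs, several.ok = TRUE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Classification stage `", what, "` failed: ", conditionMessage(e)))
    })
  }
  spectra <- stage("spectra", spectra_table(dataset))
  split <- stage("split", stratified_split(dataset$manifest, seed = seed))
  cal <- spectra[match(split_ids(split, "calibration"), spectra$sample_id), ]
  pred <- spectra[match(split_ids(split, "prediction"), spectra$sample_id), ]
  pp <- stage("preprocess", preprocess_spectra(cal, pred))
  spa <- stage("spa", select_effective_wavelengths(
    pp$calibration, "class", max_vars = spa_max_vars, alpha = spa_alpha))
  ew_nm <- spa$selected_wavelengths_nm
  combined <- dplyr::bind_rows(pp$calibration, pp$prediction)
  combined <- combined[match(spectra$sample_id, combined$sample_id), ]
  texture_tbl <- NULL
  if (any(c("texture", "fused") %in% inputs)) {
    texture_tbl <- stage("texture", texture_feature_table(dataset, ew_nm, glcm))
  }
  svm$seed <- as.integer(seed) + 100L
  ew_cols <- wavelength_colnames(sort(ew_nm))
  meta <- c("sample_id", "soil_type")
  feature_sets <- list(
    full_spectrum = combined[c(meta, grep("^wl_", names(combined), value = TRUE))],
    effective_wavelengths = combined[c(meta, ew_cols)],
    texture = texture_tbl,
    fused = if (!is.null(texture_tbl)) {
      fuse_features(combined[c(meta, ew_cols)], texture_tbl)
    }
  )[inputs]
  reports <- purrr::imap(feature_sets, function(f, nm) {
    stage(paste0("svm_", nm), fit_svm(f, split, svm))
  })
  summary <- purrr::imap_dfr(reports, function(rep, nm) {
    purrr::map_dfr(c("calibration", "prediction"), function(set) {
      acc <- rep$accuracy[[set]]
      dplyr::bind_rows(
        dplyr::mutate(acc, input = nm, set = set, .before = 1),
        tibble(input = nm, set = set, soil_type = "total",
               n = sum(acc$n), correct = sum(acc$correct),
               accuracy = rep$overall[[set]])
      )
    })
  })
  structure(
    list(summary = summary, reports = reports, spa = spa,
         texture = texture_tbl, split = split, seed = as.integer(seed)),
    class = "classification_experiment"
  )
}

#' @export
print.classification_experiment <- function(x, ...) {
  cat("<classification_experiment>\n")
  tot <- dplyr::filter(x$summary, .data$soil_type == "total")
  wide <- tidyr::pivot_wider(tot[c("input", "set", "accuracy")],
                             names_from = "set", values_from = "accuracy")
  print(dplyr::mutate(wide, dplyr::across(-"input", ~ round(100 * .x, 1))))
  invisible(x)
}

#' @export
tidy.classification_experiment <- function(x, ...) x$summary

#' @export
glance.classification_experiment <- function(x, ...) {
  tot <- dplyr::filter(x$summary, .data$soil_type == "total",
                       .data$set == "prediction")
  tidyr::pivot_wider(tot[c("input", "accuracy")],
                     names_from = "input", values_from = "accuracy",
                     names_prefix = "accuracy_")
}

# fan a master seed out to a stage-specific stream (kept under 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}

fit_tn_models <- function(cal_tbl, pred_tbl, spa_alpha, spa_max_vars,
                          plsr_max_components) {
  pp <- preprocess_spectra(cal_tbl, pred_tbl)
  Xc <- spectra_matrix(pp$calibration)
  Xp <- spectra_matrix(pp$prediction)
  y_cal <- cal_tbl$tn_percent
  y_pred <- pred_tbl$tn_percent
  spa <- select_effective_wavelengths(
    pp$calibration, "tn",
    max_vars = min(spa_max_vars, nrow(cal_tbl) - 2L, ncol(Xc)),
    alpha = spa_alpha)
  sel <- sort(spa$selected_indices)
  fits <- list(
    full_spectrum = list(X_cal = Xc, X_pred = Xp, n_vars = ncol(Xc)),
    effective_wavelengths = list(X_cal = Xc[, sel, drop = FALSE],
                                 X_pred = Xp[, sel, drop = FALSE],
                                 n_vars = length(sel))
  )
  rows <- purrr::imap_dfr(fits, function(f, nm) {
    mc <- min(plsr_max_components, nrow(f$X_cal) - 1L, f$n_vars)
    model <- fit_plsr(f$X_cal, y_cal, max_components = mc)
    metrics <- regression_metrics(y_pred, predict(model, f$X_pred))
    dplyr::mutate(metrics, input = nm, n_vars = f$n_vars,
                  ncomp = model$ncomp, .before = 1)
  })
  list(summary = rows, spa = spa)
}

#' Local vs general TN calibration experiment
#'
#' For the general scope the pooled samples are split 2:1, SPA (response =
#' TN) selects effective wavelengths on the calibration set, and PLSR models
#' are fitted on the full spectrum and on the effective wavelengths. For the
#' local scope the same protocol runs independently inside each soil type.
#' Prediction-set RMSEP, R2 and RPD are reported per model.
#'
#' @inheritParams run_classification_experiment
#' @param plsr_max_components Ceiling on PLSR latent components (default 20,
#'   chosen by leave-one-out RMSECV).
#' @param scopes `"local"`, `"general"` or both.
#' @return Object of class `tn_experiment`: `summary` tibble (`scope`,
#'   `property`, `input`, `n`, `n_vars`, `ncomp`, `rmsep`, `r2`, `rpd`),
#'   `spa` (named list per fitted scope/property), `seed`.
#' @export
run_tn_experiment <- function(dataset, seed = 1L,
                              spa_alpha = 0.25, spa_max_vars = 20L,
                              plsr_max_components = 20L,
                              scopes = c("local", "general")) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  spectra <- spectra_table(dataset)
  spa_results <- list()
  rows <- list()
  if ("local" %in% scopes) {
    classes <- soil_types()$name
    for (k in seq_along(classes)) {
      cl <- classes[k]
      sub <- spectra[spectra$soil_type == cl, ]
      if (nrow(sub) < 6) abort(paste0("Local scope needs >= 6 samples for ", cl, "."))
      split <- stratified_split(sub, seed = derive_seed(seed, k), stratify = FALSE)
      cal <- sub[match(split_ids(split, "calibration"), sub$sample_id), ]
      pred <- sub[match(split_ids(split, "prediction"), sub$sample_id), ]
      fit <- fit_tn_models(cal, pred, spa_alpha, spa_max_vars, plsr_max_components)
      spa_results[[paste0("local_", cl)]] <- fit$spa
      rows[[paste0("local_", cl)]] <-
        dplyr::mutate(fit$summary, scope = "local", property = cl, .before = 1)
    }
  }
  if ("general" %in% scopes) {
    split <- stratified_split(spectra, seed = derive_seed(seed, 0L), stratify = FALSE)
    cal <- spectra[match(split_ids(split, "calibration"), spectra$sample_id), ]
    pred <- spectra[match(split_ids(split, "prediction"), spectra$sample_id), ]
    fit <- fit_tn_models(cal, pred, spa_alpha, spa_max_vars, plsr_max_components)
    spa_results[["general"]] <- fit$spa
    rows[["general"]] <-
      dplyr::mutate(fit$summary, scope = "general", property = "general", .before = 1)
  }
  structure(
    list(summary = dplyr::bind_rows(rows), spa = spa_results,
         seed = as.integer(seed)),
    class = "tn_experiment"
  )
}

#' @export
print.tn_experiment <- function(x, ...) {
  cat("<tn_experiment>\n")
  print(dplyr::mutate(
    x$summary[c("scope", "property", "input", "n_vars", "ncomp", "rmsep", "r2", "rpd")],
    dplyr::across(c("rmsep"), ~ round(.x, 4)),
    dplyr::across(c("r2", "rpd"), ~ round(.x, 2))
  ), n = Inf)
  invisible(x)
}

#' @export
tidy.tn_experiment <- function(x, ...) x$summary

#' @export
glance.tn_experiment <- function(x, ...) {
  x$summary %>%
    dplyr::group_by(.data$scope) %>%
    dplyr::summarise(mean_rmsep = mean(.data$rmsep),
                     mean_r2 = mean(.data$r2),
                     mean_rpd = mean(.data$rpd), .groups = "drop")
}

#' @export
autoplot.tn_experiment <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$property, y = .data$rmsep,
                               fill = .data$input)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$scope, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "RMSEP (% TN)", fill = "Input variables",
                  title = "TN prediction error: local vs general models") +
    ggplot2::theme_minimal()
}

#' Combine experiment sections into a report
#'
#' @param classification A [run_classification_experiment()] result (or
#'   `NULL`).
#' @param tn A [run_tn_experiment()] result (or `NULL`).
#' @return Object of class `experiment_report`.
#' @export
experiment_report <- function(classification = NULL, tn = NULL) {
  structure(list(classification = classification, tn = tn),
            class = "experiment_report")
}

#' Render an experiment report to deterministic JSON
#'
#' Serialises the report's summary tables, confusion matrices, selected
#' wavelengths and seeds. Rendering is deterministic, and
#' `report_render(report_parse(json))` reproduces `json` exactly.
#'
#' @param report An [experiment_report()] (either section may be `NULL`), or
#'   a payload previously produced by [report_parse()] (so that
#'   render -> parse -> render is idempotent).
#' @return A JSON string (class `json`).
#' @export
report_render <- function(report) {
  if (!inherits(report, "experiment_report")) {
    if (!is.list(report) || !all(names(report) %in% c("classification", "tn"))) {
      abort("`report` must be an experiment_report or a parsed payload.")
    }
    return(jsonlite::toJSON(report, dataframe = "columns", digits = NA,
                            auto_unbox = TRUE, null = "null", pretty = TRUE))
  }
  as_payload <- function(section, kind) {
    if (is.null(section)) return(NULL)
    if (kind == "classification") {
      list(
        summary = section$summary,
        confusion = purrr::map(section$reports, function(r) {
          purrr::map(r$confusion, function(cm) unclass(as.matrix(cm)))
        }),
        cg = purrr::map(section$reports, function(r) c(cost = r$cost, gamma = r$gamma)),
        effective_wavelengths_nm = sort(section$spa$selected_wavelengths_nm),
        seed = section$seed
      )
    } else {
      list(
        summary = section$summary,
        effective_wavelengths_nm =
          purrr::map(section$spa, function(s) sort(s$selected_wavelengths_nm)),
        seed = section$seed
      )
    }
  }
  payload <- list(
    classification = as_payload(report$classification, "classification"),
    tn = as_payload(report$tn, "tn")
  )
  jsonlite::toJSON(payload, dataframe = "columns", digits = NA,
                   auto_unbox = TRUE, null = "null", pretty = TRUE)
}

#' Parse a rendered report back into tables
#'
#' @param json JSON produced by [report_render()].
#' @return A list mirroring the rendered payload, with summary tables as
#'   tibbles. Rendering the parsed object again reproduces the input.
#' @export
report_parse <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  for (part in intersect(names(x), c("classification", "tn"))) {
    if (!is.null(x[[part]]$summary)) {
      x[[part]]$summary <- as_tibble(as.data.frame(x[[part]]$summary))
    }
  }
  x
}
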