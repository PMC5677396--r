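#' Stratified 2:1 calibration/prediction split
#'
#' Per soil type, `floor(ratio * n)` samples go to the calibration set after
#' a seeded shuffle and the remainder to the prediction set; with the default
#' 2:1 ratio the cohort (84, 57, 42) splits into calibration (56, 38, 28)
#' and prediction (28, 19, 14). With `stratify = FALSE` the pooled samples
#' are split as one group (183 -> 122/61).
#'
#' @param manifest Tibble with `sample_id` and (when stratifying)
#'   `soil_type`.
#' @param ratio Calibration fraction in (0, 1); default 2/3.
#' @param seed Integer seed for the shuffle.
#' @param stratify Split within each soil type (default `TRUE`).
#' @return Tibble of class `soil_split`: `sample_id`, `set`
#'   (`"calibration"` / `"prediction"`).
#' @examples
#' m <- tibble::tibble(sample_id = as.character(1:9),
#'                     soil_type = rep(c("paddy", "red", "seashore_saline"), each = 3))
#' table(stratified_split(m, seed = 1)$set)
#' @export
stratified_split <- function(manifest, ratio = 2 / 3, seed = 1L, stratify = TRUE) {
  if (ratio <= 0 || ratio >= 1) abort("`ratio` must be inside (0, 1).")
  if (!"sample_id" %in% names(manifest)) abort("`manifest` needs a `sample_id` column.")
  groups <- if (stratify) {
    if (!"soil_type" %in% names(manifest)) abort("Stratified split needs `soil_type`.")
    split(manifest$sample_id, manifest$soil_type)
  } else {
    list(all = manifest$sample_id)
  }
  if (any(lengths(groups) < 3)) abort("Every stratum needs at least 3 samples.")
  out <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(groups, function(ids) {
      n_cal <- floor(length(ids) * ratio)
      shuffled <- sample(ids)
      tibble(
        sample_id = shuffled,
        set = rep(c("calibration", "prediction"),
                  c(n_cal, length(ids) - n_cal))
      )
    })
  })
  out <- out[match(manifest$sample_id, out$sample_id), ]
  structure(out, class = c("soil_split", class(tibble())))
}

split_ids <- function(split, which) split$sample_id[split$set == which]

#' SVM configuration
#'
#' @param cost,gamma Optional fixed `(c, g)`; when `NULL` both are chosen by
#'   grid search.
#' @param log2_cost,log2_gamma Grid of exponents searched for the penalty
#'   coefficient `c` and RBF kernel parameter `g`.
#' @param folds Cross-validation folds for the grid search (default 5).
#' @param seed Seed for the CV fold assignment.
#' @return List of class `svm_config`.
#' @export
svm_config <- function(cost = NULL, gamma = NULL,
                       log2_cost = seq(-5, 15, by = 2),
                       log2_gamma = seq(-15, 5, by = 2),
                       folds = 5L, seed = 1L) {
  structure(list(cost = cost, gamma = gamma,
                 log2_cost = log2_cost, log2_gamma = log2_gamma,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "svm_config")
}

standardize_features <- function(cal, pred) {
  center <- colMeans(cal)
  scale <- apply(cal, 2, sd)
  scale[scale == 0] <- 1 # constant feature carries no information; leave centered
  list(cal = sweep(sweep(cal, 2, center), 2, scale, "/"),
       pred = sweep(sweep(pred, 2, center), 2, scale, "/"))
}

confusion_3x3 <- function(truth, pred) {
  lv <- soil_types()$name
  table(factor(truth, levels = lv), factor(pred, levels = lv))
}

accuracy_from_confusion <- function(cm) {
  n <- unname(rowSums(cm))
  correct <- unname(diag(cm))
  tibble(
    soil_type = rownames(cm),
    n = n,
    correct = correct,
    accuracy = ifelse(n > 0, correct / n, NA_real_)
  )
}

#' RBF-SVM soil-type classification with grid-searched (c, g)
#'
#' Features are standardized with calibration-set statistics, `(c, g)` is
#' chosen by k-fold cross-validated accuracy on the calibration set over a
#' log2 grid, and the final model is refit on the whole calibration set.
#' Confusion matrices and per-class/overall accuracies are reported for both
#' sets.
#'
#' @param features Tibble with `sample_id`, `soil_type` and numeric feature
#'   columns (spectral, textural or fused).
#' @param split A [stratified_split()] result covering the same samples.
#' @param config An [svm_config()].
#' @return Object of class `svm_report`: confusion matrices, accuracy
#'   tables, overall accuracies and the `(c, g)` used.
#' @export
fit_svm <- function(features, split, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  feat_cols <- setdiff(names(features), c("sample_id", "soil_type", "tn_percent"))
  X <- as.matrix(features[feat_cols])
  rownames(X) <- features$sample_id
  y <- as_soil_type(features$soil_type)
  cal_ids <- split_ids(split, "calibration")
  pred_ids <- split_ids(split, "prediction")
  ical <- match(cal_ids, features$sample_id)
  ipred <- match(pred_ids, features$sample_id)
  if (anyNA(ical) || anyNA(ipred)) abort("Split ids missing from `features`.")
  if (length(unique(y[ical])) < 2) abort("Calibration set contains a single class.")
  std <- standardize_features(X[ical, , drop = FALSE], X[ipred, , drop = FALSE])

  if (is.null(config$cost) || is.null(config$gamma)) {
    grid <- expand.grid(cost = 2^config$log2_cost, gamma = 2^config$log2_gamma)
    folds <- withr::with_seed(config$seed, {
      sample(rep(seq_len(config$folds), length.out = length(ical)))
    })
    cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
      hits <- 0L
      for (f in seq_len(config$folds)) {
        tr <- folds != f
        if (length(unique(y[ical][tr])) < 2) return(NA_real_)
        fit <- e1071::svm(std$cal[tr, , drop = FALSE], y[ical][tr],
                          type = "C-classification", kernel = "radial",
                          cost = grid$cost[g], gamma = grid$gamma[g],
                          scale = FALSE)
        hits <- hits + sum(predict(fit, std$cal[!tr, , drop = FALSE]) == y[ical][!tr])
      }
      hits / length(ical)
    }, numeric(1))
    best <- which.max(cv_acc)
    cost <- grid$cost[best]
    gamma <- grid$gamma[best]
  } else {
    cost <- config$cost
    gamma <- config$gamma
    cv_acc <- NULL
  }

  model <- e1071::svm(std$cal, y[ical], type = "C-classification",
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
  cm_cal <- confusion_3x3(y[ical], predict(model, std$cal))
  cm_pred <- confusion_3x3(y[ipred], predict(model, std$pred))
  structure(
    list(
      confusion = list(calibration = cm_cal, prediction = cm_pred),
      accuracy = list(calibration = accuracy_from_confusion(cm_cal),
                      prediction = accuracy_from_confusion(cm_pred)),
      overall = c(calibration = sum(diag(cm_cal)) / sum(cm_cal),
                  prediction = sum(diag(cm_pred)) / sum(cm_pred)),
      cost = cost, gamma = gamma,
      n_features = ncol(X),
      model = model
    ),
    class = "svm_report"
  )
}

#' @export
print.svm_report <- function(x, ...) {
  cat(sprintf(
    "<svm_report> RBF SVM, %d features, (c, g) = (%.4g, %.4g); accuracy cal %.1f%% / pred %.1f%%\n",
    x$n_features, x$cost, x$gamma,
    100 * x$overall[["calibration"]], 100 * x$overall[["prediction"]]))
  invisible(x)
}

#' @export
tidy.svm_report <- function(x, ...) {
  purrr::map_dfr(c("calibration", "prediction"), function(set) {
    cm <- x$confusion[[set]]
    df <- as.data.frame(cm, stringsAsFactors = FALSE)
    names(df) <- c("truth", "predicted", "n")
    dplyr::mutate(as_tibble(df), set = set, .before = 1)
  })
}

#' @export
glance.svm_report <- function(x, ...) {
  tibble(
    accuracy_calibration = x$overall[["calibration"]],
    accuracy_prediction = x$overall[["prediction"]],
    cost = x$cost, gamma = x$gamma, n_features = x$n_features
  )
}

#' Fuse spectral and texture feature blocks
#'
#' Column-wise concatenation of the effective-wavelength spectral block and
#' the texture block, with a strict sample-identity check.
#'
#' @param spectral Tibble with `sample_id` (+ optional metadata) and spectral
#'   feature columns.
#' @param texture Tibble with `sample_id` and texture feature columns; may be
#'   `NULL`/empty, in which case the spectral block is returned unchanged.
#' @return Tibble with both feature blocks.
#' @export
fuse_features <- function(spectral, texture = NULL) {
  if (is.null(texture) || !ncol(dplyr::select(texture, -dplyr::any_of(c("sample_id", "soil_type"))))) {
    return(spectral)
  }
  if (!identical(spectral$sample_id, texture$sample_id)) {
    abort("Sample ids (and their order) must match between feature blocks.")
  }
  dplyr::bind_cols(
    spectral,
    dplyr::select(texture, -dplyr::any_of(c("sample_id", "soil_type")))
  )
}

#' Exploratory PCA + Fisher LDA of the full-spectrum matrix
#'
#' PCA on the preprocessed full-spectrum matrix; the first `n_pcs` score
#' vectors are submitted to Fisher's linear discriminant analysis and the
#' resubstitution correct-classification percentage is reported along with
#' 2-D discriminant coordinates for plotting.
#'
#' @param tbl Preprocessed spectra tibble with `soil_type`.
#' @param n_pcs Number of leading principal components used (default 4).
#' @return Object of class `soil_lda`: `scores` tibble (`sample_id`,
#'   `soil_type`, `LD1`, `LD2`, predicted class), `accuracy` (fraction),
#'   `variance_explained` per PC.
#' @export
pca_lda_explore <- function(tbl, n_pcs = 4L) {
  X <- spectra_matrix(tbl)
  if (n_pcs >= nrow(X)) abort("`n_pcs` must be below the number of samples.")
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  y <- as_soil_type(tbl$soil_type)
  fit <- MASS::lda(scores, grouping = y)
  proj <- predict(fit, scores)
  ld <- proj$x
  if (ncol(ld) < 2) ld <- cbind(ld, LD2 = 0)
  structure(
    list(
      scores = tibble(
        sample_id = tbl$sample_id,
        soil_type = as.character(y),
        LD1 = ld[, 1], LD2 = ld[, 2],
        predicted = as.character(proj$class)
      ),
      accuracy = mean(proj$class == y),
      variance_explained = pca$sdev^2 / sum(pca$sdev^2),
      n_pcs = as.integer(n_pcs)
    ),
    class = "soil_lda"
  )
}

#' @export
print.soil_lda <- function(x, ...) {
  cat(sprintf(
    "<soil_lda> Fisher LDA on %d PCs (%.1f%% variance): %.1f%% correct (resubstitution)\n",
    x$n_pcs, 100 * sum(x$variance_explained[seq_len(x$n_pcs)]), 100 * x$accuracy))
  invisible(x)
}

#' @export
tidy.soil_lda <- function(x, ...) x$scores

#' @export
glance.soil_lda <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_pcs = x$n_pcs,
         variance_explained = sum(x$variance_explained[seq_len(x$n_pcs)]))
}

#' @export
autoplot.soil_lda <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$LD1, y = .data$LD2,
                               colour = .data$soil_type,
                               shape = .data$soil_type)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = sprintf("Fisher LDA scores (%.1f%% correct)",
                                  100 * object$accuracy),
                  colour = "Soil type", shape = "Soil type") +
    ggplot2::theme_minimal()
}

#' Prediction-set regression metrics
#'
#' `RMSEP = sqrt(mean((y - yhat)^2))`; `R2 = 1 - SSres / SStot` on the
#' prediction set; `RPD = sd(y) / RMSEP` with the sample SD (n - 1). A
#' perfect prediction gives `RMSEP = 0`, `R2 = 1` and `RPD = Inf`.
#'
#' @param y_true Reference values (length >= 2, non-constant).
#' @param y_pred Predicted values.
#' @return One-row tibble: `rmsep`, `r2`, `rpd`, `n`.
#' @examples
#' regression_metrics(c(0.1, 0.2, 0.3), c(0.11, 0.19, 0.29))
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("Lengths differ.")
  if (length(y_true) < 2) abort("Need at least 2 observations.")
  if (sd(y_true) == 0) abort("Constant reference values: R2 and RPD undefined.")
  rmsep <- sqrt(mean((y_true - y_pred)^2))
  r2 <- 1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
  tibble(
    rmsep = rmsep,
    r2 = r2,
    rpd = if (rmsep == 0) Inf else sd(y_true) / rmsep,
    n = length(y_true)
  )
}
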