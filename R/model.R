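#' Train an annual risk model
#'
#' Fits a pluggable binary classifier on annual prediction instances
#' ([build_instances()]). The default engine is gradient boosting
#' (`xgboost`, single-threaded, seeded, so training is deterministic); a
#' logistic-regression engine (`stats::glm`) is available so analyses do not
#' depend on one library's numerics. The returned model carries an unset
#' `frozen_threshold`; freeze it from the test cohort with [apply_cutoff()] +
#' [set_frozen_threshold()] before any lead-time scan.
#'
#' @param instances Instance tibble with feature columns and a logical
#'   `label`; both classes must be present.
#' @param engine `"xgboost"` or `"logistic"`.
#' @param cutoff_fraction Fraction of the cohort flagged positive (default
#'   0.10, the top decile).
#' @param seed Integer seed for the training RNG.
#' @param nrounds,max_depth,eta Gradient-boosting parameters.
#' @return An object of class `"risk_model"`.
#' @export
train_risk_model <- function(instances, engine = c("xgboost", "logistic"),
                             cutoff_fraction = 0.10, seed = 1L,
                             nrounds = 60, max_depth = 3, eta = 0.3) {
  engine <- match.arg(engine)
  feats <- setdiff(names(instances),
                   c("patient_id", "year", "as_of", "label"))
  y <- instances$label
  if (length(unique(y)) < 2) {
    abort("training data contain a single outcome class",
          class = "asthmawarn_precondition_error")
  }
  x <- as.matrix(instances[, feats, drop = FALSE])
  fit <- switch(
    engine,
    xgboost = {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, nthread = 1, seed = seed),
        data = dtrain, nrounds = nrounds, verbose = 0
      )
    },
    logistic = {
      df <- as.data.frame(x)
      df$.label <- y
      glm(.label ~ ., data = df, family = binomial())
    }
  )
  structure(
    list(engine = engine, fit = fit, feature_names = feats,
         cutoff_fraction = cutoff_fraction,
         frozen_threshold = NA_real_, n_train = nrow(instances),
         seed = as.integer(seed)),
    class = "risk_model"
  )
}

#' Construct a fixed linear scorer
#'
#' A deterministic `risk_model` whose score is `intercept + sum(w * x)`.
#' Used in simulation studies and tests where the scoring rule must be
#' known in closed form.
#'
#' @param weights Named numeric vector of feature weights.
#' @param intercept Numeric intercept.
#' @param frozen_threshold Optional classification threshold.
#' @return An object of class `"risk_model"`.
#' @export
linear_risk_model <- function(weights, intercept = 0,
                              frozen_threshold = NA_real_) {
  stopifnot(!is.null(names(weights)), all(nzchar(names(weights))))
  structure(
    list(engine = "linear",
         fit = list(weights = weights, intercept = intercept),
         feature_names = names(weights), cutoff_fraction = NA_real_,
         frozen_threshold = frozen_threshold, n_train = 0L, seed = NA_integer_),
    class = "risk_model"
  )
}

#' Score instances with a risk model
#'
#' @param model A `risk_model`.
#' @param newdata Instance tibble (feature columns selected by name) or a
#'   numeric matrix with the model's feature columns.
#' @return Numeric vector of risk scores.
#' @export
risk_scores <- function(model, newdata) {
  x <- if (is.matrix(newdata)) {
    newdata[, model$feature_names, drop = FALSE]
  } else {
    as.matrix(newdata[, model$feature_names, drop = FALSE])
  }
  switch(
    model$engine,
    xgboost = predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1)),
    logistic = {
      df <- as.data.frame(x)
      as.numeric(predict(model$fit, newdata = df, type = "response"))
    },
    linear = as.numeric(x %*% model$fit$weights + model$fit$intercept),
    abort(sprintf("unknown engine: %s", model$engine))
  )
}

#' Apply the top-fraction classification cutoff
#'
#' Flags exactly `floor(fraction * N)` patients with the highest risk scores
#' (ties broken by `patient_id` ascending, so the flagged set is
#' reproducible); the classification threshold is the lowest flagged score.
#'
#' @param scores Tibble with columns `patient_id` and `score`.
#' @param fraction Fraction flagged, in (0, 1); default 0.10 (top decile).
#' @return The input tibble plus a logical `flagged` column, with attributes
#'   `threshold` and `cutoff_fraction`.
#' @export
#' @examples
#' scores <- tibble::tibble(patient_id = sprintf("P%02d", 1:10),
#'                          score = (1:10) / 10)
#' apply_cutoff(scores, 0.10)
apply_cutoff <- function(scores, fraction = 0.10) {
  if (nrow(scores) == 0) {
    abort("`scores` is empty", class = "asthmawarn_precondition_error")
  }
  if (!(fraction > 0 && fraction < 1)) {
    abort("`fraction` must be in (0, 1)",
          class = "asthmawarn_precondition_error")
  }
  n_flag <- floor(fraction * nrow(scores))
  ord <- order(-scores$score, scores$patient_id)
  flagged_idx <- ord[seq_len(n_flag)]
  out <- scores |>
    mutate(flagged = dplyr::row_number() %in% flagged_idx)
  threshold <- if (n_flag > 0) min(scores$score[flagged_idx]) else Inf
  attr(out, "threshold") <- threshold
  attr(out, "cutoff_fraction") <- fraction
  out
}

#' Freeze a classification threshold into a model
#'
#' @param model A `risk_model`.
#' @param threshold Numeric threshold (typically `attr(classified,
#'   "threshold")` from [apply_cutoff()]).
#' @return The model with `frozen_threshold` set.
#' @export
set_frozen_threshold <- function(model, threshold) {
  stopifnot(inherits(model, "risk_model"), is.finite(threshold))
  model$frozen_threshold <- threshold
  model
}

#' Confusion-matrix metrics for a binary classification
#'
#' Joins flags to outcome labels and computes the 2x2 table with the
#' standard derived ratios (as proportions in `[0, 1]`; format for printing
#' with [format_percentage()]).
#'
#' @param classified Tibble with `patient_id` and logical `flagged`
#'   (output of [apply_cutoff()]).
#' @param labels Tibble with `patient_id` and logical `label`, covering
#'   every classified patient.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `n`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
confusion_metrics <- function(classified, labels) {
  joined <- left_join(classified, labels, by = "patient_id")
  if (any(is.na(joined$label))) {
    abort("`labels` must cover every classified patient",
          class = "asthmawarn_precondition_error")
  }
  tp <- sum(joined$flagged & joined$label)
  fp <- sum(joined$flagged & !joined$label)
  tn <- sum(!joined$flagged & !joined$label)
  fn <- sum(!joined$flagged & joined$label)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = ratio(tp + tn, tp + fp + tn + fn)
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> engine: %s | %d features | trained on %d instances\n",
              x$engine, length(x$feature_names), x$n_train))
  cat(sprintf("  cutoff fraction: %s | frozen threshold: %s\n",
              format(x$cutoff_fraction),
              if (is.na(x$frozen_threshold)) "unset"
              else format(x$frozen_threshold, digits = 4)))
  invisible(x)
}

#' Tidy a risk model
#'
#' Returns per-feature terms: gradient-boosting gain-based importances, GLM
#' coefficients, or linear weights, depending on the engine.
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (plus
#'   engine-specific columns).
#' @export
tidy.risk_model <- function(x, ...) {
  switch(
    x$engine,
    xgboost = {
      imp <- xgboost::xgb.importance(model = x$fit)
      tibble(term = imp$Feature, estimate = imp$Gain,
             cover = imp$Cover, frequency = imp$Frequency)
    },
    logistic = {
      co <- stats::coef(x$fit)
      tibble(term = names(co), estimate = unname(co))
    },
    linear = tibble(term = names(x$fit$weights),
                    estimate = unname(x$fit$weights))
  )
}

#' Glance at a risk model
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return One-row tibble summarising the fitted model.
#' @export
glance.risk_model <- function(x, ...) {
  tibble(engine = x$engine, n_features = length(x$feature_names),
         n_train = x$n_train, cutoff_fraction = x$cutoff_fraction,
         frozen_threshold = x$frozen_threshold)
}
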