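#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney form with tie correction: AUC = (sum of case ranks -
#' n_case(n_case+1)/2) / (n_case * n_control), with midranks for ties.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical (or 0/1) outcome labels.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Feature specification for the prediction harness
#'
#' @param name Feature label.
#' @param source Column name on the cohort data.frame.
#' @param transform `"identity"`, `"standardize"`, or `"onehot"` (for
#'   categorical sources).
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(name, source = name,
                         transform = c("identity", "standardize", "onehot")) {
  transform <- match.arg(transform)
  structure(list(name = name, source = source, transform = transform),
            class = "feature_spec")
}

.build_design <- function(cohort_df, features) {
  cols <- lapply(features, function(f) {
    if (!f$source %in% names(cohort_df)) {
      stop(sprintf("feature '%s': column '%s' not found", f$name, f$source),
           call. = FALSE)
    }
    v <- cohort_df[[f$source]]
    if (f$transform == "onehot") {
      fac <- factor(v)
      m <- stats::model.matrix(~ fac - 1)
      colnames(m) <- paste0(f$name, "_", levels(fac))
      return(m)
    }
    v <- as.numeric(v)
    if (anyNA(v)) {
      # median imputation with a missingness indicator (waist etc.)
      ind <- as.numeric(is.na(v))
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      m <- cbind(v, ind)
      colnames(m) <- c(f$name, paste0(f$name, "_missing"))
      return(m)
    }
    m <- matrix(v, ncol = 1, dimnames = list(NULL, f$name))
    m
  })
  x <- do.call(cbind, cols)
  std <- vapply(features, function(f) f$transform == "standardize", logical(1))
  for (i in which(std)) {
    nm <- features[[i]]$name
    if (nm %in% colnames(x) && stats::sd(x[, nm]) > 0) {
      x[, nm] <- (x[, nm] - mean(x[, nm])) / stats::sd(x[, nm])
    }
  }
  x
}

# stratified fold assignment: cases and controls split separately
.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) {
      stop("stratification error: a class has fewer members than folds", call. = FALSE)
    }
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# L2-regularized logistic classifier (ridge), C = 1 in sklearn's
# parameterization i.e. lambda = 1 / (n * C)
.ridge_classifier <- function(C = 1.0) {
  function(x_train, y_train, x_test) {
    if (ncol(x_train) < 2) {  # glmnet requires >= 2 columns
      x_train <- cbind(x_train, .pad = 0)
      x_test <- cbind(x_test, .pad = 0)
    }
    fit <- glmnet::glmnet(x_train, y_train, family = "binomial", alpha = 0,
                          lambda = 1 / (nrow(x_train) * C), standardize = TRUE)
    as.numeric(stats::predict(fit, newx = x_test, type = "response"))
  }
}

#' Cross-validated AUC of a logistic prediction model
#'
#' Stratified k-fold cross-validation of a binary classifier; out-of-fold
#' scores are pooled, the AUC is computed by the rank statistic, and the 95%
#' CI comes from a bootstrap over the pooled out-of-fold (score, label)
#' pairs. Deterministic under `seed`.
#'
#' @param cohort_df Cohort data.frame with a logical `gd` column.
#' @param features List of [feature_spec()]s.
#' @param n_folds Number of CV folds (default 10).
#' @param n_boot Bootstrap iterations for the CI (default 100).
#' @param seed Integer RNG seed.
#' @param classifier A function `(x_train, y_train, x_test) -> scores`;
#'   defaults to an L2-regularized logistic regression with C = 1.
#' @param model_name Label carried into the result.
#' @return List of class `cv_result`: `mean_auc`, `sd_auc` (across folds),
#'   `ci_low`, `ci_high`, `n_folds`, `n_boot`, `model_name`, `seed`, and the
#'   pooled out-of-fold `scores`/`labels`.
#' @export
evaluate_model <- function(cohort_df, features, n_folds = 10, n_boot = 100,
                           seed = 20220830, classifier = NULL,
                           model_name = "model") {
  if (is.null(classifier)) classifier <- .ridge_classifier(1.0)
  y <- as.logical(cohort_df$gd)
  if (anyNA(y)) stop("gd status missing", call. = FALSE)
  x <- .build_design(cohort_df, features)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- .stratified_folds(y, n_folds)
  scores <- numeric(length(y))
  fold_auc <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    te <- fold == k
    scores[te] <- classifier(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE])
    fold_auc[k] <- auc_rank(scores[te], y[te])
  }
  pooled <- auc_rank(scores, y)
  boot_auc <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(y), replace = TRUE)
    if (!any(y[idx]) || all(y[idx])) return(NA_real_)
    auc_rank(scores[idx], y[idx])
  }, numeric(1))
  ci <- stats::quantile(boot_auc, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(mean_auc = pooled, sd_auc = stats::sd(fold_auc),
                 fold_auc = fold_auc, ci_low = ci[1], ci_high = ci[2],
                 n_folds = n_folds, n_boot = n_boot,
                 model_name = model_name, seed = seed,
                 scores = scores, labels = y), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: AUC %.3f (SD %.3f; 95%% CI %.3f-%.3f), %d folds\n",
              x$model_name, x$mean_auc, x$sd_auc, x$ci_low, x$ci_high, x$n_folds))
  invisible(x)
}

#' Baseline clinical feature set
#'
#' Age, BMI, race/ethnicity indicator, family history of diabetes, PCOS,
#' hypertension, and waist circumference (median-imputed with a missingness
#' indicator when absent). Pregnancy-history features and HbA1c are omitted
#' (unavailable for a nulliparous cohort).
#'
#' @param cohort_df Cohort data.frame (used to check column availability).
#' @return List of `feature_spec`s present in the cohort.
#' @export
baseline_features <- function(cohort_df) {
  cand <- list(
    feature_spec("age"), feature_spec("bmi"),
    feature_spec("race_white", transform = "identity"),
    feature_spec("family_history_diabetes"),
    feature_spec("pcos"), feature_spec("hypertension"),
    feature_spec("waist")
  )
  Filter(function(f) f$source %in% names(cohort_df), cand)
}
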