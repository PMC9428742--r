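#' PRS-by-activity interaction logistic model
#'
#' Fits, by maximum likelihood,
#' \deqn{logit P(GD = 1) = a + b\,age + c\,BMI + d\,X_3 + e\,X_4 + f\,X_3 X_4}
#' where \eqn{X_3} indicates PRS in the top quartile and \eqn{X_4} METs below
#' the activity threshold. The unadjusted model drops the age and BMI terms
#' and, having one parameter per design cell, is saturated: its fitted
#' probabilities equal the empirical cell proportions, and its coefficients
#' equal closed-form cell log-odds contrasts. The Wald z-test on the
#' interaction coefficient f tests for a non-additive (on the log-odds scale)
#' joint association.
#'
#' @param cohort_df Cohort data.frame with logical `gd`, `prs_top25`,
#'   `mets_low` columns; when `adjust_confounders`, also numeric `age`, `bmi`.
#' @param adjust_confounders Include age and BMI as confounders.
#' @return List of class `interaction_fit` with elements `a`, `b`, `c`, `d`,
#'   `e`, `f` (NA where not in the model), `se_f`, `p_f`, `converged`, `n`,
#'   and the underlying `glm` fit as `fit`.
#' @export
fit_interaction <- function(cohort_df, adjust_confounders = FALSE) {
  req <- c("gd", "prs_top25", "mets_low")
  if (adjust_confounders) req <- c(req, "age", "bmi")
  missing_cols <- setdiff(req, names(cohort_df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(y = as.integer(cohort_df$gd),
                  x3 = as.integer(cohort_df$prs_top25),
                  x4 = as.integer(cohort_df$mets_low))
  if (adjust_confounders) { d$x1 <- cohort_df$age; d$x2 <- cohort_df$bmi }
  if (anyNA(d)) stop("missing covariate values in the interaction model", call. = FALSE)
  form <- if (adjust_confounders) y ~ x1 + x2 + x3 + x4 + x3:x4 else y ~ x3 + x4 + x3:x4
  fit <- stats::glm(form, family = stats::binomial(), data = d,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || any(abs(cf) > 15)) {
    stop("interaction model did not yield finite stable coefficients (possible complete separation)",
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  f_name <- "x3:x4"
  out <- list(
    a = unname(cf["(Intercept)"]),
    b = if (adjust_confounders) unname(cf["x1"]) else NA_real_,
    c = if (adjust_confounders) unname(cf["x2"]) else NA_real_,
    d = unname(cf["x3"]),
    e = unname(cf["x4"]),
    f = unname(cf[f_name]),
    se_f = unname(sm[f_name, "Std. Error"]),
    p_f = unname(sm[f_name, "Pr(>|z|)"]),
    converged = fit$converged,
    n = nrow(d),
    adjusted = adjust_confounders,
    fit = fit
  )
  class(out) <- "interaction_fit"
  out
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("<interaction_fit> %s, n = %d%s\n",
              if (x$adjusted) "adjusted (age, BMI)" else "unadjusted",
              x$n, if (x$converged) "" else " [NOT CONVERGED]"))
  co <- c(a = x$a, b = x$b, c = x$c, d = x$d, e = x$e, f = x$f)
  co <- co[!is.na(co)]
  cat(paste(sprintf("  %s = %.3f", names(co), co), collapse = "\n"), "\n")
  cat(sprintf("  Wald test for f: se = %.3f, p = %.3g\n", x$se_f, x$p_f))
  invisible(x)
}

#' Write an interaction fit report as JSON
#' @param x An `interaction_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_report <- function(x, path) {
  rep <- x[c("a", "b", "c", "d", "e", "f", "se_f", "p_f", "converged", "n", "adjusted")]
  rep$model <- if (x$adjusted) {
    "logit(P(gd)) = a + b*age + c*bmi + d*prs_top25 + e*mets_low + f*prs_top25*mets_low"
  } else {
    "logit(P(gd)) = a + d*prs_top25 + e*mets_low + f*prs_top25*mets_low"
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
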