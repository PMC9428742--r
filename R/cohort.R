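#' Glucose tolerance test result
#'
#' Container for one oral glucose tolerance test (GTT). Three protocols are
#' supported: the fasting 3-hour 100-g test (4 timed values), the fasting
#' 2-hour 75-g test (3 values), and the non-fasting 50-g screen (1 value).
#' All values are plasma glucose in mg/dL.
#'
#' @param kind One of `"fasting_100g_3h"`, `"fasting_75g_2h"`,
#'   `"nonfasting_50g"`.
#' @param values Numeric vector of glucose measurements in mg/dL, ordered
#'   fasting, 1h, 2h, 3h as applicable. Must match the protocol length
#'   (4, 3, 1 respectively) and be positive.
#' @return An object of class `gtt_result`.
#' @examples
#' gtt_result("fasting_100g_3h", c(96, 181, 150, 139))
#' @export
gtt_result <- function(kind = c("fasting_100g_3h", "fasting_75g_2h", "nonfasting_50g"),
                       values) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  n_req <- switch(kind, fasting_100g_3h = 4L, fasting_75g_2h = 3L, nonfasting_50g = 1L)
  if (length(values) != n_req) {
    stop(sprintf("GTT kind '%s' requires exactly %d values, got %d",
                 kind, n_req, length(values)), call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("GTT glucose values must be finite and positive (mg/dL)", call. = FALSE)
  }
  structure(list(kind = kind, values = values), class = "gtt_result")
}

#' @export
print.gtt_result <- function(x, ...) {
  cat(sprintf("<gtt_result> %s: %s mg/dL\n", x$kind, paste(x$values, collapse = ", ")))
  invisible(x)
}

# Diagnostic thresholds (mg/dL), inclusive ("at least" as printed).
.gtt_thresholds <- list(
  fasting_100g_3h = c(fasting = 95, h1 = 180, h2 = 155, h3 = 140),
  fasting_75g_2h  = c(fasting = 92, h1 = 180, h2 = 153),
  nonfasting_50g  = c(screen = 200)
)

.gtt_positive <- function(gtt, fasting_gtt_present) {
  thr <- .gtt_thresholds[[gtt$kind]]
  n_abn <- sum(gtt$values >= thr)
  switch(gtt$kind,
    fasting_100g_3h = n_abn >= 2,
    fasting_75g_2h  = n_abn >= 1,
    # the 50-g screen only counts when no fasting GTT was performed
    nonfasting_50g  = n_abn >= 1 && !fasting_gtt_present
  )
}

#' Determine gestational diabetes status
#'
#' Applies the diagnostic criteria: a fasting 3-hour 100-g GTT is positive
#' with at least 2 abnormal values (fasting >= 95, 1h >= 180, 2h >= 155,
#' 3h >= 140 mg/dL); a fasting 2-hour 75-g GTT with at least 1 abnormal value
#' (fasting >= 92, 1h >= 180, 2h >= 153); a non-fasting 50-g screen with a
#' value >= 200 mg/dL counts only when no fasting GTT was performed. When no
#' GTT data are available the clinical diagnosis is used. When a fasting GTT
#' and a clinical diagnosis disagree, the GTT wins (clinical diagnosis is a
#' fallback, not an override).
#'
#' If several GTTs are supplied (e.g. both a 100-g and a 75-g test), each is
#' evaluated independently and GD is reported if any qualifies.
#'
#' @param gtt A `gtt_result`, a list of `gtt_result`s, or `NULL`.
#' @param clinical Logical clinical GD diagnosis, or `NULL`/`NA` if absent.
#' @return Logical scalar: `TRUE` if GD criteria are met.
#' @export
diagnose_gd <- function(gtt = NULL, clinical = NULL) {
  if (inherits(gtt, "gtt_result")) gtt <- list(gtt)
  if (!is.null(gtt)) {
    if (!length(gtt)) gtt <- NULL
    else if (!all(vapply(gtt, inherits, logical(1), "gtt_result"))) {
      stop("'gtt' must be a gtt_result or a list of gtt_result objects", call. = FALSE)
    }
  }
  if (is.null(clinical) || (length(clinical) == 1L && is.na(clinical))) clinical <- NULL
  if (is.null(gtt) && is.null(clinical)) {
    stop("undeterminable outcome: no GTT data and no clinical diagnosis", call. = FALSE)
  }
  if (is.null(gtt)) return(isTRUE(as.logical(clinical)))
  fasting_present <- any(vapply(gtt, function(g) g$kind != "nonfasting_50g", logical(1)))
  any(vapply(gtt, .gtt_positive, logical(1), fasting_gtt_present = fasting_present))
}

#' Convert glucose mg/dL to mmol/L (display helper)
#'
#' Multiplies by 0.0555. All internal comparisons are done in mg/dL; this
#' utility exists for reporting only.
#'
#' @param mg_dl Numeric vector of glucose values in mg/dL.
#' @return Values in mmol/L.
#' @export
mgdl_to_mmoll <- function(mg_dl) mg_dl * 0.0555

#' Assemble a cohort data frame
#'
#' A cohort is a plain `data.frame` (class `gd_cohort`) with one row per
#' participant and a `provenance` attribute auditing applied exclusions.
#' Required columns are created (as `NA`) when absent.
#'
#' @param participants A data.frame with at least an `id` column. Recognised
#'   columns: `age`, `bmi`, `waist`, `family_history_diabetes`, `pcos`,
#'   `hypertension`, `prior_diabetes`, `prediabetes`, `gtt` (list column of
#'   `gtt_result` or `NULL`), `clinical_gd_diagnosis`, `mets`, `prs`, `gd`,
#'   `ancestry_eligible`.
#' @param provenance Free-text audit string.
#' @return A `gd_cohort` data.frame.
#' @export
cohort <- function(participants, provenance = "raw") {
  stopifnot(is.data.frame(participants), "id" %in% names(participants))
  if (anyDuplicated(participants$id)) {
    stop("participant ids must be unique", call. = FALSE)
  }
  defaults <- list(
    age = NA_real_, bmi = NA_real_, waist = NA_real_,
    family_history_diabetes = NA, pcos = NA, hypertension = NA,
    prior_diabetes = NA, prediabetes = NA,
    clinical_gd_diagnosis = NA, mets = NA_real_, prs = NA_real_,
    gd = NA, ancestry_eligible = NA
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(participants)) {
      participants[[nm]] <- rep(defaults[[nm]], nrow(participants))
    }
  }
  if (!"gtt" %in% names(participants)) {
    participants$gtt <- replicate(nrow(participants), NULL, simplify = FALSE)
  }
  with_age <- participants$age
  if (any(!is.na(with_age) & with_age <= 0)) stop("age must be positive", call. = FALSE)
  if (any(!is.na(participants$bmi) & participants$bmi <= 0)) {
    stop("bmi must be positive", call. = FALSE)
  }
  if (any(!is.na(participants$mets) & participants$mets < 0)) {
    stop("mets must be non-negative", call. = FALSE)
  }
  structure(participants, class = c("gd_cohort", "data.frame"),
            provenance = provenance)
}

#' Derive GD status for every participant in a cohort
#'
#' Applies [diagnose_gd()] row-wise using the `gtt` list column and the
#' `clinical_gd_diagnosis` column, writing the result into `gd`. Participants
#' with neither source keep `gd = NA` (they are removed by
#' [apply_eligibility()]).
#'
#' @param x A `gd_cohort`.
#' @return The cohort with the `gd` column filled in.
#' @export
derive_gd <- function(x) {
  stopifnot(inherits(x, "gd_cohort"))
  x$gd <- vapply(seq_len(nrow(x)), function(i) {
    g <- x$gtt[[i]]
    cl <- x$clinical_gd_diagnosis[i]
    if ((is.null(g) || !length(g)) && is.na(cl)) return(NA)
    diagnose_gd(g, if (is.na(cl)) NULL else cl)
  }, logical(1))
  x
}

#' Apply the eligibility / exclusion cascade
#'
#' Removes participants in a fixed order and reports per-step counts:
#' (1) missing all covariates (age, BMI, METs, family history all absent);
#' (2) prediabetes; (3) pre-pregnancy diabetes; (4) no GD determination
#' possible (no GTT and no clinical diagnosis); (5) missing or invalid METs;
#' (6) missing PRS. The function is idempotent and the step counts sum to
#' the number of rows removed.
#'
#' @param x A `gd_cohort`.
#' @return The filtered cohort; the exclusion report (a data.frame with
#'   columns `step` and `n_removed`) is attached as attribute
#'   `exclusion_report` and appended to `provenance`.
#' @export
apply_eligibility <- function(x) {
  stopifnot(inherits(x, "gd_cohort"))
  if (!all(!is.na(x$gd)) ) x <- derive_gd(x)
  steps <- list(
    missing_all_covariates = function(d)
      is.na(d$age) & is.na(d$bmi) & is.na(d$mets) & is.na(d$family_history_diabetes),
    prediabetes            = function(d) !is.na(d$prediabetes) & d$prediabetes,
    prepregnancy_diabetes  = function(d) !is.na(d$prior_diabetes) & d$prior_diabetes,
    no_gd_determination    = function(d) is.na(d$gd),
    missing_or_invalid_mets = function(d) is.na(d$mets) | d$mets < 0,
    missing_prs            = function(d) is.na(d$prs)
  )
  report <- data.frame(step = names(steps), n_removed = 0L,
                       stringsAsFactors = FALSE)
  keep <- x
  for (i in seq_along(steps)) {
    drop <- steps[[i]](keep)
    report$n_removed[i] <- sum(drop)
    keep <- keep[!drop, , drop = FALSE]
  }
  if (nrow(keep) == 0L) warning("no participants retained after eligibility filtering")
  out <- structure(keep, class = c("gd_cohort", "data.frame"),
                   provenance = paste0(attr(x, "provenance"),
                                       " | eligibility cascade applied"))
  attr(out, "exclusion_report") <- report
  out
}

#' Write an exclusion report as JSON
#'
#' @param x A cohort returned by [apply_eligibility()] (or the report itself).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(x, path) {
  rep <- if (is.data.frame(x)) attr(x, "exclusion_report") else x
  if (is.null(rep)) stop("no exclusion report attached; run apply_eligibility() first",
                         call. = FALSE)
  jsonlite::write_json(rep, path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a phenotype CSV into a cohort
#'
#' Expected columns: `id` plus any of the cohort covariates. GTT data are
#' encoded in two columns: `gtt_kind` (protocol name, empty when none) and
#' `gtt_values` (semicolon-separated mg/dL values).
#'
#' @param path CSV file path.
#' @return A `gd_cohort`.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  gtt <- replicate(nrow(d), NULL, simplify = FALSE)
  if (all(c("gtt_kind", "gtt_values") %in% names(d))) {
    for (i in seq_len(nrow(d))) {
      k <- d$gtt_kind[i]
      if (!is.na(k) && nzchar(k)) {
        vals <- as.numeric(strsplit(d$gtt_values[i], ";", fixed = TRUE)[[1]])
        gtt[[i]] <- gtt_result(k, vals)
      }
    }
    d$gtt_kind <- NULL
    d$gtt_values <- NULL
  }
  d$gtt <- gtt
  cohort(d, provenance = paste("read from", path))
}
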