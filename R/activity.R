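#' Total weekly METs from an activity log
#'
#' Each record contributes intensity (METs) x sessions/week x minutes/session,
#' i.e. the weighted sum of weekly minutes across activities, in MET.min/wk.
#'
#' @param records A data.frame with columns `met_value`, `sessions_per_week`,
#'   `minutes_per_session` (one row per reported activity). An empty frame
#'   gives 0.
#' @return Total METs (MET.min/wk), a single non-negative number.
#' @examples
#' total_mets(data.frame(met_value = 3, sessions_per_week = 5,
#'                       minutes_per_session = 30))  # 450
#' @export
total_mets <- function(records) {
  req <- c("met_value", "sessions_per_week", "minutes_per_session")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop("records must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) return(0)
  v <- as.matrix(records[, req])
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("activity fields must be finite and non-negative", call. = FALSE)
  }
  sum(records$met_value * records$sessions_per_week * records$minutes_per_session)
}

#' Dichotomize activity level at a METs threshold
#'
#' The default threshold of 450 MET.min/wk corresponds to 150 minutes of
#' moderate (3.0 MET) or 75 minutes of vigorous (6.0 MET) activity per week.
#' The boundary itself is classed as more active (`mets >= threshold`),
#' mirroring the "METs >= 450" / "METs < 450" subgroup labels.
#'
#' @param mets Numeric vector of total METs (MET.min/wk), non-negative.
#' @param threshold Cut point, default 450.
#' @return Factor with levels `less_active`, `more_active`.
#' @export
activity_class <- function(mets, threshold = 450) {
  stopifnot(is.numeric(mets), all(is.finite(mets)), all(mets >= 0),
            is.numeric(threshold), threshold > 0)
  factor(ifelse(mets < threshold, "less_active", "more_active"),
         levels = c("less_active", "more_active"))
}

#' Compute per-participant METs from an activity CSV
#'
#' @param path CSV with columns `participant_id`, `activity_name`,
#'   `met_value`, `sessions_per_week`, `minutes_per_session`. When
#'   `met_value` is missing it is looked up in `met_config` by activity name.
#' @param met_config Optional data.frame mapping `activity_name` to
#'   `met_value` (see [default_met_values()]).
#' @return data.frame with columns `id` and `mets`.
#' @export
read_activity_mets <- function(path, met_config = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"met_value" %in% names(d)) d$met_value <- NA_real_
  if (!is.null(met_config)) {
    idx <- match(d$activity_name, met_config$activity_name)
    fill <- is.na(d$met_value)
    d$met_value[fill] <- met_config$met_value[idx[fill]]
  }
  if (anyNA(d$met_value)) {
    stop("unresolved MET intensity for activities: ",
         paste(unique(d$activity_name[is.na(d$met_value)]), collapse = ", "),
         call. = FALSE)
  }
  agg <- lapply(split(d, d$participant_id), total_mets)
  data.frame(id = names(agg), mets = unname(unlist(agg)),
             stringsAsFactors = FALSE)
}

#' Default MET intensity values for common leisure activities
#'
#' A small compendium-style lookup shipped as a convenience; intensities are
#' caller-overridable since questionnaires differ in activity granularity.
#'
#' @return data.frame with `activity_name` and `met_value`.
#' @export
default_met_values <- function() {
  utils::read.delim(
    system.file("extdata", "met_values.tsv", package = "gdrisk"),
    stringsAsFactors = FALSE
  )
}
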