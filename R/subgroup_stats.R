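#' 2x2 subgroup-by-outcome contingency table
#'
#' The atom of the subgroup analysis: gestational-diabetes cases and controls
#' inside a subgroup, and in the rest of the cohort.
#'
#' @param cases_in,controls_in Counts inside the subgroup.
#' @param cases_out,controls_out Counts in the remainder of the cohort.
#' @return A `two_by_two` object.
#' @export
two_by_two <- function(cases_in, controls_in, cases_out, controls_out) {
  cnt <- c(cases_in = cases_in, controls_in = controls_in,
           cases_out = cases_out, controls_out = controls_out)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cnt) == 0) stop("all counts are zero", call. = FALSE)
  structure(as.list(cnt), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("<two_by_two> in: %d/%d  out: %d/%d (cases/controls)\n",
              x$cases_in, x$controls_in, x$cases_out, x$controls_out))
  invisible(x)
}

#' Define a subgroup
#'
#' A named predicate over cohort rows, optionally nested inside a parent
#' subgroup (membership must be a subset of the parent's).
#'
#' @param name Subgroup label.
#' @param predicate Function taking the cohort data.frame and returning a
#'   logical vector of memberships.
#' @param parent Optional parent `subgroup_spec`.
#' @return A `subgroup_spec` object.
#' @export
subgroup_spec <- function(name, predicate, parent = NULL) {
  stopifnot(is.character(name), is.function(predicate))
  if (!is.null(parent)) stopifnot(inherits(parent, "subgroup_spec"))
  structure(list(name = name, predicate = predicate, parent = parent),
            class = "subgroup_spec")
}

.evaluate_subgroup <- function(cohort_df, spec) {
  m <- spec$predicate(cohort_df)
  if (anyNA(m)) {
    bad <- cohort_df$id[is.na(m)]
    stop(sprintf("subgroup '%s' predicate unevaluable for participant(s): %s",
                 spec$name, paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(spec$parent)) {
    pm <- .evaluate_subgroup(cohort_df, spec$parent)
    if (any(m & !pm)) {
      stop(sprintf("subgroup '%s' is not nested within its parent '%s'",
                   spec$name, spec$parent$name), call. = FALSE)
    }
  }
  m
}

#' Build the 2x2 table for a subgroup against the rest of the cohort
#'
#' @param cohort_df A cohort data.frame with a logical `gd` column (no NAs).
#' @param spec A `subgroup_spec`.
#' @return A `two_by_two`.
#' @export
make_table <- function(cohort_df, spec) {
  stopifnot(is.data.frame(cohort_df), "gd" %in% names(cohort_df))
  if (anyNA(cohort_df$gd)) stop("gd status missing for some participants", call. = FALSE)
  m <- .evaluate_subgroup(cohort_df, spec)
  gd <- as.logical(cohort_df$gd)
  two_by_two(sum(m & gd), sum(m & !gd), sum(!m & gd), sum(!m & !gd))
}

#' Odds ratio with Woolf confidence interval and Fisher exact p
#'
#' OR = (cases_in/controls_in) / (cases_out/controls_out). The 95% CI is the
#' Woolf log-OR normal approximation, exp(log OR +/- 1.96 * SE) with
#' SE = sqrt(sum of reciprocal cell counts). When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied to the OR and
#' CI and flagged. The p-value is the conventional two-sided Fisher exact
#' test (sum of probabilities of tables no more probable than the observed).
#'
#' @param t A `two_by_two`.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `or_result`: `or`, `ci_low`, `ci_high`, `fisher_p`,
#'   `haldane` (logical), `table`.
#' @export
odds_ratio <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  a <- t$cases_in; b <- t$controls_in; cc <- t$cases_out; d <- t$controls_out
  if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) {
    stop("a whole margin of the table is zero: odds ratio undefined", call. = FALSE)
  }
  haldane <- any(c(a, b, cc, d) == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  or <- (a / b) / (cc / d)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- stats::fisher.test(matrix(c(t$cases_in, t$controls_in,
                                   t$cases_out, t$controls_out),
                                 nrow = 2, byrow = TRUE))$p.value
  structure(list(or = or, ci_low = ci[1], ci_high = ci[2], fisher_p = p,
                 haldane = haldane, table = t), class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), Fisher p = %.3g%s\n",
              x$or, x$ci_low, x$ci_high, x$fisher_p,
              if (x$haldane) " [Haldane +0.5]" else ""))
  invisible(x)
}

#' Positive likelihood ratio of a subgroup
#'
#' Ratio of posterior to prior odds of diagnosis: posterior odds are the
#' case/control odds inside the subgroup; prior odds are those of the
#' reference group — the whole cohort (in + out of the table) or the parent
#' subgroup's own counts.
#'
#' @param t A `two_by_two` for the subgroup.
#' @param reference `"whole_cohort"` or `"parent"`.
#' @param parent_table The parent subgroup's `two_by_two` (its `cases_in` /
#'   `controls_in` are the prior odds) — required when `reference = "parent"`.
#' @return The positive LR (may be `Inf` with a warning when the subgroup has
#'   no controls).
#' @export
positive_lr <- function(t, reference = c("whole_cohort", "parent"),
                        parent_table = NULL) {
  stopifnot(inherits(t, "two_by_two"))
  reference <- match.arg(reference)
  prior <- if (reference == "whole_cohort") {
    (t$cases_in + t$cases_out) / (t$controls_in + t$controls_out)
  } else {
    if (is.null(parent_table)) stop("parent_table required for reference = 'parent'", call. = FALSE)
    parent_table$cases_in / parent_table$controls_in
  }
  if (!is.finite(prior) || prior <= 0) {
    stop("reference odds must be positive and finite", call. = FALSE)
  }
  if (t$controls_in == 0) {
    warning("subgroup has no controls: positive LR is infinite")
    return(Inf)
  }
  (t$cases_in / t$controls_in) / prior
}

# Collapse cohort rows into joint (child, parent, gd) stratum counts.
# Bootstrap resampling of rows with replacement is then exactly a
# multinomial draw over these strata (rows within a stratum are
# exchangeable), which keeps n_boot = 10000 cheap.
.boot_strata <- function(child, parent, gd) {
  idx <- 1L + child + 2L * parent + 4L * gd
  tabulate(idx, nbins = 8L)
}

.lr_from_counts <- function(ci, co, ca_tot, co_tot) (ci / co) / (ca_tot / co_tot)

#' Bootstrap inference for a subgroup's positive likelihood ratio
#'
#' Resamples participants with replacement `n_boot` times. Each replicate
#' recomputes the child subgroup's LR against the whole replicate cohort and
#' (when a parent is given) the parent's LR. `p_vs_all` is the proportion of
#' replicates in which the child LR falls on the null side of 1; `p_vs_parent`
#' the proportion on the null side of the parent LR. With
#' `direction = "auto"` (the default) the null side is chosen from the
#' observed comparison — lower when the child's point estimate exceeds the
#' reference, higher otherwise; note that this adaptive choice doubles the
#' type-I rate relative to a fixed one-sided test. Ties count 0.5. The 95%
#' CI is the percentile interval of the child-LR replicates. Replicates with
#' an empty child subgroup (or empty parent) are dropped and counted.
#'
#' @param cohort_df Cohort data.frame with `gd` and predicate inputs.
#' @param spec Child `subgroup_spec` (its `parent`, if any, defines the
#'   parent comparison).
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer RNG seed (required for reproducibility).
#' @param direction `"auto"` (adaptive, matching the published analysis),
#'   `"greater"` (test LR > reference) or `"less"`.
#' @return List of class `lr_result`: `lr`, `ci_low`, `ci_high`, `p_vs_all`,
#'   `p_vs_parent` (NA when no parent), `n_boot`, `n_dropped`, `direction`
#'   (the directions actually used, named for each comparison), `seed`.
#' @export
bootstrap_lr <- function(cohort_df, spec, n_boot = 10000, seed = 20220830,
                         direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(n_boot >= 1)
  child <- .evaluate_subgroup(cohort_df, spec)
  parent <- if (!is.null(spec$parent)) .evaluate_subgroup(cohort_df, spec$parent)
            else rep(FALSE, nrow(cohort_df))
  gd <- as.logical(cohort_df$gd)
  if (anyNA(gd)) stop("gd status missing for some participants", call. = FALSE)
  n <- nrow(cohort_df)
  cnt <- .boot_strata(child, parent, gd)

  # observed counts (strata index: 1 + child + 2*parent + 4*gd)
  child_ca <- sum(cnt[c(6, 8)]); child_co <- sum(cnt[c(2, 4)])
  par_ca <- sum(cnt[c(7, 8)]); par_co <- sum(cnt[c(3, 4)])
  tot_ca <- sum(cnt[5:8]); tot_co <- sum(cnt[1:4])
  obs_child_lr <- .lr_from_counts(child_ca, child_co, tot_ca, tot_co)
  obs_parent_lr <- if (!is.null(spec$parent)) .lr_from_counts(par_ca, par_co, tot_ca, tot_co) else NA_real_

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  m <- stats::rmultinom(n_boot, n, cnt / n)           # 8 x n_boot
  b_child_ca <- m[6, ] + m[8, ]; b_child_co <- m[2, ] + m[4, ]
  b_par_ca <- m[7, ] + m[8, ];   b_par_co <- m[3, ] + m[4, ]
  b_tot_ca <- colSums(m[5:8, , drop = FALSE]); b_tot_co <- colSums(m[1:4, , drop = FALSE])
  ok <- (b_child_ca + b_child_co) > 0 & b_tot_ca > 0 & b_tot_co > 0
  if (!is.null(spec$parent)) ok <- ok & (b_par_ca + b_par_co) > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0.1 * n_boot) {
    warning(sprintf("%d of %d bootstrap replicates dropped (empty subgroup)",
                    n_dropped, n_boot))
  }
  lr_child <- .lr_from_counts(b_child_ca[ok], b_child_co[ok], b_tot_ca[ok], b_tot_co[ok])

  one_sided <- function(stat, ref, dir) {
    if (dir == "auto") dir <- if (stat_point >= ref_point) "greater" else "less"
    if (dir == "greater") (sum(stat < ref) + 0.5 * sum(stat == ref)) / length(stat)
    else                  (sum(stat > ref) + 0.5 * sum(stat == ref)) / length(stat)
  }
  dirs <- c(vs_all = NA_character_, vs_parent = NA_character_)

  # vs whole cohort: null LR value is 1
  stat_point <- obs_child_lr; ref_point <- 1
  dirs["vs_all"] <- if (direction == "auto") {
    if (obs_child_lr >= 1) "greater" else "less"
  } else direction
  p_vs_all <- one_sided(lr_child, 1, direction)

  p_vs_parent <- NA_real_
  if (!is.null(spec$parent)) {
    lr_parent <- .lr_from_counts(b_par_ca[ok], b_par_co[ok], b_tot_ca[ok], b_tot_co[ok])
    stat_point <- obs_child_lr; ref_point <- obs_parent_lr
    dirs["vs_parent"] <- if (direction == "auto") {
      if (obs_child_lr >= obs_parent_lr) "greater" else "less"
    } else direction
    p_vs_parent <- one_sided(lr_child, lr_parent, direction)
  }

  ci <- stats::quantile(lr_child, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(lr = obs_child_lr, parent_lr = obs_parent_lr,
                 ci_low = ci[1], ci_high = ci[2],
                 p_vs_all = p_vs_all, p_vs_parent = p_vs_parent,
                 n_boot = n_boot, n_dropped = n_dropped,
                 direction = dirs, seed = seed), class = "lr_result")
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.lr_result <- function(x, ...) {
  cat(sprintf("positive LR %.2f (95%% CI %.2f-%.2f), p_vs_all = %.3g%s [n_boot = %d]\n",
              x$lr, x$ci_low, x$ci_high, x$p_vs_all,
              if (!is.na(x$p_vs_parent)) sprintf(", p_vs_parent = %.3g", x$p_vs_parent) else "",
              x$n_boot))
  invisible(x)
}

#' Expand categorical counts into an individual-level cohort
#'
#' Turns cell counts over categorical flags into one row per participant, so
#' that printed contingency tables can be resampled and fitted like raw data.
#' Marginal tables recomputed from the output equal the input counts exactly.
#'
#' @param cells data.frame with columns `cases` and `controls` plus any
#'   logical flag columns (e.g. `prs_top25`, `prs_bottom25`, `mets_low`,
#'   `family_history`, `age_ge35`, `bmi_ge25`). Each row is one cell.
#' @param total Optional `c(cases, controls)` cohort totals; when supplied, a
#'   remainder cell with all flags `FALSE` is appended, and the listed cells
#'   must not exceed the totals.
#' @return A `gd_cohort` data.frame with `id`, `gd`, and the flag columns.
#' @export
from_counts <- function(cells, total = NULL) {
  stopifnot(is.data.frame(cells), all(c("cases", "controls") %in% names(cells)))
  if (any(cells$cases < 0) || any(cells$controls < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  flags <- setdiff(names(cells), c("cases", "controls"))
  for (f in flags) cells[[f]] <- as.logical(cells[[f]])
  if (!is.null(total)) {
    rem_ca <- total[1] - sum(cells$cases)
    rem_co <- total[2] - sum(cells$controls)
    if (rem_ca < 0 || rem_co < 0) {
      stop(sprintf("inconsistent nesting: cell counts (%d cases, %d controls) exceed totals (%d, %d)",
                   sum(cells$cases), sum(cells$controls), total[1], total[2]),
           call. = FALSE)
    }
    rem <- as.data.frame(c(stats::setNames(as.list(rep(FALSE, length(flags))), flags),
                           list(cases = rem_ca, controls = rem_co)))
    cells <- rbind(cells[, names(rem), drop = FALSE], rem)
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    n_ca <- cells$cases[i]; n_co <- cells$controls[i]
    if (n_ca + n_co == 0) return(NULL)
    out <- cells[rep(i, n_ca + n_co), flags, drop = FALSE]
    out$gd <- rep(c(TRUE, FALSE), c(n_ca, n_co))
    out
  }))
  if (is.null(rows)) rows <- cbind(cells[0, flags, drop = FALSE], gd = logical(0))
  rows$id <- if (nrow(rows)) sprintf("p%05d", seq_len(nrow(rows))) else character(0)
  rownames(rows) <- NULL
  cohort(rows, provenance = "expanded from categorical counts")
}

#' Read the published-table counts fixture
#'
#' Reads a JSON transcription of the subgroup contingency counts (cohort
#' totals, and per covariate family the parent counts plus child counts
#' within the parent).
#'
#' @param path JSON path; defaults to the fixture shipped with the package.
#' @return The parsed counts list.
#' @export
read_counts_json <- function(path = system.file("extdata", "tables_counts.json",
                                                package = "gdrisk")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Expand one covariate family (parent + nested child) to a cohort
#'
#' Builds the three-cell decomposition parent&child / parent&!child /
#' !parent from printed counts and expands it via [from_counts()]. The
#' child's flag outside the parent is left `FALSE`; it never enters the
#' parent-vs-child comparisons.
#'
#' @param parent_counts `c(cases, controls)` of the parent subgroup.
#' @param child_counts `c(cases, controls)` of the child within the parent.
#' @param total `c(cases, controls)` of the whole cohort.
#' @param parent_flag,child_flag Column names for the two memberships.
#' @return A `gd_cohort`.
#' @export
expand_family <- function(parent_counts, child_counts, total,
                          parent_flag = "parent", child_flag = "child") {
  if (any(child_counts > parent_counts)) {
    stop(sprintf("inconsistent nesting: child (%d/%d) exceeds parent (%d/%d)",
                 child_counts[1], child_counts[2],
                 parent_counts[1], parent_counts[2]), call. = FALSE)
  }
  cells <- data.frame(a = c(TRUE, TRUE), b = c(TRUE, FALSE),
                      cases = c(child_counts[1], parent_counts[1] - child_counts[1]),
                      controls = c(child_counts[2], parent_counts[2] - child_counts[2]))
  names(cells)[1:2] <- c(parent_flag, child_flag)
  from_counts(cells, total = total)
}

#' Subgroup analysis table (odds ratios and positive likelihood ratios)
#'
#' For each parent subgroup and its nested children, computes the OR against
#' the rest of the cohort (with Woolf CI and Fisher exact p), the positive LR
#' against the whole cohort, and bootstrap p-values (`p_vs_all`, and
#' `p_vs_parent` for children).
#'
#' @param counts The parsed counts list (see [read_counts_json()]): elements
#'   `total` (`cases`, `controls`) and one or more named families, each with
#'   `cases`, `controls` and a named `children` list of `[cases, controls]`.
#' @param n_boot Bootstrap replicates per row (0 skips bootstrap columns).
#' @param seed RNG seed.
#' @return data.frame, one row per subgroup, stable column order:
#'   `subgroup`, `parent`, `cases`, `controls`, `or`, `or_low`, `or_high`,
#'   `fisher_p`, `lr`, `lr_low`, `lr_high`, `p_vs_all`, `p_vs_parent`,
#'   `n_boot`, `seed`.
#' @export
subgroup_table <- function(counts, n_boot = 10000, seed = 20220830) {
  tot <- c(counts$total$cases, counts$total$controls)
  fam_names <- setdiff(names(counts), c("total", "provenance"))
  rows <- list()
  for (fam in fam_names) {
    f <- counts[[fam]]
    pc <- c(f$cases, f$controls)
    rows[[length(rows) + 1L]] <- .subgroup_row(fam, NA, pc, NULL, tot, n_boot, seed)
    for (ch in names(f$children)) {
      cc <- unlist(f$children[[ch]])
      rows[[length(rows) + 1L]] <- .subgroup_row(
        paste(fam, ch, sep = ":"), fam, cc, pc, tot, n_boot, seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.subgroup_row <- function(name, parent_name, cnt, parent_cnt, tot, n_boot, seed) {
  t <- two_by_two(cnt[1], cnt[2], tot[1] - cnt[1], tot[2] - cnt[2])
  orr <- odds_ratio(t)
  lr <- positive_lr(t, "whole_cohort")
  row <- data.frame(subgroup = name, parent = parent_name,
                    cases = cnt[1], controls = cnt[2],
                    or = orr$or, or_low = orr$ci_low, or_high = orr$ci_high,
                    fisher_p = orr$fisher_p, lr = lr,
                    lr_low = NA_real_, lr_high = NA_real_,
                    p_vs_all = NA_real_, p_vs_parent = NA_real_,
                    n_boot = n_boot, seed = seed, stringsAsFactors = FALSE)
  if (n_boot > 0) {
    if (is.null(parent_cnt)) {
      coh <- from_counts(data.frame(member = TRUE, cases = cnt[1], controls = cnt[2]),
                         total = tot)
      spec <- subgroup_spec(name, function(d) d$member)
    } else {
      coh <- expand_family(parent_cnt, cnt, tot, "in_parent", "in_child")
      par <- subgroup_spec(parent_name, function(d) d$in_parent)
      spec <- subgroup_spec(name, function(d) d$in_parent & d$in_child, parent = par)
    }
    b <- bootstrap_lr(coh, spec, n_boot = n_boot, seed = seed)
    row$lr_low <- b$ci_low; row$lr_high <- b$ci_high
    row$p_vs_all <- b$p_vs_all; row$p_vs_parent <- b$p_vs_parent
  }
  row
}

#' Write a subgroup results table as TSV
#' @param tab Output of [subgroup_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subgroup_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
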