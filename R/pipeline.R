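#' Pipeline run configuration
#'
#' Collects input paths, thresholds and reproducibility parameters for
#' [run_pipeline()]. All analysis thresholds default to the published values
#' and are never hard-coded in stage logic.
#'
#' @param phenotypes Path to the phenotype CSV (see [read_phenotypes()]).
#' @param dosages Path to a TSV dosage matrix (see [read_dosage_tsv()]);
#'   mutually exclusive with `vcf`.
#' @param vcf Path to a VCF (see [read_vcf_genotypes()]).
#' @param weights Path to the PRS weights TSV.
#' @param activity Optional path to an activity-log CSV (used when the
#'   phenotype file lacks a `mets` column).
#' @param counts Optional path to a counts JSON for the printed-table
#'   subgroup analysis.
#' @param out_dir Output directory.
#' @param seed RNG seed.
#' @param n_boot Bootstrap replicates for LR inference.
#' @param mets_threshold Activity dichotomization threshold.
#' @param qc Named list of QC thresholds (`max_missing`, `min_maf`,
#'   `min_hwe_p`, `min_call_rate`, `max_fhet`).
#' @return A `run_config` list.
#' @export
run_config <- function(phenotypes = NULL, dosages = NULL, vcf = NULL,
                       weights = NULL, activity = NULL, counts = NULL,
                       out_dir = tempdir(), seed = 20220830, n_boot = 10000,
                       mets_threshold = 450,
                       qc = list(max_missing = 0.02, min_maf = 0.01,
                                 min_hwe_p = 1e-6, min_call_rate = 0.98,
                                 max_fhet = 0.2)) {
  for (p in c(phenotypes, dosages, vcf, weights, activity, counts)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p,
                                             call. = FALSE)
  }
  stopifnot(seed == round(seed), n_boot >= 0, mets_threshold > 0)
  structure(as.list(environment()), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Composition of the library stages: load inputs, derive GD status, apply
#' the eligibility cascade, genotype QC, PRS and quartiles, METs
#' classification, subgroup OR/LR analysis, and the interaction fit. Stages
#' whose inputs are not configured are skipped. All results are returned and
#' written as TSV/JSON under `config$out_dir` together with a log of seed and
#' parameter values.
#'
#' @param config A [run_config()].
#' @return Named list of stage results (`cohort`, `exclusions`, `genotypes`,
#'   `prs`, `subgroups`, `interaction`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(paths = character(0))
  log <- c(sprintf("gdrisk %s", as.character(utils::packageVersion("gdrisk"))),
           sprintf("seed = %d, n_boot = %d, mets_threshold = %g",
                   config$seed, config$n_boot, config$mets_threshold),
           sprintf("qc: %s", paste(names(config$qc), unlist(config$qc),
                                   sep = "=", collapse = ", ")))

  g <- NULL
  if (!is.null(config$dosages) || !is.null(config$vcf)) {
    g <- .stage("load_genotypes", {
      if (!is.null(config$dosages)) read_dosage_tsv(config$dosages)
      else read_vcf_genotypes(config$vcf)
    })
    g <- .stage("qc", {
      g <- qc_filter_variants(g, config$qc$max_missing, config$qc$min_maf,
                              config$qc$min_hwe_p)
      qc_filter_samples(g, config$qc$min_call_rate, config$qc$max_fhet)
    })
    res$genotypes <- g
    log <- c(log, sprintf("genotypes after QC: %d variants x %d samples",
                          nrow(g$dosages), ncol(g$dosages)))
  }

  coh <- NULL
  if (!is.null(config$phenotypes)) {
    coh <- .stage("load_phenotypes", read_phenotypes(config$phenotypes))
    if (!is.null(config$activity) && all(is.na(coh$mets))) {
      am <- .stage("mets", read_activity_mets(config$activity, default_met_values()))
      coh$mets <- am$mets[match(coh$id, am$id)]
    }
    if (!is.null(g) && !is.null(config$weights)) {
      prs <- .stage("prs", compute_prs(g, read_weights(config$weights)))
      coh$prs <- as.numeric(prs)[match(coh$id, names(prs))]
      res$prs <- prs
      p <- file.path(config$out_dir, "prs_scores.tsv")
      write_scores(prs, p)
      res$paths <- c(res$paths, prs_scores = p)
    }
    coh <- .stage("eligibility", apply_eligibility(derive_gd(coh)))
    res$exclusions <- attr(coh, "exclusion_report")
    p <- file.path(config$out_dir, "exclusion_report.json")
    write_exclusion_report(coh, p)
    res$paths <- c(res$paths, exclusions = p)
    if (nrow(coh)) {
      qb <- quartile_bins(coh$prs)
      coh$prs_top25 <- qb$top25
      coh$prs_bottom25 <- qb$bottom25
      coh$prs_quartile <- qb$quartile
      coh$mets_low <- activity_class(coh$mets, config$mets_threshold) == "less_active"
    }
    res$cohort <- coh
    p <- file.path(config$out_dir, "analysis_cohort.csv")
    ph <- as.data.frame(coh); ph$gtt <- NULL
    utils::write.csv(ph, p, row.names = FALSE)
    res$paths <- c(res$paths, cohort = p)
    log <- c(log, sprintf("analysis cohort: %d participants (%d GD)",
                          nrow(coh), sum(coh$gd)))
  }

  if (!is.null(config$counts)) {
    counts <- .stage("load_counts", read_counts_json(config$counts))
    res$subgroups <- .stage("subgroups",
                            subgroup_table(counts, n_boot = config$n_boot,
                                           seed = config$seed))
  } else if (!is.null(coh) && nrow(coh) >= 100) {
    res$subgroups <- .stage("subgroups",
                            cohort_subgroup_table(coh, n_boot = config$n_boot,
                                                  seed = config$seed))
  }
  if (!is.null(res$subgroups)) {
    p <- file.path(config$out_dir, "subgroup_results.tsv")
    write_subgroup_table(res$subgroups, p)
    res$paths <- c(res$paths, subgroups = p)
  }

  if (!is.null(coh) && nrow(coh) >= 100) {
    res$interaction <- .stage("interaction", fit_interaction(coh, FALSE))
    p <- file.path(config$out_dir, "interaction_fit.json")
    write_interaction_report(res$interaction, p)
    res$paths <- c(res$paths, interaction = p)
    log <- c(log, sprintf("interaction f = %.3f (p = %.3g)",
                          res$interaction$f, res$interaction$p_f))
  }

  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  res$paths <- c(res$paths, log = file.path(config$out_dir, "run_log.txt"))
  res
}

#' Subgroup table computed from an individual-level cohort
#'
#' Mirrors the published table layout on a cohort with realized flags:
#' families are the PRS extreme quartiles and the METs classes, each with the
#' complementary covariate's children nested inside.
#'
#' @param cohort_df Cohort with `gd`, `prs_top25`, `prs_bottom25`, `mets_low`.
#' @param n_boot,seed Bootstrap parameters (see [bootstrap_lr()]).
#' @return data.frame in the [subgroup_table()] layout.
#' @export
cohort_subgroup_table <- function(cohort_df, n_boot = 10000, seed = 20220830) {
  fams <- list(
    prs_bottom25 = function(d) d$prs_bottom25,
    prs_top25 = function(d) d$prs_top25,
    mets_ge450 = function(d) !d$mets_low,
    mets_lt450 = function(d) d$mets_low
  )
  children <- list(
    prs_bottom25 = list(mets_lt450 = function(d) d$mets_low,
                        mets_ge450 = function(d) !d$mets_low),
    prs_top25 = list(mets_lt450 = function(d) d$mets_low,
                     mets_ge450 = function(d) !d$mets_low),
    mets_ge450 = list(prs_bottom25 = function(d) d$prs_bottom25,
                      prs_top25 = function(d) d$prs_top25),
    mets_lt450 = list(prs_bottom25 = function(d) d$prs_bottom25,
                      prs_top25 = function(d) d$prs_top25)
  )
  gd <- as.logical(cohort_df$gd)
  rows <- list()
  for (fam in names(fams)) {
    pspec <- subgroup_spec(fam, fams[[fam]])
    pm <- fams[[fam]](cohort_df)
    t <- make_table(cohort_df, pspec)
    rows[[length(rows) + 1L]] <- .cohort_row(cohort_df, fam, NA, pspec, n_boot, seed)
    for (ch in names(children[[fam]])) {
      chfun <- children[[fam]][[ch]]
      famfun <- fams[[fam]]
      cspec <- subgroup_spec(paste(fam, ch, sep = ":"),
                             local({ cf <- chfun; ff <- famfun
                                     function(d) ff(d) & cf(d) }),
                             parent = pspec)
      rows[[length(rows) + 1L]] <- .cohort_row(cohort_df, paste(fam, ch, sep = ":"),
                                               fam, cspec, n_boot, seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.cohort_row <- function(cohort_df, name, parent_name, spec, n_boot, seed) {
  t <- make_table(cohort_df, spec)
  orr <- odds_ratio(t)
  row <- data.frame(subgroup = name, parent = parent_name,
                    cases = t$cases_in, controls = t$controls_in,
                    or = orr$or, or_low = orr$ci_low, or_high = orr$ci_high,
                    fisher_p = orr$fisher_p,
                    lr = positive_lr(t, "whole_cohort"),
                    lr_low = NA_real_, lr_high = NA_real_,
                    p_vs_all = NA_real_, p_vs_parent = NA_real_,
                    n_boot = n_boot, seed = seed, stringsAsFactors = FALSE)
  if (n_boot > 0) {
    b <- bootstrap_lr(cohort_df, spec, n_boot = n_boot, seed = seed)
    row$lr_low <- b$ci_low; row$lr_high <- b$ci_high
    row$p_vs_all <- b$p_vs_all; row$p_vs_parent <- b$p_vs_parent
  }
  row
}
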