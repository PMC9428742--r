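#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of the study population: a
#' nulliparous cohort of 3533 with ~3.7% GD prevalence, age ~ N(28.6, 4.9^2)
#' years, BMI ~ N(24, 4.4^2) kg/m^2 (so that P(BMI >= 25) matches the ~41%
#' table margin), right-skewed weekly METs ~ lognormal with mean ~900 and SD
#' ~950 MET.min/wk, family-history prevalence 0.18, an 84-variant PRS panel,
#' and a logistic outcome model on (age, BMI, top-quartile PRS, low METs)
#' with a positive PRS-by-inactivity interaction (coefficients default to the
#' published adjusted fit; the intercept is solved to hit the prevalence
#' target).
#'
#' @param n Cohort size (>= 100).
#' @param seed Integer seed; child seeds for each component are derived by
#'   fixed offsets so adding a component never perturbs earlier draws.
#' @param prevalence_target Target GD prevalence (default 0.037).
#' @param age_mean,age_sd Age distribution (years).
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2).
#' @param mets_meanlog,mets_sdlog Lognormal METs parameters (defaults give
#'   mean ~900, SD ~950 MET.min/wk).
#' @param fam_hist_prob Family-history prevalence.
#' @param n_variants PRS panel size.
#' @param allele_freqs Optional per-variant effect-allele frequencies in
#'   (0, 1); drawn Uniform(0.05, 0.95) from the seed when NULL.
#' @param betas Optional per-variant weights; drawn |N(0.1, 0.04)| when NULL
#'   (giving a raw PRS with mean ~8.3 and SD ~0.55).
#' @param coef_age,coef_bmi,coef_prs,coef_mets,coef_interaction Outcome model
#'   coefficients (b, c, d, e, f).
#' @param mets_threshold Activity dichotomization threshold (MET.min/wk).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = 3533, seed = 20220830,
                             prevalence_target = 0.037,
                             age_mean = 28.6, age_sd = 4.9,
                             bmi_mean = 24, bmi_sd = 4.4,
                             mets_meanlog = 6.428, mets_sdlog = 0.865,
                             fam_hist_prob = 0.18,
                             n_variants = 84,
                             allele_freqs = NULL, betas = NULL,
                             coef_age = 0.10, coef_bmi = 0.08,
                             coef_prs = 0.41, coef_mets = 0.10,
                             coef_interaction = 0.78,
                             mets_threshold = 450) {
  stopifnot(n >= 100, prevalence_target > 0, prevalence_target < 1,
            fam_hist_prob > 0, fam_hist_prob < 1, n_variants >= 1)
  if (!is.null(allele_freqs)) {
    stopifnot(length(allele_freqs) == n_variants,
              all(allele_freqs > 0), all(allele_freqs < 1))
  }
  if (!is.null(betas)) stopifnot(length(betas) == n_variants, all(is.finite(betas)))
  structure(as.list(environment()), class = "synthetic_config")
}

# deterministic child-seed fan-out; offsets are fixed per component
.child_seed <- function(seed, offset) (abs(seed) %% 1000000000L) + offset

#' Simulate a cohort with genotypes and known generative truth
#'
#' Draws genotypes variant-wise as Binomial(2, freq), computes the PRS with
#' [compute_prs()], draws covariates from the configured marginals, derives
#' the top-quartile PRS and low-METs flags from the realized values, and
#' draws GD ~ Bernoulli(logit^-1(a + b age + c BMI + d X3 + e X4 + f X3 X4)),
#' where the intercept a is solved so the expected prevalence equals the
#' target. Byte-identical output under a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @param genotypes When `FALSE`, skip genotype simulation and draw the PRS
#'   directly from its implied normal approximation (fast path for large-n
#'   experiments that do not exercise the genetics module).
#' @return List with `cohort` (a `gd_cohort` including `prs_top25`,
#'   `mets_low` flags), `genotypes` (a `genotype_matrix` or NULL), and
#'   `truth` (generating parameters, including the solved intercept).
#' @export
simulate_cohort <- function(config = synthetic_config(), genotypes = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  # panel parameters (offset 1)
  set.seed(.child_seed(config$seed, 1L))
  freqs <- config$allele_freqs
  if (is.null(freqs)) freqs <- stats::runif(config$n_variants, 0.05, 0.95)
  betas <- config$betas
  if (is.null(betas)) betas <- abs(stats::rnorm(config$n_variants, 0.1, 0.04))

  # genotypes and PRS (offset 2)
  set.seed(.child_seed(config$seed, 2L))
  gmat <- NULL
  if (genotypes) {
    # non-palindromic pairs only, so scoring needs no strand caveats
    pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                   c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
    dos <- matrix(stats::rbinom(config$n_variants * n, 2, rep(freqs, n)),
                  nrow = config$n_variants, ncol = n)
    ref_alt <- pairs[sample.int(nrow(pairs), config$n_variants, replace = TRUE), ,
                     drop = FALSE]
    variants <- data.frame(
      rsid = sprintf("rs%06d", seq_len(config$n_variants)),
      chrom = sample(1:22, config$n_variants, replace = TRUE),
      pos = sample.int(1e8, config$n_variants),
      ref = ref_alt[, 1], alt = ref_alt[, 2],
      typed = TRUE, info = NA_real_, stringsAsFactors = FALSE
    )
    gmat <- genotype_matrix(dos, variants, samples = sprintf("S%05d", seq_len(n)))
    weights <- data.frame(rsid = variants$rsid,
                          effect_allele = variants$alt,
                          other_allele = variants$ref,
                          beta = betas, stringsAsFactors = FALSE)
    prs <- as.numeric(compute_prs(gmat, weights))
  } else {
    prs_mean <- sum(2 * freqs * betas)
    prs_sd <- sqrt(sum(betas^2 * 2 * freqs * (1 - freqs)))
    prs <- stats::rnorm(n, prs_mean, prs_sd)
    weights <- NULL
  }

  # covariates (offset 3)
  set.seed(.child_seed(config$seed, 3L))
  age <- pmax(16, stats::rnorm(n, config$age_mean, config$age_sd))
  bmi <- pmax(15, stats::rnorm(n, config$bmi_mean, config$bmi_sd))
  mets <- stats::rlnorm(n, config$mets_meanlog, config$mets_sdlog)
  fam <- stats::runif(n) < config$fam_hist_prob
  waist <- pmax(55, 2.2 * bmi + stats::rnorm(n, 28, 6))
  pcos <- stats::runif(n) < 0.07
  htn <- stats::runif(n) < 0.05

  qb <- quartile_bins(prs)
  x3 <- as.integer(qb$top25)
  x4 <- as.integer(mets < config$mets_threshold)

  # outcome (offset 4); intercept solved to the prevalence target
  eta0 <- config$coef_age * age + config$coef_bmi * bmi +
    config$coef_prs * x3 + config$coef_mets * x4 + config$coef_interaction * x3 * x4
  solve_fn <- function(a) mean(stats::plogis(a + eta0)) - config$prevalence_target
  a_int <- tryCatch(
    stats::uniroot(solve_fn, lower = -50, upper = 10, tol = 1e-10)$root,
    error = function(e) stop("unreachable prevalence target: intercept solve failed",
                             call. = FALSE)
  )
  set.seed(.child_seed(config$seed, 4L))
  gd <- stats::runif(n) < stats::plogis(a_int + eta0)

  coh <- cohort(data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age = age, bmi = bmi, waist = waist,
    family_history_diabetes = fam, pcos = pcos, hypertension = htn,
    prior_diabetes = FALSE, prediabetes = FALSE,
    clinical_gd_diagnosis = gd, mets = mets, prs = prs, gd = gd,
    prs_top25 = qb$top25, prs_bottom25 = qb$bottom25,
    prs_quartile = qb$quartile, mets_low = x4 == 1L,
    race_white = TRUE,
    stringsAsFactors = FALSE
  ), provenance = sprintf("synthetic cohort (n = %d, seed = %d)", n, config$seed))

  truth <- list(intercept = a_int, coef_age = config$coef_age,
                coef_bmi = config$coef_bmi, coef_prs = config$coef_prs,
                coef_mets = config$coef_mets,
                coef_interaction = config$coef_interaction,
                allele_freqs = freqs, betas = betas,
                prevalence_target = config$prevalence_target,
                seed = config$seed, weights = weights)
  list(cohort = coh, genotypes = gmat, truth = truth)
}

#' Mask entries completely at random
#'
#' Corrupts a copy of a genotype matrix (dosages and hard calls) or selected
#' cohort columns, masking each entry independently with probability `rate`,
#' and returns the truth mask for oracle checks.
#'
#' @param x A `genotype_matrix` or `gd_cohort`.
#' @param rate Missingness rate in [0, 1).
#' @param columns For cohorts, which columns to corrupt (default `"mets"`).
#' @param seed Integer seed.
#' @return List with the corrupted object (`data`) and the logical `mask`
#'   (matrix for genotypes; named list of logical vectors for cohorts).
#' @export
inject_missingness <- function(x, rate, columns = "mets", seed = 20220830) {
  stopifnot(rate >= 0, rate < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (inherits(x, "genotype_matrix")) {
    mask <- matrix(stats::runif(length(x$dosages)) < rate,
                   nrow = nrow(x$dosages), dimnames = dimnames(x$dosages))
    x$dosages[mask] <- NA
    x$hard_calls[mask] <- NA
    return(list(data = x, mask = mask))
  }
  if (inherits(x, "gd_cohort") || is.data.frame(x)) {
    masks <- list()
    for (cl in columns) {
      m <- stats::runif(nrow(x)) < rate
      x[[cl]][m] <- NA
      masks[[cl]] <- m
    }
    return(list(data = x, mask = masks))
  }
  stop("unsupported input type", call. = FALSE)
}

#' Write synthetic data in the pipeline's input dialects
#'
#' Emits the phenotype CSV, the dosage-matrix TSV, the PRS weights TSV, and
#' the generative truth record as JSON.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.csv"),
             dosages = file.path(dir, "dosages.tsv"),
             weights = file.path(dir, "weights.tsv"),
             truth = file.path(dir, "truth.json"))
  ph <- as.data.frame(sim$cohort)
  ph$gtt <- NULL
  utils::write.csv(ph, paths["phenotypes"], row.names = FALSE)
  if (!is.null(sim$genotypes)) {
    g <- sim$genotypes
    tab <- cbind(g$variants[, c("rsid", "chrom", "pos", "ref", "alt")],
                 as.data.frame(g$dosages))
    utils::write.table(tab, paths["dosages"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(sim$truth$weights)) {
    utils::write.table(sim$truth$weights, paths["weights"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  truth <- sim$truth
  truth$weights <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
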