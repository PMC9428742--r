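#' Genotype matrix container
#'
#' Variants in rows, samples in columns. Dosages are expected alternate-allele
#' counts in [0, 2] (`NA` = missing); hard calls are integer genotypes
#' {0, 1, 2}. For imputed variants, per-genotype maximum posterior
#' probabilities (`max_gp`) and a per-variant INFO score support the
#' imputation-quality filter.
#'
#' @param dosages Numeric matrix (variants x samples), entries in [0, 2] or NA.
#' @param variants data.frame with at least `rsid`; optional `chrom`, `pos`,
#'   `ref`, `alt`, `typed` (logical; FALSE = imputed), `info` (imputation
#'   quality in [0, 1]).
#' @param samples Character sample ids; defaults to `colnames(dosages)`.
#' @param hard_calls Optional integer matrix of called genotypes; defaults to
#'   rounded dosages.
#' @param max_gp Optional numeric matrix of per-genotype maximum posterior
#'   probabilities in [0, 1].
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, variants, samples = colnames(dosages),
                            hard_calls = NULL, max_gp = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(dosages)))
  stopifnot(is.data.frame(variants), "rsid" %in% names(variants),
            nrow(variants) == nrow(dosages), length(samples) == ncol(dosages))
  rng <- range(dosages, na.rm = TRUE)
  if (nrow(dosages) && any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (is.null(hard_calls)) hard_calls <- round(dosages)
  if (!"typed" %in% names(variants)) variants$typed <- TRUE
  if (!"info" %in% names(variants)) variants$info <- NA_real_
  dimnames(dosages) <- list(variants$rsid, samples)
  dimnames(hard_calls) <- dimnames(dosages)
  if (!is.null(max_gp)) dimnames(max_gp) <- dimnames(dosages)
  structure(list(dosages = dosages, hard_calls = hard_calls, max_gp = max_gp,
                 variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variants x %d samples (%d typed, %d imputed)\n",
              nrow(x$dosages), ncol(x$dosages),
              sum(x$variants$typed), sum(!x$variants$typed)))
  invisible(x)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on biallelic genotype counts: the p-value is the sum
#' of probabilities of all heterozygote counts (given the allele counts) no
#' more probable than the observed one. No mid-p correction is applied.
#'
#' @param n_het Observed heterozygote count.
#' @param n_hom1,n_hom2 Homozygote counts for the two alleles.
#' @return Exact p-value in [0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  # distribution of heterozygote count given allele counts (Levene/Haldane)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2          # rare homozygotes
    hc <- n - h - hr                # common homozygotes
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hr + 1) - lgamma(hc + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(n_rare + 1) - lgamma(2 * n - n_rare + 1))
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hets == n_het)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Per-variant QC statistics
#'
#' Missingness, minor allele frequency and exact HWE p-value, recomputed from
#' the stored calls (input metadata is never trusted).
#'
#' @param g A `genotype_matrix`.
#' @return data.frame with `rsid`, `missingness`, `maf`, `hwe_p`.
#' @export
variant_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  hc <- g$hard_calls
  miss <- rowMeans(is.na(g$dosages))
  p_alt <- rowMeans(g$dosages, na.rm = TRUE) / 2
  p_alt[is.nan(p_alt)] <- 0
  maf <- pmin(p_alt, 1 - p_alt)
  hwe <- vapply(seq_len(nrow(hc)), function(i) {
    v <- hc[i, ]; v <- v[!is.na(v)]
    if (!length(v)) return(1)
    hwe_exact_p(sum(v == 1), sum(v == 0), sum(v == 2))
  }, numeric(1))
  data.frame(rsid = g$variants$rsid, missingness = miss, maf = maf,
             hwe_p = hwe, stringsAsFactors = FALSE, row.names = NULL)
}

.subset_variants <- function(g, keep) {
  genotype_matrix(g$dosages[keep, , drop = FALSE],
                  g$variants[keep, , drop = FALSE],
                  g$samples,
                  hard_calls = g$hard_calls[keep, , drop = FALSE],
                  max_gp = if (!is.null(g$max_gp)) g$max_gp[keep, , drop = FALSE])
}

.subset_samples <- function(g, keep) {
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  g$variants,
                  g$samples[keep],
                  hard_calls = g$hard_calls[, keep, drop = FALSE],
                  max_gp = if (!is.null(g$max_gp)) g$max_gp[, keep, drop = FALSE])
}

#' Variant-level quality-control filter
#'
#' Retains variants with missingness <= `max_missing`, minor allele frequency
#' >= `min_maf`, and exact HWE p >= `min_hwe_p`. Statistics are recomputed
#' from the calls. The per-variant fate log is attached as attribute
#' `variant_fate` (columns `rsid`, `kept`, `reason`).
#'
#' @param g A `genotype_matrix`.
#' @param max_missing Maximum tolerated per-variant missingness (default 0.02).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @param min_hwe_p Minimum exact HWE p-value (default 1e-6).
#' @return Filtered `genotype_matrix`.
#' @export
qc_filter_variants <- function(g, max_missing = 0.02, min_maf = 0.01,
                               min_hwe_p = 1e-6) {
  st <- variant_stats(g)
  fail_miss <- st$missingness > max_missing
  fail_maf <- st$maf < min_maf
  fail_hwe <- st$hwe_p < min_hwe_p
  keep <- !(fail_miss | fail_maf | fail_hwe)
  reason <- rep("pass", nrow(st))
  reason[fail_hwe] <- "hwe"
  reason[fail_maf] <- "maf"
  reason[fail_miss] <- "missingness"   # first-listed reason wins
  if (!any(keep)) warning("no variants pass QC")
  out <- .subset_variants(g, keep)
  attr(out, "variant_fate") <- data.frame(rsid = st$rsid, kept = keep,
                                          reason = reason, stringsAsFactors = FALSE)
  out
}

#' Per-sample QC statistics
#'
#' Call rate, and the heterozygosity coefficient F_het = 1 - observed
#' heterozygosity / expected heterozygosity, where the expectation sums
#' 2 p (1 - p) over the variants called in that sample (p = cohort alternate
#' allele frequency).
#'
#' @param g A `genotype_matrix`.
#' @return data.frame with `sample`, `call_rate`, `f_het`.
#' @export
sample_stats <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  hc <- g$hard_calls
  call_rate <- colMeans(!is.na(hc))
  p <- rowMeans(g$dosages, na.rm = TRUE) / 2
  exp_het_v <- 2 * p * (1 - p)
  obs <- colSums(hc == 1, na.rm = TRUE)
  expd <- colSums(exp_het_v * !is.na(hc))
  f <- ifelse(expd > 0, 1 - obs / expd, 0)
  data.frame(sample = g$samples, call_rate = call_rate, f_het = f,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sample-level quality-control filter
#'
#' Retains samples with call rate >= `min_call_rate` and |F_het| <=
#' `max_fhet`.
#'
#' @param g A `genotype_matrix` (ideally after [qc_filter_variants()]).
#' @param min_call_rate Minimum genotype call rate (default 0.98).
#' @param max_fhet Maximum |F_het| (default 0.2).
#' @return Filtered `genotype_matrix`, with attribute `sample_fate`.
#' @export
qc_filter_samples <- function(g, min_call_rate = 0.98, max_fhet = 0.2) {
  st <- sample_stats(g)
  keep <- st$call_rate >= min_call_rate & abs(st$f_het) <= max_fhet
  if (sum(keep) < 2) warning("fewer than 2 samples retained by sample QC")
  out <- .subset_samples(g, keep)
  attr(out, "sample_fate") <- cbind(st, kept = keep)
  out
}

#' Imputation-quality filter
#'
#' Applies only to imputed variants (`typed == FALSE`): genotypes whose
#' maximum posterior probability is not greater than `min_genotype_prob` are
#' set to missing, and variants with INFO score not greater than `min_info`
#' or minor allele frequency not greater than `min_maf` are dropped. Directly
#' genotyped variants pass through untouched.
#'
#' @param g A `genotype_matrix` with `max_gp` and `variants$info` populated
#'   for imputed variants.
#' @param min_genotype_prob Genotype posterior threshold (default 0.80;
#'   strictly greater to keep).
#' @param min_info INFO score threshold (default 0.1; strictly greater to keep).
#' @param min_maf MAF threshold (default 0.005; strictly greater to keep).
#' @param per_variant If `TRUE`, the genotype-probability rule is applied as
#'   a per-variant aggregate (drop variants whose mean max posterior is not
#'   greater than the threshold) instead of per genotype.
#' @return Filtered `genotype_matrix`.
#' @export
filter_imputed <- function(g, min_genotype_prob = 0.80, min_info = 0.1,
                           min_maf = 0.005, per_variant = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  imp <- !g$variants$typed
  if (!any(imp)) return(g)
  if (is.null(g$max_gp) || any(is.na(g$variants$info[imp]))) {
    stop("imputed variants present without genotype-probability/INFO metadata",
         call. = FALSE)
  }
  if (per_variant) {
    low <- rowMeans(g$max_gp, na.rm = TRUE) <= min_genotype_prob & imp
  } else {
    mask <- imp & (g$max_gp <= min_genotype_prob)  # recycles imp by column
    mask[is.na(mask)] <- FALSE
    g$dosages[mask] <- NA
    g$hard_calls[mask] <- NA
    low <- rep(FALSE, nrow(g$dosages))
  }
  st <- variant_stats(g)
  drop <- imp & (g$variants$info <= min_info | st$maf <= min_maf) | low
  .subset_variants(g, !drop)
}

#' Read a PRS weights table
#'
#' TSV with header `rsid`, `effect_allele`, `other_allele`, `beta` and
#' optionally `info`.
#'
#' @param path TSV file path.
#' @return data.frame of variant weights.
#' @export
read_weights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("rsid", "effect_allele", "other_allele", "beta")
  if (!all(req %in% names(w))) {
    stop("weights file must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  validate_weights(w)
  w
}

#' Validate a PRS weights table
#' @param w data.frame of weights.
#' @return `w`, invisibly; errors on violation.
#' @export
validate_weights <- function(w) {
  ok_allele <- function(a) all(a %in% c("A", "C", "G", "T"))
  if (!ok_allele(w$effect_allele) || !ok_allele(w$other_allele)) {
    stop("alleles must be one of A, C, G, T", call. = FALSE)
  }
  if (any(w$effect_allele == w$other_allele)) {
    stop("effect and other allele must differ", call. = FALSE)
  }
  if (any(!is.finite(w$beta))) stop("beta must be finite", call. = FALSE)
  invisible(w)
}

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Weighted-allele polygenic risk score
#'
#' For each sample, the score is the sum over matched variants of the effect
#' (risk) allele dosage weighted by its beta coefficient. Orientation is
#' resolved by allele identity: when the effect allele equals the variant's
#' ALT allele the dosage is used as is; when it equals REF the dosage is
#' flipped (2 - dosage); otherwise the weight is dropped. Strand-ambiguous
#' palindromic pairs (A/T, C/G) are matched by identity with a warning.
#' Missing dosages are imputed as twice the cohort effect-allele frequency.
#' Scores are reported on the raw (unstandardized) scale.
#'
#' @param g A `genotype_matrix` whose `variants` include `ref` and `alt`.
#' @param weights data.frame as from [read_weights()].
#' @return Named numeric vector of per-sample scores, with attribute
#'   `match_report` (n_matched, n_flipped, n_dropped, n_imputed_entries,
#'   dropped rsids).
#' @export
compute_prs <- function(g, weights) {
  stopifnot(inherits(g, "genotype_matrix"))
  validate_weights(weights)
  if (!all(c("ref", "alt") %in% names(g$variants))) {
    stop("genotype matrix variants need 'ref' and 'alt' columns for allele matching",
         call. = FALSE)
  }
  idx <- match(weights$rsid, g$variants$rsid)
  found <- !is.na(idx)
  n_flipped <- 0L
  dropped <- weights$rsid[!found]
  scores <- stats::setNames(numeric(length(g$samples)), g$samples)
  n_imputed <- 0L
  pal <- character(0)
  for (k in which(found)) {
    i <- idx[k]
    ref <- g$variants$ref[i]; alt <- g$variants$alt[i]
    ea <- weights$effect_allele[k]; oa <- weights$other_allele[k]
    if (ea == alt && oa == ref) {
      dos <- g$dosages[i, ]
    } else if (ea == ref && oa == alt) {
      dos <- 2 - g$dosages[i, ]
      n_flipped <- n_flipped + 1L
    } else {
      dropped <- c(dropped, weights$rsid[k])
      next
    }
    if (.is_palindromic(ea, oa)) pal <- c(pal, weights$rsid[k])
    if (anyNA(dos)) {
      eaf <- mean(dos, na.rm = TRUE) / 2
      if (is.nan(eaf)) eaf <- 0
      n_imputed <- n_imputed + sum(is.na(dos))
      dos[is.na(dos)] <- 2 * eaf
    }
    scores <- scores + weights$beta[k] * dos
  }
  n_matched <- nrow(weights) - length(dropped)
  if (length(pal)) {
    warning("strand-ambiguous palindromic variants matched by allele identity: ",
            paste(pal, collapse = ", "))
  }
  if (n_matched < 0.5 * nrow(weights)) {
    stop(sprintf("only %d of %d weight variants matched (<50%%); likely a genome-build or naming mismatch",
                 n_matched, nrow(weights)), call. = FALSE)
  }
  attr(scores, "match_report") <- list(
    n_matched = n_matched, n_flipped = n_flipped,
    n_dropped = length(dropped), n_imputed_entries = n_imputed,
    dropped = dropped
  )
  scores
}

#' Quartile bins for PRS (or any score)
#'
#' Cut points at the 25th/50th/75th percentiles (quantile type 7); samples
#' exactly at a cut point go to the lower bin. Q1 is the lowest quartile.
#'
#' @param scores Numeric vector (>= 4 values).
#' @return data.frame with `sample` (names of `scores`, or index), `score`,
#'   `quartile` (factor Q1-Q4), `top25`, `bottom25`.
#' @export
quartile_bins <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 4, all(is.finite(scores)))
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
  if (length(unique(q)) < 3 && stats::var(scores) == 0) {
    warning("constant scores: all samples assigned to Q1")
    lab <- rep("Q1", length(scores))
  } else {
    lab <- ifelse(scores <= q[1], "Q1",
           ifelse(scores <= q[2], "Q2",
           ifelse(scores <= q[3], "Q3", "Q4")))
  }
  qt <- factor(lab, levels = paste0("Q", 1:4))
  data.frame(sample = if (!is.null(names(scores))) names(scores) else seq_along(scores),
             score = as.numeric(scores), quartile = qt,
             top25 = qt == "Q4", bottom25 = qt == "Q1",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write PRS scores as TSV
#' @param scores Output of [compute_prs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  b <- quartile_bins(scores)
  utils::write.table(data.frame(sample_id = b$sample, prs = b$score,
                                quartile = b$quartile),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV dosage matrix
#'
#' Dialect: first columns `rsid`, `ref`, `alt` (and optionally `chrom`,
#' `pos`, `typed`, `info`), then one numeric dosage column per sample.
#'
#' @param path TSV file path.
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("rsid", "chrom", "pos", "ref", "alt", "typed", "info"),
                         names(d))
  samp_cols <- setdiff(names(d), meta_cols)
  genotype_matrix(as.matrix(d[, samp_cols, drop = FALSE]),
                  d[, meta_cols, drop = FALSE], samples = samp_cols)
}

#' Read genotypes from a VCF
#'
#' Uses the DS (dosage) FORMAT field when present, otherwise alternate-allele
#' counts from GT. The imputation-quality score is read from the INFO column
#' under `info_key`. Requires the VariantAnnotation package.
#'
#' @param path VCF file path.
#' @param info_key INFO column key holding the imputation quality
#'   (`"INFO"` or `"R2"` in common pipelines).
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path, info_key = c("INFO", "R2")) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf_genotypes() requires the VariantAnnotation package", call. = FALSE)
  }
  info_key <- match.arg(info_key)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno)) {
    dos <- geno$DS
    storage.mode(dos) <- "double"
  } else if ("GT" %in% names(geno)) {
    gt <- geno$GT
    dos <- apply(gt, c(1, 2), function(x) {
      if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
    })
  } else stop("VCF has neither DS nor GT genotype fields", call. = FALSE)
  info_df <- VariantAnnotation::info(vcf)
  info_score <- if (info_key %in% names(info_df)) as.numeric(info_df[[info_key]]) else NA_real_
  typed <- if ("TYPED" %in% names(info_df)) {
    !is.na(info_df$TYPED) & as.logical(info_df$TYPED)
  } else rep(TRUE, length(rr))
  variants <- data.frame(
    rsid = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(seq_along(rr), function(i) as.character(rr$ALT[[i]][1]), character(1)),
    typed = typed, info = info_score,
    stringsAsFactors = FALSE
  )
  max_gp <- if ("GP" %in% names(geno)) {
    gp <- geno$GP
    apply(gp, c(1, 2), function(x) if (all(is.na(unlist(x)))) NA_real_ else max(unlist(x), na.rm = TRUE))
  }
  genotype_matrix(dos, variants, samples = colnames(dos), max_gp = max_gp)
}
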