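# Shared builders for small in-code fixtures.

# toy genotype matrix: dosages supplied as a variants x samples matrix
toy_genotypes <- function(dosages, ref = "A", alt = "G", typed = TRUE,
                          info = NA_real_, max_gp = NULL) {
  nv <- nrow(dosages)
  variants <- data.frame(
    rsid = sprintf("rs%03d", seq_len(nv)),
    chrom = 1L, pos = seq_len(nv) * 100L,
    ref = rep_len(ref, nv), alt = rep_len(alt, nv),
    typed = rep_len(typed, nv), info = rep_len(info, nv),
    stringsAsFactors = FALSE
  )
  genotype_matrix(dosages, variants,
                  samples = sprintf("S%02d", seq_len(ncol(dosages))),
                  max_gp = max_gp)
}

# minimal participant frame for cohort()
toy_participants <- function(n, ...) {
  d <- data.frame(id = sprintf("P%03d", seq_len(n)),
                  age = 28, bmi = 24, mets = 500, prs = 1,
                  clinical_gd_diagnosis = FALSE,
                  stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) d[[nm]] <- extra[[nm]]
  d
}

# the four PRS x METs design cells from the published joint table
table2_cells <- function() {
  data.frame(prs_top25 = c(TRUE, TRUE, FALSE, FALSE),
             mets_low = c(TRUE, FALSE, TRUE, FALSE),
             cases = c(31, 24, 27, 50),
             controls = c(278, 551, 832, 1740))
}

# independent Fisher two-sided p by full hypergeometric enumeration
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b            # row 1 total (in-subgroup)
  n_ <- c + d           # row 2 total
  k <- a + c            # column total (cases)
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force per-sample PRS accumulation (effect allele == alt everywhere)
prs_brute_force <- function(dosages, betas) {
  vapply(seq_len(ncol(dosages)), function(j) {
    s <- 0
    for (i in seq_len(nrow(dosages))) s <- s + betas[i] * dosages[i, j]
    s
  }, numeric(1))
}
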