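#!/usr/bin/env Rscript
# Genotype QC and polygenic risk scoring on the simulated inputs from
# 01_simulate.R: variant filters (missingness <= 0.02, MAF >= 0.01, exact HWE
# p >= 1e-6), sample filters (call rate >= 0.98, |F_het| <= 0.2), then the
# beta-weighted risk-allele score and its quartiles.

suppressPackageStartupMessages(library(gdrisk))
if (!file.exists("results/synthetic_inputs/dosages.tsv")) {
  stop("run analysis/01_simulate.R first")
}

g <- read_dosage_tsv("results/synthetic_inputs/dosages.tsv")
w <- read_weights("results/synthetic_inputs/weights.tsv")

gv <- qc_filter_variants(g)
fate <- attr(gv, "variant_fate")
gs <- qc_filter_samples(gv)
sfate <- attr(gs, "sample_fate")

prs <- compute_prs(gs, w)
rep <- attr(prs, "match_report")
write_scores(prs, "results/02_prs_scores.tsv")
write.table(fate, "results/02_variant_fate.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sfate, "results/02_sample_fate.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Variant QC: %d of %d retained (%s).\n",
            nrow(gv$dosages), nrow(g$dosages),
            paste(names(table(fate$reason)), table(fate$reason),
                  sep = "=", collapse = ", ")))
cat(sprintf("Sample QC: %d of %d retained.\n", ncol(gs$dosages), ncol(g$dosages)))
cat(sprintf("PRS: %d/%d weight variants matched (%d flipped, %d dropped); mean %.2f, SD %.2f.\n",
            rep$n_matched, nrow(w), rep$n_flipped, rep$n_dropped,
            mean(prs), sd(prs)))
cat("Scores in results/02_prs_scores.tsv; fate logs in results/02_*_fate.tsv\n")
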