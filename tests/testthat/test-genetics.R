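test_that("exact HWE p matches a Monte Carlo allele-pairing oracle", {
  set.seed(41)
  cases <- list(c(het = 5, hom1 = 12, hom2 = 3),
                c(het = 1, hom1 = 10, hom2 = 9),
                c(het = 14, hom1 = 3, hom2 = 3))
  for (cs in cases) {
    n <- sum(cs)
    n_rare_allele <- 2 * min(cs["hom1"], cs["hom2"]) + cs["het"]
    # oracle: draw random pairings of the 2n alleles, observe het counts
    alleles <- rep(c(1, 0), c(n_rare_allele, 2 * n - n_rare_allele))
    hets <- replicate(20000, {
      a <- sample(alleles)
      sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
    })
    pmf <- table(factor(hets, levels = 0:n)) / length(hets)
    p_obs <- pmf[[as.character(cs["het"])]]
    p_mc <- sum(pmf[pmf <= p_obs * (1 + 1e-9)])
    expect_equal(hwe_exact_p(cs["het"], cs["hom1"], cs["hom2"]), p_mc,
                 tolerance = 0.03)
  }
  # degenerate cases
  expect_equal(hwe_exact_p(0, 10, 0), 1)
  expect_equal(hwe_exact_p(0, 0, 0), 1)
})

test_that("variant QC removes the documented violations", {
  set.seed(42)
  n <- 100
  # 60 well-behaved variants near HWE
  dos <- t(sapply(1:60, function(i) rbinom(n, 2, runif(1, 0.2, 0.8))))
  g_ok <- toy_genotypes(dos)
  # variant with 3/100 missing calls (missingness 0.03 > 0.02) -> removed
  v_miss <- rbinom(n, 2, 0.5); v_miss[1:3] <- NA
  # monomorphic variant (MAF 0) -> removed
  v_mono <- rep(0L, n)
  # gross HWE violation: all heterozygous at allele frequency 0.5
  v_hwe <- rep(1L, n)
  g <- toy_genotypes(rbind(dos, v_miss, v_mono, v_hwe))
  filtered <- qc_filter_variants(g)
  fate <- attr(filtered, "variant_fate")
  expect_equal(nrow(filtered$dosages), 60)
  expect_equal(fate$reason[61:63], c("missingness", "maf", "hwe"))

  # brute-force oracle over the three predicates
  st <- variant_stats(g)
  keep_bf <- st$missingness <= 0.02 & st$maf >= 0.01 & st$hwe_p >= 1e-6
  expect_equal(fate$kept, keep_bf)
})

test_that("sample QC applies call-rate and F_het rules", {
  set.seed(43)
  nv <- 100
  dos <- matrix(rbinom(nv * 20, 2, 0.5), nrow = nv)
  # sample 1: 5 missing genotypes of 100 -> call rate 0.95 < 0.98
  dos[1:5, 1] <- NA
  # sample 2: fully homozygous at MAF ~0.5 loci -> F_het near 1
  dos[, 2] <- rbinom(nv, 1, 0.5) * 2
  g <- toy_genotypes(dos)
  st <- sample_stats(g)
  expect_lt(st$call_rate[1], 0.98)
  expect_gt(st$f_het[2], 0.8)
  filtered <- qc_filter_samples(g)
  expect_false(any(c("S01", "S02") %in% filtered$samples))
  # brute-force oracle over the two sample predicates
  keep_bf <- st$call_rate >= 0.98 & abs(st$f_het) <= 0.2
  expect_equal(filtered$samples, g$samples[keep_bf])
  # a fully typed sample in HWE has F_het near 0 and is retained
  expect_lt(abs(st$f_het[3]), 0.2)
  expect_true("S03" %in% filtered$samples)
})

test_that("imputation filter drops low-INFO variants and masks low-GP calls", {
  set.seed(44)
  n <- 50
  dos <- matrix(rbinom(4 * n, 2, 0.4), nrow = 4)
  gp <- matrix(0.99, nrow = 4, ncol = n)
  gp[2, 1:10] <- 0.6  # low-confidence genotypes on variant 2
  g <- toy_genotypes(dos, typed = c(TRUE, FALSE, FALSE, FALSE),
                     info = c(NA, 0.9, 0.05, 0.9), max_gp = gp)
  out <- filter_imputed(g)
  # INFO 0.05 <= 0.1 -> dropped; typed variant untouched
  expect_false("rs003" %in% out$variants$rsid)
  expect_true("rs001" %in% out$variants$rsid)
  expect_equal(sum(is.na(out$dosages["rs002", ])), 10)
  expect_equal(out$dosages["rs001", ], g$dosages["rs001", ])

  # brute-force predicate oracle on the retained set
  masked <- g
  masked$dosages[2, 1:10] <- NA
  st <- variant_stats(toy_genotypes(masked$dosages))
  keep_bf <- g$variants$typed | (g$variants$info > 0.1 & st$maf > 0.005)
  expect_equal(out$variants$rsid, g$variants$rsid[keep_bf])

  # metadata absent for an imputed variant is a validation error
  g_bad <- toy_genotypes(dos, typed = FALSE, info = NA_real_, max_gp = gp)
  expect_error(filter_imputed(g_bad), "metadata")
})

test_that("PRS is the beta-weighted effect-allele dosage sum", {
  g <- toy_genotypes(matrix(c(2, 1), nrow = 2), ref = "A", alt = "G")
  w <- data.frame(rsid = c("rs001", "rs002"), effect_allele = "G",
                  other_allele = "A", beta = c(0.1, 0.2))
  expect_equal(as.numeric(compute_prs(g, w)), 0.4)
  # zero effect alleles everywhere -> zero score
  g0 <- toy_genotypes(matrix(0, nrow = 2, ncol = 3), ref = "A", alt = "G")
  expect_equal(as.numeric(compute_prs(g0, w)), c(0, 0, 0))
})

test_that("PRS matches brute-force accumulation on a random 84-variant panel", {
  set.seed(45)
  nv <- 84; ns <- 30
  dos <- matrix(rbinom(nv * ns, 2, runif(nv, 0.1, 0.9)), nrow = nv)
  g <- toy_genotypes(dos, ref = "C", alt = "T")
  betas <- rnorm(nv, 0.1, 0.05)
  w <- data.frame(rsid = g$variants$rsid, effect_allele = "T",
                  other_allele = "C", beta = betas)
  expect_equal(as.numeric(compute_prs(g, w)), prs_brute_force(dos, betas))
})

test_that("PRS is linear in the weights and respects the allele-flip identity", {
  set.seed(46)
  nv <- 20; ns <- 15
  dos <- matrix(rbinom(nv * ns, 2, 0.5), nrow = nv)
  g <- toy_genotypes(dos, ref = "A", alt = "C")
  betas <- rnorm(nv, 0, 0.2)
  w <- data.frame(rsid = g$variants$rsid, effect_allele = "C",
                  other_allele = "A", beta = betas)
  s1 <- compute_prs(g, w)
  s2 <- compute_prs(g, transform(w, beta = 2 * beta))
  expect_equal(as.numeric(s2), 2 * as.numeric(s1))
  # flipping effect/other and negating beta shifts every score by -2*sum(beta):
  # -beta * (2 - dosage) = beta * dosage - 2 * beta
  w_flip <- data.frame(rsid = w$rsid, effect_allele = "A",
                       other_allele = "C", beta = -betas)
  s3 <- compute_prs(g, w_flip)
  expect_equal(as.numeric(s3), as.numeric(s1) - 2 * sum(betas))
})

test_that("PRS orientation: flipped, dropped and missing-dosage handling", {
  dos <- matrix(c(2, 1, 0,
                  0, 1, 2,
                  1, NA, 1), nrow = 3, byrow = TRUE)
  g <- toy_genotypes(dos, ref = c("A", "A", "A"), alt = c("G", "G", "G"))
  w <- data.frame(rsid = c("rs001", "rs002", "rs003", "rs999"),
                  effect_allele = c("G", "A", "G", "G"),
                  other_allele = c("A", "G", "A", "A"),
                  beta = c(1, 1, 1, 1))
  s <- suppressWarnings(compute_prs(g, w))
  rep <- attr(s, "match_report")
  expect_equal(rep$n_matched, 3)
  expect_equal(rep$n_flipped, 1)
  expect_equal(rep$n_dropped, 1)
  # rs002 flipped: dosage(A) = 2 - dosage(G); rs003 missing entry imputed at
  # 2 x effect-allele frequency = mean of observed dosages
  eaf2 <- mean(c(1, 1)) / 2
  expect_equal(as.numeric(s), c(2 + 2 + 1, 1 + 1 + 2 * eaf2, 0 + 0 + 1))
  # <50% matched guard
  w_bad <- data.frame(rsid = c("rsX", "rsY", "rsZ"),
                      effect_allele = "G", other_allele = "A", beta = 1)
  expect_error(compute_prs(g, w_bad), "50%")
})

test_that("palindromic variants are scored with a warning", {
  g <- toy_genotypes(matrix(c(2, 1), nrow = 1), ref = "A", alt = "T")
  w <- data.frame(rsid = "rs001", effect_allele = "T", other_allele = "A",
                  beta = 0.5)
  expect_warning(s <- compute_prs(g, w), "palindromic")
  expect_equal(as.numeric(s), c(1, 0.5))
})

test_that("quartile bins split symmetric inputs and honor the tie rule", {
  b <- quartile_bins(1:8)
  expect_equal(as.character(b$quartile), c("Q1","Q1","Q2","Q2","Q3","Q3","Q4","Q4"))
  expect_equal(b$top25, b$quartile == "Q4")
  expect_equal(b$bottom25, b$quartile == "Q1")
  # value exactly at a cut point goes to the lower bin
  x <- c(1, 2, 3, 4)  # q25 = 1.75, q50 = 2.5, q75 = 3.25
  expect_equal(as.character(quartile_bins(x)$quartile), c("Q1","Q2","Q3","Q4"))
  x2 <- c(0, 1, 1, 2)  # q25 exactly 0.75? no: quantile(type 7) = 0.75 -> check tie at q50 = 1
  expect_equal(as.character(quartile_bins(c(0, 1, 1, 2))$quartile)[2:3], c("Q2", "Q2"))
  expect_warning(bc <- quartile_bins(rep(5, 8)), "constant")
  expect_true(all(bc$quartile == "Q1"))
})

test_that("quartile occupancy matches a sort-and-split oracle on 1000 draws", {
  set.seed(47)
  s <- rnorm(1000)
  b <- quartile_bins(s)
  expect_equal(unname(table(b$quartile)), rep(250L, 4), ignore_attr = TRUE)
  # oracle: sort and split into four blocks of 250
  ord <- order(s)
  oracle <- integer(1000)
  oracle[ord] <- rep(1:4, each = 250)
  expect_equal(as.integer(b$quartile), oracle)
})

test_that("QC filters commute with variant and sample permutations", {
  set.seed(48)
  nv <- 30; ns <- 40
  dos <- matrix(rbinom(nv * ns, 2, runif(nv, 0.05, 0.95)), nrow = nv)
  dos[sample(length(dos), 60)] <- NA
  g <- toy_genotypes(dos)
  pv <- sample(nv); ps <- sample(ns)
  g_perm <- genotype_matrix(dos[pv, ps], g$variants[pv, ], g$samples[ps])
  f1 <- qc_filter_variants(g)
  f2 <- qc_filter_variants(g_perm)
  expect_setequal(f2$variants$rsid, f1$variants$rsid)
  s1 <- qc_filter_samples(f1)
  s2 <- qc_filter_samples(f2)
  expect_setequal(s2$samples, s1$samples)
})

test_that("dosage TSV and weights TSV round-trip through the readers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tref\talt\tS1\tS2",
               "rs001\tA\tG\t2\t1",
               "rs002\tC\tT\t0\tNA"), path)
  g <- read_dosage_tsv(path)
  expect_equal(dim(g$dosages), c(2L, 2L))
  expect_true(is.na(g$dosages["rs002", "S2"]))
  wpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\teffect_allele\tother_allele\tbeta",
               "rs001\tG\tA\t0.12"), wpath)
  w <- read_weights(wpath)
  expect_equal(w$beta, 0.12)
  expect_error(read_weights(path), "columns")
})

test_that("VCF genotypes load via DS or GT with INFO scores", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trs001\tA\tG\t.\tPASS\tR2=0.95\tGT:DS\t0/1:1.1\t1/1:1.9",
    "1\t200\trs002\tC\tT\t.\tPASS\tR2=0.80\tGT:DS\t0/0:0.1\t0/1:0.8"
  ), vcf)
  g <- read_vcf_genotypes(vcf, info_key = "R2")
  expect_equal(dim(g$dosages), c(2L, 2L))
  expect_equal(unname(g$dosages[1, ]), c(1.1, 1.9))
  expect_equal(g$variants$info, c(0.95, 0.80))
  expect_equal(g$variants$alt, c("G", "T"))
})
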