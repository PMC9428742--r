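test_that("make_table counts subgroup and remainder against GD status", {
  # family-history subgroup reconstructed from the printed counts
  coh <- expand_family(c(45, 591), c(16, 172), c(132, 3401),
                       "family_history", "prs_top25")
  t <- make_table(coh, subgroup_spec("fh", function(d) d$family_history))
  expect_equal(unclass(t)[c("cases_in", "controls_in", "cases_out", "controls_out")],
               list(cases_in = 45, controls_in = 591,
                    cases_out = 87, controls_out = 2810))
  # subgroup = everyone -> empty complement
  t_all <- make_table(coh, subgroup_spec("all", function(d) rep(TRUE, nrow(d))))
  expect_equal(t_all$cases_in, 132)
  expect_equal(t_all$controls_in, 3401)
  expect_equal(t_all$cases_out + t_all$controls_out, 0)
})

test_that("make_table equals a brute-force double loop on random predicates", {
  set.seed(51)
  sim <- simulate_cohort(synthetic_config(n = 400, seed = 7), genotypes = FALSE)
  coh <- sim$cohort
  for (rep in 1:5) {
    cut <- stats::runif(1, 20, 35)
    spec <- subgroup_spec("bmi_cut", local({ cc <- cut; function(d) d$bmi >= cc }))
    t <- make_table(coh, spec)
    a <- b <- cc2 <- d2 <- 0L
    for (i in seq_len(nrow(coh))) {
      inside <- coh$bmi[i] >= cut
      if (inside && coh$gd[i]) a <- a + 1L
      else if (inside) b <- b + 1L
      else if (coh$gd[i]) cc2 <- cc2 + 1L
      else d2 <- d2 + 1L
    }
    expect_equal(c(t$cases_in, t$controls_in, t$cases_out, t$controls_out),
                 c(a, b, cc2, d2))
  }
  # unevaluable predicate names the participant
  coh$bmi[3] <- NA
  expect_error(make_table(coh, subgroup_spec("x", function(d) d$bmi > 25)),
               coh$id[3])
})

test_that("odds ratio, Woolf CI and Fisher p behave on canonical tables", {
  r <- odds_ratio(two_by_two(45, 591, 87, 2810))
  expect_equal(round(r$or, 1), 2.5)
  expect_equal(round(r$ci_low, 1), 1.7)
  expect_equal(round(r$ci_high, 1), 3.6)
  sym <- odds_ratio(two_by_two(10, 10, 10, 10))
  expect_equal(sym$or, 1)
  expect_equal(sym$fisher_p, 1)
  # zero cell triggers the Haldane correction and is flagged
  h <- odds_ratio(two_by_two(0, 10, 5, 10))
  expect_true(h$haldane)
  expect_equal(h$or, (0.5 / 10.5) / (5.5 / 10.5))
  expect_error(odds_ratio(two_by_two(0, 0, 5, 10)), "margin")
})

test_that("Fisher p equals full hypergeometric enumeration on small tables", {
  set.seed(52)
  for (rep in 1:40) {
    cells <- rbinom(4, 6, 0.5)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    expect_equal(odds_ratio(t)$fisher_p,
                 fisher_p_enum(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-7)
  }
})

test_that("OR and LR are invariant under scaling all cells", {
  set.seed(53)
  for (rep in 1:10) {
    cells <- rbinom(4, 30, 0.5) + 1
    k <- sample(2:5, 1)
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t2 <- two_by_two(k * cells[1], k * cells[2], k * cells[3], k * cells[4])
    expect_equal(odds_ratio(t2)$or, odds_ratio(t1)$or)
    expect_equal(positive_lr(t2, "whole_cohort"), positive_lr(t1, "whole_cohort"))
  }
})

test_that("positive LR is posterior over prior odds", {
  # family history vs the whole cohort
  t <- two_by_two(45, 591, 87, 2810)
  expect_equal(round(positive_lr(t, "whole_cohort"), 1), 2.0)
  expect_equal(positive_lr(t, "whole_cohort"), (45 / 591) / (132 / 3401))
  # subgroup identical to the reference has LR 1
  t_id <- two_by_two(50, 450, 0, 0)
  expect_equal(positive_lr(t_id, "whole_cohort"), 1)
  # parent reference uses the parent's own odds
  parent <- two_by_two(45, 591, 87, 2810)
  child <- two_by_two(16, 172, 116, 3229)
  expect_equal(positive_lr(child, "parent", parent), (16 / 172) / (45 / 591))
  # random nested tables match the hand formula
  set.seed(54)
  for (rep in 1:10) {
    A <- sample(5:50, 1); B <- sample(50:500, 1)
    a <- sample.int(A, 1); b <- sample.int(B, 1)
    expect_equal(positive_lr(two_by_two(a, b, 99, 999), "parent",
                             two_by_two(A, B, 9, 9)),
                 (a / b) / (A / B))
  }
  expect_warning(lr_inf <- positive_lr(two_by_two(5, 0, 10, 100), "whole_cohort"),
                 "infinite")
  expect_equal(lr_inf, Inf)
})

test_that("a subgroup and its complement straddle LR = 1", {
  set.seed(55)
  for (rep in 1:20) {
    cells <- rbinom(4, 40, 0.5) + 1
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t_c <- two_by_two(cells[3], cells[4], cells[1], cells[2])
    lrs <- c(positive_lr(t, "whole_cohort"), positive_lr(t_c, "whole_cohort"))
    expect_true(max(lrs) >= 1 && min(lrs) <= 1)
  }
})

test_that("from_counts round-trips consistent counts", {
  cells <- table2_cells()
  coh <- from_counts(cells)
  expect_equal(nrow(coh), 3533)
  t <- make_table(coh, subgroup_spec("top", function(d) d$prs_top25))
  expect_equal(c(t$cases_in, t$controls_in), c(55, 829))
  # randomized consistent count sets round-trip
  set.seed(56)
  for (rep in 1:10) {
    rc <- data.frame(flag_a = c(TRUE, TRUE, FALSE, FALSE),
                     flag_b = c(TRUE, FALSE, TRUE, FALSE),
                     cases = rbinom(4, 40, 0.5),
                     controls = rbinom(4, 400, 0.5))
    coh2 <- from_counts(rc)
    for (i in 1:4) {
      m <- coh2$flag_a == rc$flag_a[i] & coh2$flag_b == rc$flag_b[i]
      expect_equal(sum(m & coh2$gd), rc$cases[i])
      expect_equal(sum(m & !coh2$gd), rc$controls[i])
    }
  }
  # empty counts give an empty cohort
  expect_equal(nrow(from_counts(data.frame(flag = logical(0),
                                           cases = integer(0),
                                           controls = integer(0)))), 0)
  # inconsistent nesting is named
  expect_error(from_counts(data.frame(flag = TRUE, cases = 200, controls = 10),
                           total = c(132, 3401)), "inconsistent nesting")
  expect_error(expand_family(c(10, 100), c(12, 90), c(132, 3401)),
               "inconsistent nesting")
})

test_that("bootstrap p is near 0.5 when child equals parent", {
  coh <- expand_family(c(50, 450), c(50, 450), c(132, 3401), "par", "chi")
  par <- subgroup_spec("par", function(d) d$par)
  sp <- subgroup_spec("chi", function(d) d$par & d$chi, parent = par)
  b <- bootstrap_lr(coh, sp, n_boot = 10000, seed = 99)
  # exchangeable null: p within 3 binomial SEs of 0.5
  expect_lt(abs(b$p_vs_parent - 0.5), 3 * sqrt(0.25 / 10000) + 1e-9)
})

test_that("bootstrap is seed-reproducible and the point estimate is seed-free", {
  coh <- expand_family(c(55, 829), c(31, 278), c(132, 3401), "par", "chi")
  par <- subgroup_spec("par", function(d) d$par)
  sp <- subgroup_spec("chi", function(d) d$par & d$chi, parent = par)
  b1 <- bootstrap_lr(coh, sp, n_boot = 2000, seed = 123)
  b2 <- bootstrap_lr(coh, sp, n_boot = 2000, seed = 123)
  b3 <- bootstrap_lr(coh, sp, n_boot = 2000, seed = 456)
  expect_identical(b1[c("ci_low", "ci_high", "p_vs_all", "p_vs_parent")],
                   b2[c("ci_low", "ci_high", "p_vs_all", "p_vs_parent")])
  expect_equal(b3$lr, b1$lr)  # computed on the original cohort
  expect_equal(b1$lr, (31 / 278) / (132 / 3401))
  # CI brackets the point estimate at this n_boot
  expect_true(b1$ci_low <= b1$lr && b1$lr <= b1$ci_high)
  # direction bookkeeping: child LR exceeds both references
  expect_equal(unname(b1$direction["vs_all"]), "greater")
  expect_equal(unname(b1$direction["vs_parent"]), "greater")
})

test_that("adaptive direction doubles the null rejection rate as documented", {
  # under the exchangeable null the adaptive one-sided p lives on (0, 0.5),
  # so rejection at alpha is ~2*alpha; the fixed-direction test is calibrated
  set.seed(57)
  n <- 600
  p_auto <- p_fixed <- numeric(120)
  for (i in seq_len(120)) {
    coh <- cohort(data.frame(id = sprintf("p%04d", 1:n),
                             member = runif(n) < 0.3,
                             gd = runif(n) < 0.1))
    sp <- subgroup_spec("m", function(d) d$member)
    p_auto[i] <- bootstrap_lr(coh, sp, n_boot = 500, seed = i)$p_vs_all
    p_fixed[i] <- bootstrap_lr(coh, sp, n_boot = 500, seed = i,
                               direction = "greater")$p_vs_all
  }
  # adaptive p never exceeds 1/2 (up to tie mass); fixed-direction p does
  expect_lt(quantile(p_auto, 0.9), 0.55)
  expect_gt(mean(p_fixed > 0.5), 0.25)
})

test_that("subgroup_table lays out families with stable columns", {
  counts <- read_counts_json()
  tab <- subgroup_table(counts, n_boot = 500, seed = 11)
  expect_equal(names(tab),
               c("subgroup", "parent", "cases", "controls", "or", "or_low",
                 "or_high", "fisher_p", "lr", "lr_low", "lr_high",
                 "p_vs_all", "p_vs_parent", "n_boot", "seed"))
  expect_equal(nrow(tab), 7 + 4 * 3 + 2 * 4)  # 7 parents + their children
  expect_true(all(is.na(tab$p_vs_parent[is.na(tab$parent)])))
  expect_true(all(!is.na(tab$p_vs_parent[!is.na(tab$parent)])))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_subgroup_table(tab, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(tab))
})
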