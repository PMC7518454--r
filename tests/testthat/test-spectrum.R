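test_that("classification reproduces the category structure of the report tables", {
  t1 <- table_old()
  cls <- classify_mutations(t1)

  pick <- function(mouse, pos) which(t1$mouse == mouse & t1$position == pos)[1]
  # amino-acid change in a gene: coding only
  i <- pick("A4", 3293090)
  expect_equal(unname(which(cls[i, ])), which(colnames(cls) == "coding"))
  # gene-interrupting IS: IS + coding
  i <- pick("B10", 1770086)
  expect_setequal(colnames(cls)[cls[i, ]], c("IS", "coding"))
  # intergenic single-base insertion: intergenic + indel
  i <- pick("A4", 1219708)
  expect_setequal(colnames(cls)[cls[i, ]], c("intergenic", "indel"))
  # intergenic inversion: intergenic + structural, not an indel
  i <- pick("A4", 4540714)
  expect_setequal(colnames(cls)[cls[i, ]], c("intergenic", "structural"))
  # prophage rows: prophage only
  i <- pick("C13", 1127918)
  expect_setequal(colnames(cls)[cls[i, ]], "prophage")

  expect_error(classify_mutations(data.frame(mutation = NA, annotation = "x")),
               "classification error")
})

test_that("per-mouse counts match hand-tallied table rows", {
  co <- cohort_counts(table_old(), cohort = "old")
  expect_equal(co$total[match(c("A4", "A5", "B6", "B7", "B10", "C13"), co$mouse)],
               c(5, 4, 10, 7, 5, 4))
  cy <- cohort_counts(table_young(), cohort = "young")
  expect_equal(cy$IS[match(c("A2", "B2", "D2", "E2", "G2", "H2", "I2"), cy$mouse)],
               c(0, 3, 0, 0, 0, 0, 0))
  # a declared mouse without records still gets a zero row
  z <- cohort_counts(table_old(), mice = c("A4", "ZZ"))
  expect_equal(z$total[z$mouse == "ZZ"], 0)
  expect_error(cohort_counts(table_old(), cohort = "middle-aged"), "unknown cohort")
})

test_that("mean_sem uses the sample standard deviation", {
  expect_equal(round(mean_sem(c(5, 4, 10, 7, 5, 4)), 1),
               c(mean = 5.8, sem = 0.9))
  expect_equal(round(mean_sem(c(0, 3, 0, 0, 0, 0, 0)), 1),
               c(mean = 0.4, sem = 0.4))
  expect_equal(mean_sem(c(2, 2, 2)), c(mean = 2, sem = 0))
  expect_error(mean_sem(5), "SEM undefined")
})

test_that("mann_whitney reproduces the reported statistics", {
  is_cmp <- mann_whitney(c(1, 1, 1, 1, 2, 1), c(0, 3, 0, 0, 0, 0, 0))
  expect_equal(is_cmp$U, 6.0)
  expect_lt(is_cmp$p_value, 0.05)

  tot_cmp <- mann_whitney(c(5, 4, 10, 7, 5, 4), c(3, 10, 2, 6, 6, 2, 6))
  expect_equal(tot_cmp$U, 17.5)
  expect_gt(tot_cmp$p_value, 0.5)

  idn <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idn$U, 4.5)
  expect_equal(idn$p_value, 1)
})

test_that("mann_whitney agrees with brute-force enumeration, ties included", {
  set.seed(101)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:6, 1)
    if (n1 * n2 > 30) next
    a <- sample(0:3, n1, replace = TRUE)
    b <- sample(0:3, n2, replace = TRUE)
    got <- mann_whitney(a, b)
    orc <- mw_oracle(a, b)
    expect_equal(got$U, orc$U)
    expect_equal(got$U1 + got$U2, n1 * n2)
    expect_gte(got$U, 0)
    expect_lte(got$U, n1 * n2)
  }
  # also agree with the rank-sum route of the standard implementation
  sw <- suppressWarnings(wilcox.test(c(1, 1, 2, 5), c(0, 3, 3))$statistic)
  got <- mann_whitney(c(1, 1, 2, 5), c(0, 3, 3))
  expect_true(got$U == sw || got$U == 4 * 3 - sw)
})

test_that("cohort ratios and site summaries match direct scans of the tables", {
  co <- cohort_counts(table_old())
  cy <- cohort_counts(table_young())
  expect_equal(round(coding_syn_ratio(co), 2), 3.67)
  expect_equal(round(coding_syn_ratio(cy), 2), 4.75)
  expect_equal(sum(co$coding), 11); expect_equal(sum(co$synonymous), 3)
  expect_equal(sum(cy$coding), 19); expect_equal(sum(cy$synonymous), 4)
  zero <- co; zero$synonymous <- 0L
  expect_warning(r <- coding_syn_ratio(zero), "undefined")
  expect_true(is.na(r))

  t1 <- table_old()
  s <- site_frequency_summary(t1, "^IS5$", "tdcA", threshold = 0.05)
  expect_equal(s$n_mice_above, 4)
  expect_equal(s$max_frequency, 0.65)
  expect_equal(site_frequency_summary(t1, "^IS5$", "tdcA", threshold = 1)$n_mice_above, 0)
  s2 <- site_frequency_summary(t1, ".", "psuK", threshold = 0.5)
  expect_equal(s2$n_mice_above, 3)
  expect_equal(s2$max_frequency, 1.00)
  s3 <- site_frequency_summary(t1, "^IS999$", threshold = 0.05)
  expect_equal(s3$n_mice_above, 0)
  expect_true(is.na(s3$max_frequency))
})

test_that("marker series computes binomial SEM and flags empty timepoints", {
  ms <- marker_series(data.frame(day = c(8, 8, 10), positive = c(50, 100, 0),
                                 total = c(100, 100, 0)))
  expect_equal(ms$frequency, c(0.5, 1, NA))
  expect_equal(ms$sem, c(0.05, 0, NA))

  set.seed(41)
  tot <- 200
  pos <- rbinom(200, tot, 0.5)
  sim <- marker_series(data.frame(day = 1:200, positive = pos, total = tot))
  inside <- abs(sim$frequency - 0.5) <= 2 * sim$sem
  expect_gt(mean(inside), 0.90)
  expect_lt(mean(inside), 0.995)
})

test_that("a simulated cohort's truth table reproduces the planted table statistics", {
  g <- fix_cohort_genome()
  t1 <- table_old()
  spec <- plan_cohort_variants(t1, g, seed = 4)
  sim <- simulate_cohort(spec, g, coverage = 2, seed = 15)
  truth <- sim$truth
  co_truth <- cohort_counts(truth)
  co_table <- cohort_counts(t1)
  expect_equal(co_truth[order(co_truth$mouse), -1],
               co_table[order(co_table$mouse), -1], ignore_attr = TRUE)
  # realized frequencies are the printed ones (multiples of 1/100); SNP
  # alleles follow the synthetic sequence, so compare per-mouse multisets
  for (m in unique(truth$mouse)) {
    expect_equal(sort(truth$frequency[truth$mouse == m]),
                 sort(t1$frequency[t1$mouse == m]))
  }

  empty <- simulate_cohort(spec[0, ], g, coverage = 2, seed = 16, mice = "M1")
  expect_equal(nrow(empty$truth), 0)
  expect_named(empty$truth, c("mouse", "cohort", "position", "mutation", "gene",
                              "annotation", "frequency"))
})

test_that("rate-drawn cohorts realise their per-mouse category rates", {
  g <- fix_genome()
  spec <- sample_cohort_spec(g, sprintf("m%04d", 1:1000), "old",
                             rates = list(is = 1.2), seed = 33)
  counts <- table(factor(spec$mouse, levels = sprintf("m%04d", 1:1000)))
  m <- mean(counts)
  expect_gte(m, 1.1)
  expect_lte(m, 1.3)
})
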