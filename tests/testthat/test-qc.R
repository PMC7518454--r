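qv <- function(q, n) intToUtf8(rep.int(q + 33L, n))

test_that("sliding-window trimming follows the hand-computed window rule", {
  p <- qc_params()
  # clean read: untouched
  t1 <- trim_read(strrep("A", 250), qv(30, 250), p)
  expect_true(t1$kept)
  expect_equal(c(t1$start, t1$end), c(1, 250))

  # 90 good bases then 160 at Q2: the last acceptable 4-window ends where the
  # window mean first drops below 20 -> survivor 90 bp < 100 -> discarded.
  qual <- intToUtf8(c(rep(30 + 33L, 90), rep(2 + 33L, 160)))
  t2 <- trim_read(strrep("A", 250), qual, p)
  expect_false(t2$kept)

  # same construction but 130 good bases: the last window whose mean still
  # reaches 20 starts at 128 (30+30+30+2)/4 = 23, so the survivor runs to 131
  qual3 <- intToUtf8(c(rep(30 + 33L, 130), rep(2 + 33L, 120)))
  t3 <- trim_read(strrep("A", 250), qual3, p)
  expect_true(t3$kept)
  expect_equal(c(t3$start, t3$end), c(1, 131))

  # interior low quality passes the window scan but fails the Q20 fraction:
  # 120 bp with 70 interior bases at Q19 -> 50/120 < 0.5 -> discarded
  qual4 <- intToUtf8(c(rep(30 + 33L, 25), rep(19 + 33L, 70), rep(30 + 33L, 25)))
  t4 <- trim_read(strrep("A", 120), qual4, p)
  expect_false(t4$kept)

  # empty read: a discard verdict, not an exception
  expect_false(trim_read("", "", p)$kept)
})

test_that("trimming is idempotent and yields substrings", {
  p <- qc_params()
  set.seed(31)
  for (i in 1:50) {
    n <- sample(100:250, 1)
    q <- sample(c(2L, 10L, 19L, 25L, 35L), n, replace = TRUE,
                prob = c(1, 1, 1, 2, 5))
    bases <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    t1 <- trim_read(bases, intToUtf8(q + 33L), p)
    if (!t1$kept) next
    expect_identical(t1$bases, substr(bases, t1$start, t1$end))
    t2 <- trim_read(t1$bases, t1$qualities, p)
    expect_true(t2$kept)
    expect_identical(t2$bases, t1$bases)
    expect_lte(nchar(t1$bases), n)
  }
})

test_that("a pair is discarded whenever either mate fails", {
  p <- qc_params()
  good <- strrep("A", 250); gq <- qv(30, 250)
  bad <- strrep("A", 250); bq <- qv(2, 250)
  expect_true(filter_pair(good, gq, good, gq, p)$kept)
  expect_false(filter_pair(good, gq, bad, bq, p)$kept)
  expect_false(filter_pair(bad, bq, good, gq, p)$kept)
})

test_that("trim_pairs equals the per-mate brute-force application", {
  g <- fix_genome()
  rs <- simulate_reads(g, coverage = 30, seed = 17, tail_prob = 0.6)
  kept <- trim_pairs(rs)
  manual_keep <- vapply(seq_len(gutevol:::n_pairs(rs)), function(i) {
    filter_pair(rs$r1_seq[i], rs$r1_qual[i], rs$r2_seq[i], rs$r2_qual[i])$kept
  }, logical(1))
  expect_identical(kept$id, rs$id[manual_keep])
  i <- which(manual_keep)[1]
  t1 <- trim_read(rs$r1_seq[i], rs$r1_qual[i])
  expect_identical(kept$r1_seq[1], t1$bases)
})

test_that("read pairs partition to their source genome with ties unassigned", {
  g <- fix_genome()
  resident <- generate_genome(10000, 0.5, n_is_elements = 1, n_prophages = 0,
                              seed = 55, n_plasmids = 1)
  # an error-free invader-only pair
  frag <- substr(g$sequence, 2001, 2500)
  pr <- read_pair_set(substr(frag, 1, 250), qv(35, 250),
                      revcomp(substr(frag, 251, 500)), qv(35, 250))
  res <- partition_reads(pr, g, resident)
  expect_identical(unname(res$bin), "invader")

  # a region shared verbatim by both genomes scores a tie -> unassigned
  shared <- g
  shared_res <- resident
  shared_res$sequence <- paste0(substr(resident$sequence, 1, 5000),
                                substr(g$sequence, 2001, 2500),
                                substr(resident$sequence, 5501, 10000))
  res2 <- partition_reads(pr, shared, shared_res)
  expect_identical(unname(res2$bin), "unassigned")

  expect_error(partition_reads(pr, g, resident, k = 500), "parameter error")
})

test_that("partitioning a contaminated sample is accurate and conserves pairs", {
  g <- fix_genome()
  resident <- generate_genome(10000, 0.5, n_is_elements = 1, n_prophages = 0,
                              seed = 55, n_plasmids = 1)
  rs <- simulate_reads(g, coverage = 60, seed = 19,
                       contamination = list(genome = resident, fraction = 0.3))
  part <- partition_reads(rs, g, resident)
  sizes <- vapply(part$bins, gutevol:::n_pairs, integer(1))
  expect_equal(sum(sizes), gutevol:::n_pairs(rs))

  truth_res <- rs$source == "resident"
  called_res <- part$bin == "resident"
  recall <- sum(called_res & truth_res) / sum(truth_res)
  precision <- sum(called_res & truth_res) / sum(called_res)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  inv_recall <- sum(part$bin == "invader" & grepl("^invader", rs$source)) /
    sum(grepl("^invader", rs$source))
  expect_gte(inv_recall, 0.95)

  # determinism
  part2 <- partition_reads(rs, g, resident)
  expect_identical(part$bin, part2$bin)
})
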