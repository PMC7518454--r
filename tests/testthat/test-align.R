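qv35 <- function(n) intToUtf8(rep.int(35L + 33L, n))

test_that("error-free reads from unique loci map exactly", {
  g <- fix_genome()
  start <- 3001L
  frag <- substr(g$sequence, start, start + 499L)
  pr <- read_pair_set(substr(frag, 1, 250), qv35(250),
                      revcomp(substr(frag, 251, 500)), qv35(250))
  rec <- align_reads(pr, g, 21)
  r1 <- rec[rec$mate == 1L, ]
  r2 <- rec[rec$mate == 2L, ]
  expect_true(all(rec$mapped))
  expect_equal(r1$pos, start)
  expect_identical(r1$strand, "+")
  expect_identical(r1$cigar, "250M")
  expect_equal(r1$mapq, 60L)
  expect_equal(r2$pos, start + 250L)
  expect_identical(r2$strand, "-")
  expect_identical(r2$seq, substr(frag, 251, 500))
})

test_that("a read spanning a planted 1 bp deletion gets a left-aligned 1D cigar", {
  g <- fix_genome()
  seqn <- g$sequence
  # pick a deletion site whose neighbours break homopolymer ambiguity
  p <- 4000L
  while (!(substr(seqn, p, p) != substr(seqn, p + 1L, p + 1L) &&
           substr(seqn, p - 1L, p - 1L) != substr(seqn, p, p))) p <- p + 1L
  read <- paste0(substr(seqn, p - 120L, p - 1L), substr(seqn, p + 1L, p + 130L))
  pr <- read_pair_set(read, qv35(nchar(read)), revcomp(read), qv35(nchar(read)))
  rec <- align_reads(pr, g, 21)
  r1 <- rec[rec$mate == 1L, ]
  expect_identical(r1$cigar, "120M1D130M")
  expect_equal(r1$pos, p - 120L)
})

test_that("a read inside a novel IS element is unmapped; junction reads clip", {
  g <- fix_genome()
  el <- g$is_library[["IS1"]]
  inner <- substr(el, 301, 550)
  pr <- read_pair_set(inner, qv35(250), revcomp(inner), qv35(250))
  rec <- align_reads(pr, g, 21)
  expect_true(all(!rec$mapped))

  junction <- paste0(substr(g$sequence, 5101, 5250), substr(el, 1, 100))
  pr2 <- read_pair_set(junction, qv35(250), revcomp(junction), qv35(250))
  rec2 <- align_reads(pr2, g, 21)
  r1 <- rec2[rec2$mate == 1L, ]
  expect_true(r1$mapped)
  # clip boundary may shift by a base or two where the element start happens
  # to match the reference
  ops <- gutevol:::parse_cigar(r1$cigar)
  expect_identical(ops$op, c("M", "S"))
  expect_lt(abs(ops$len[1] - 150L), 4L)
  expect_equal(r1$pos, 5101L)
})

test_that("the aligner recovers nearly all truth positions on unique sequence", {
  g <- fix_genome()
  popn <- plant_variants(g, g_empty_variants(), n_haplotypes = 2, seed = 1)
  rs <- simulate_reads(popn, coverage = 40, seed = 23, error_rate = 0,
                       tail_prob = 0)
  rec <- align_reads(rs, g, 21)
  r1 <- rec[rec$mate == 1L, ]
  truth <- rs$frag_start[match(r1$qname, rs$id)]
  # unique sequence only: drop fragments touching the repeat pair
  uniq <- !gutevol:::pos_in_intervals(truth, g$repeats) &
    !gutevol:::pos_in_intervals(truth + 249L, g$repeats)
  ok <- r1$mapped & r1$pos == truth & r1$mapq == 60L
  expect_gte(mean(ok[uniq]), 0.99)
})

test_that("SAM round trip is lossless and rejects foreign reference names", {
  g <- fix_genome()
  rs <- simulate_reads(g, coverage = 3, seed = 29)
  rec <- align_reads(trim_pairs(rs), g, 21)
  path <- file.path(tempdir(), "roundtrip.sam")
  write_sam(rec, path)
  back <- read_alignment_file(path, g)
  for (col in c("qname", "mate", "pos", "strand", "mapq", "cigar", "seq", "qual",
                "mapped")) {
    a <- rec[[col]][order(rec$qname, rec$mate)]
    b <- back[[col]][order(back$qname, back$mate)]
    expect_equal(a, b, ignore_attr = TRUE)
  }
  other <- generate_genome(10000, 0.5, n_is_elements = 1, n_prophages = 0, seed = 91)
  expect_error(read_alignment_file(path, other), "parse error")
})

test_that("two aligner parameterisations give concordant pileup depths", {
  sim <- fix_snp_sim()
  g <- sim$genome
  rs <- simulate_reads(g, coverage = 60, seed = 31, error_rate = 0)
  rec_a <- align_reads(rs, g, 17)
  rec_b <- align_reads(rs, g, 25)
  da <- pileup_depth(build_pileup(rec_a, g))
  db <- pileup_depth(build_pileup(rec_b, g))
  set.seed(1)
  positions <- sample(500:(genome_length(g) - 500), 100)
  xa <- da$depth[match(positions, da$pos)]
  xb <- db$depth[match(positions, db$pos)]
  xa[is.na(xa)] <- 0; xb[is.na(xb)] <- 0
  expect_true(all(abs(xa - xb) <= pmax(1, 0.05 * pmax(xa, xb))))
})

test_that("pileup columns honour mapping-quality and base-quality rules", {
  g <- fix_genome()
  mkrec <- function(n, mapq, base = "A", bq = 35L) {
    data.table::data.table(
      run = "t", qname = sprintf("r%02d", seq_len(n)), mate = 1L,
      rname = g$name, pos = 1001L, strand = rep(c("+", "-"), length.out = n),
      mapq = mapq, cigar = "1M", seq = base,
      qual = intToUtf8(bq + 33L), mapped = TRUE)
  }
  rec <- mkrec(10, 60L)
  attr(rec, "reference") <- g
  p <- build_pileup(rec, g)
  col <- pileup_column(p, 1001L)
  expect_equal(col$depth, 10)
  expect_equal(col$hq_depth, 10)
  expect_true(all(col$observations$allele == "A"))

  rec2 <- rbind(mkrec(6, 60L), mkrec(4, 0L))
  attr(rec2, "reference") <- g
  expect_equal(pileup_column(build_pileup(rec2, g), 1001L)$depth, 6)

  # low base quality is retained but flagged
  rec3 <- mkrec(10, 60L, bq = 20L)
  attr(rec3, "reference") <- g
  col3 <- pileup_column(build_pileup(rec3, g), 1001L)
  expect_equal(col3$depth, 10)
  expect_equal(col3$hq_depth, 0)

  # unsorted input is an ordering error
  rec4 <- mkrec(2, 60L)
  rec4$pos <- c(2000L, 1000L)
  attr(rec4, "reference") <- g
  expect_error(build_pileup(rec4, g), "ordering error")
})

test_that("pileup depth never exceeds overlap count and recovers a 10% SNP", {
  sim <- fix_snp_sim()
  p <- sim$pileup
  truth <- sim$truth
  n_overlap <- sum(sim$records$mapped & sim$records$mapq >= 20)
  expect_lte(max(pileup_depth(p)$depth), n_overlap)

  for (i in 1:2) {
    pos <- truth$position[i]
    col <- pileup_column(p, pos)
    alt_n <- sum(col$observations$allele == truth$alt[i] & col$observations$hq)
    f <- alt_n / col$hq_depth
    tf <- truth$realized_frequency[i]
    expect_lt(abs(f - tf), 3 * sqrt(tf * (1 - tf) / col$hq_depth))
  }
})
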