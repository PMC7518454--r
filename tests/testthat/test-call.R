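test_that("naive caller emission matches the hand-applied filter rules", {
  g <- fix_genome()
  pos <- 2000L
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"),
                                substr(g$sequence, p, p))[1]
  alt <- alt_of(pos)

  # depth 100, alt 10 split 5/5: frequency 0.10, bias 1 -> called
  p1 <- make_pileup(g, pos, 45, 45, alt, 5, 5)
  c1 <- call_naive(p1)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$frequency, 0.10)
  expect_equal(c1$pos_count / c1$neg_count, 1.0)

  # depth 100, alt 14 split 13/1: negative strand below 5 -> no call
  expect_equal(nrow(call_naive(make_pileup(g, pos, 43, 43, alt, 13, 1))), 0)

  # depth 400, alt 10 split 5/5: fraction 0.025 < 0.03 -> no call
  expect_equal(nrow(call_naive(make_pileup(g, pos, 195, 195, alt, 5, 5))), 0)

  # bias bounds are strict: 25/5 = 5.0 is rejected, 24/5 = 4.8 passes
  expect_equal(nrow(call_naive(make_pileup(g, pos, 100, 100, alt, 25, 5))), 0)
  expect_equal(nrow(call_naive(make_pileup(g, pos, 100, 100, alt, 24, 5))), 1)

  # low base quality alt reads are not quality reads
  expect_equal(nrow(call_naive(make_pileup(g, pos, 45, 45, alt, 5, 5,
                                           alt_bq = 20L))), 0)
})

test_that("polymorphism-mode caller applies coverage, frequency and exact-test rules", {
  g <- fix_genome()
  pos <- 2000L
  alt <- setdiff(c("A", "C", "G", "T"), substr(g$sequence, pos, pos))[1]

  # depth below 5 never calls
  expect_equal(nrow(call_polymode(make_pileup(g, pos, 1, 1, alt, 1, 1))), 0)

  # perfectly balanced 2x2 table: p = 1 -> called at 0.20
  c2 <- call_polymode(make_pileup(g, pos, 40, 40, alt, 10, 10))
  expect_equal(nrow(c2), 1)
  expect_equal(c2$frequency, 0.20)

  # alt 20/0 vs ref 30/50: Fisher p << 0.05 -> rejected for strand bias
  expect_equal(nrow(call_polymode(make_pileup(g, pos, 30, 50, alt, 20, 0))), 0)

  # frequency below 0.05 -> no call even at high depth
  expect_equal(nrow(call_polymode(make_pileup(g, pos, 98, 98, alt, 4, 4))), 0)
})

test_that("masking removes repeat and breakpoint calls and nothing else", {
  g <- fix_genome()
  calls <- data.table::data.table(run = "r", pos = c(150L, 3000L, 5000L),
                                  type = "snp", ref = "A", alt = "C",
                                  frequency = 0.5, pos_count = 10L,
                                  neg_count = 10L, depth = 40L)
  mask <- make_mask(g, breakpoints = 5005L)
  out <- apply_mask(calls, mask)
  # 150 is inside the first repeat copy; 5000 is within 10 bp of the breakpoint
  expect_equal(out$pos, 3000L)
  expect_identical(apply_mask(calls, make_mask(annotated_genome("x", strrep("A", 100)))),
                   calls)
})

test_that("a collapsed repeat produces a masked false-positive SNP cluster", {
  # reference carries one copy; the sequenced strain carries a second, diverged
  # copy elsewhere, so its reads pile onto the single reference copy
  set.seed(71)
  base <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE), collapse = "")
  copy <- substr(base, 2001, 2500)
  diverged <- copy
  diff_at <- c(100L, 200L, 250L, 300L, 400L)
  for (d in diff_at) {
    substr(diverged, d, d) <- setdiff(c("A", "C", "G", "T"),
                                      substr(copy, d, d))[1]
  }
  ref_genome <- annotated_genome("ref", base,
                                 repeats = data.frame(start = 2001L, end = 2500L))
  # second copy inserted mid-genome so reads sample its interior evenly
  sample_genome <- annotated_genome("sample", paste0(substr(base, 1, 5500),
                                                     diverged,
                                                     substr(base, 5501, 6000)))
  # plant a true SNP outside the repeat
  p_true <- 4000L
  truealt <- setdiff(c("A", "C", "G", "T"), substr(base, p_true, p_true))[1]
  popn <- plant_variants(sample_genome,
                         variant_spec("snp", p_true, 0.5,
                                      ref = substr(base, p_true, p_true),
                                      alt = truealt), seed = 1)
  rs <- simulate_reads(popn, coverage = 150, seed = 2, error_rate = 0)
  rec <- align_reads(trim_pairs(rs), ref_genome, 21)
  calls <- call_naive(build_pileup(rec, ref_genome))
  fp_pos <- 2000L + diff_at
  expect_true(all(fp_pos %in% calls$pos))
  masked <- apply_mask(calls, make_mask(ref_genome))
  expect_false(any(fp_pos %in% masked$pos))
  expect_true(p_true %in% masked$pos)
})

test_that("merge_runs applies the >=2-run and mean-frequency rules", {
  mkcall <- function(run, pos, freq, type = "snp", ref = "A", alt = "C") {
    data.table::data.table(run = run, pos = as.integer(pos), type = type,
                           ref = ref, alt = alt, frequency = freq,
                           pos_count = 10L, neg_count = 10L, depth = 100L)
  }
  empty <- mkcall("x", 1, 1)[0L]

  # in all three runs at 0.10 -> consensus with mean 0.10
  r1 <- mkcall("a", 100, 0.10); r2 <- mkcall("b", 100, 0.10); r3 <- mkcall("c", 100, 0.10)
  m <- merge_runs(list(r1, r2, r3))
  expect_equal(nrow(m), 1)
  expect_equal(m$mean_frequency, 0.10)
  expect_equal(m$n_supporting_runs, 3L)

  # one run only, even at 0.90 -> dropped
  m2 <- merge_runs(list(mkcall("a", 100, 0.90), empty_b <- mkcall("b", 1, 1)[0L],
                        mkcall("c", 1, 1)[0L]))
  expect_equal(nrow(m2), 0)

  # two runs at 0.06/0.07, absent third: mean 0.043 < 0.05 -> dropped,
  # but dividing by detecting runs keeps it
  r1 <- mkcall("a", 100, 0.06); r2 <- mkcall("b", 100, 0.07)
  m3 <- merge_runs(list(r1, r2, empty), n_runs_total = 3)
  expect_equal(nrow(m3), 0)
  m4 <- merge_runs(list(r1, r2, empty), n_runs_total = 3, average = "detected")
  expect_equal(nrow(m4), 1)
  expect_equal(m4$mean_frequency, 0.065)

  # symmetric in run order
  ma <- merge_runs(list(r1, r2, mkcall("c", 100, 0.20)))
  mb <- merge_runs(list(mkcall("c", 100, 0.20), r2, r1))
  expect_equal(ma$mean_frequency, mb$mean_frequency)
  expect_equal(ma$pos, mb$pos)

  expect_error(merge_runs(list(r1)), "at least 2")
})

test_that("indels are matched across runs after left alignment", {
  # genome with a homopolymer: deletion placements at either end are the same
  # event and must merge
  g <- annotated_genome("h", paste0(strrep("C", 30), "AAAAA", strrep("G", 30)))
  mk <- function(run, pos) {
    data.table::data.table(run = run, pos = as.integer(pos), type = "deletion",
                           ref = "A", alt = "-1", frequency = 0.2,
                           pos_count = 10L, neg_count = 10L, depth = 100L)
  }
  m <- merge_runs(list(mk("a", 31), mk("b", 35), mk("c", 33)), genome = g)
  expect_equal(nrow(m), 1)
  expect_equal(m$pos, 31L)
  expect_equal(m$n_supporting_runs, 3L)
})

test_that("annotation translates codons on both strands and formats contexts", {
  g <- annot_genome()
  gene1 <- g$genes[1, ]
  # codon 3 of alpA is CGT (Arg); C->T gives TGT (Cys): "R -> C"
  p_cgt <- gene1$start + 6L
  v <- list(type = "snp", pos = p_cgt, ref = "C", alt = "T", frequency = 0.23)
  rec <- annotate_variant(v, g)
  expect_identical(rec$annotation, paste("R", ARROW, "C"))
  expect_identical(rec$gene, "alpA")
  expect_identical(rec$mutation, paste("C", ARROW, "T"))

  # codon 4 GGA -> GGG is synonymous (third position)
  p_syn <- gene1$start + 11L
  expect_identical(annotate_variant(list(type = "snp", pos = p_syn, ref = "A",
                                         alt = "G", frequency = 0.1), g)$annotation,
                   "Synonymous")

  # minus-strand gene: codon 2 of betB is CCC (Pro); genomic change at the
  # second codon base: CCC -> CAC is P -> H
  gene2 <- g$genes[2, ]
  p_m <- gene2$end - 4L  # codon 2, position 2 in gene frame
  expect_identical(annotate_variant(list(type = "snp", pos = p_m, ref = "G",
                                         alt = "T", frequency = 0.1), g)$annotation,
                   paste("P", ARROW, "H"))

  # 10 bp deletion in a gene is a frameshift; 12 bp are codons deleted
  p_in <- gene1$start + 30L
  expect_identical(annotate_variant(list(type = "deletion", pos = p_in,
                                         alt = "-10", frequency = 0.05), g)$annotation,
                   "Frameshift")
  expect_identical(annotate_variant(list(type = "deletion", pos = p_in,
                                         alt = "-12", frequency = 0.05), g)$annotation,
                   "Codons deleted")
  expect_identical(annotate_variant(list(type = "deletion", pos = p_in,
                                         alt = "-220", frequency = 0.05), g)$annotation,
                   "Partial gene deletion")

  # in-frame insertion, frameshift insertion
  expect_identical(annotate_variant(list(type = "insertion", pos = p_in,
                                         alt = "+TCGAGG", frequency = 0.36), g)$annotation,
                   "Codon insertion")
  expect_identical(annotate_variant(list(type = "insertion", pos = p_in,
                                         alt = "+T", frequency = 0.9), g)$mutation,
                   "+1 T")

  # intergenic context carries flanking genes with strand arrows
  p_ig <- g$genes$end[1] + 50L
  igc <- annotate_variant(list(type = "snp", pos = p_ig, ref = "A", alt = "C",
                               frequency = 0.2), g)
  expect_identical(igc$annotation, "Intergenic")
  expect_identical(igc$gene, paste0("alpA", ARROW, "/betB", "\u2190"))

  # IS inside a gene interrupts it; outside it is intergenic
  expect_identical(annotate_variant(list(element = "IS5", pos = p_in,
                                         frequency = 0.1), g)$annotation,
                   "Gene interrupted")
  expect_identical(annotate_variant(list(element = "IS5", pos = p_ig,
                                         frequency = 0.1), g)$annotation,
                   "Intergenic")

  # pure function: repeated calls identical
  expect_identical(annotate_variant(v, g), annotate_variant(v, g))
  expect_error(annotate_variant(list(type = "snp", pos = 10^7, ref = "A",
                                     alt = "C"), g), "coordinate error")
})

test_that("the consensus pipeline recovers the planted mouse-A4 spectrum", {
  fx <- fix_a4()
  truth <- fx$truth
  cons <- fx$result$consensus
  small <- truth[truth$mutation != "IS5" &
                   !grepl("Inversion", truth$mutation), ]
  for (i in seq_len(nrow(small))) {
    hit <- cons[cons$pos == small$position[i], ]
    expect_equal(nrow(hit), 1, info = paste("row", small$mutation[i]))
    expect_lt(abs(hit$mean_frequency - small$frequency[i]), 0.05)
  }
})
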