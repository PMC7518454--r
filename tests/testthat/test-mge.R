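test_that("split-read detection localises planted insertions and needs a library", {
  sim <- fix_is_sim()
  sc <- detect_split(sim$records, sim$genome$is_library)
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    hit <- sc[sc$element == truth$element[i], ]
    expect_gte(nrow(hit), 1)
    expect_lte(min(abs(hit$site - truth$position[i])), 5)
  }
  expect_error(detect_split(sim$records, character(0)), "empty IS library")
})

test_that("nearby insertions of one element stay separate clusters", {
  g <- fix_is_sim()$genome
  gaps <- gutevol:::intergenic_gaps(g, 150)
  gaps <- gaps[order(-(gaps$end - gaps$start)), ]
  p <- gaps$start[7] + 30L
  vars <- rbind(variant_spec("is_insertion", p, 0.5, element = "IS1"),
                variant_spec("is_insertion", p + 30L, 0.5, element = "IS1"))
  popn <- plant_variants(g, vars, seed = 6)
  rs <- simulate_reads(popn, coverage = 150, seed = 7, error_rate = 0)
  rec <- align_reads(trim_pairs(rs), g, 21)
  sc <- detect_split(rec, g$is_library)
  sc1 <- sc[sc$element == "IS1" & abs(sc$site - p) < 60, ]
  expect_equal(nrow(sc1), 2)
  expect_setequal(round(sc1$site / 5) * 5, round(c(p, p + 30L) / 5) * 5)
})

test_that("discordant pairs bracket the junction; clean data yields none", {
  sim <- fix_is_sim()
  dc <- detect_discordant(sim$records, sim$genome$is_library)
  truth <- sim$truth
  # the strongest insertion must be bracketed by its discordant interval
  big <- truth[which.max(truth$frequency), ]
  hit <- dc[dc$element == big$element, ]
  expect_gte(nrow(hit), 1)
  expect_true(any(hit$lo - 20 <= big$position & hit$hi + 20 >= big$position))

  null_rec <- fix_null_sim()
  expect_equal(nrow(detect_discordant(null_rec, sim$genome$is_library)), 0)
})

test_that("junction assembly confirms true sites and is honest about support", {
  sim <- fix_is_sim()
  truth <- sim$truth
  big <- truth[which.max(truth$frequency), ]
  asm <- assemble_junction(sim$records, list(site = big$position + 3L,
                                             element = big$element),
                           sim$genome$is_library)
  expect_identical(asm$verdict, "confirms")
  expect_lte(abs(asm$site - big$position), 2)

  # a candidate in clean sequence (far from every planted junction) has no
  # clipped support
  cands <- seq(2000L, 28000L, by = 500L)
  clean_site <- cands[which.max(vapply(cands, function(x)
    min(abs(x - truth$position)), numeric(1)))]
  asm2 <- assemble_junction(sim$records, list(site = clean_site, element = "IS1"),
                            sim$genome$is_library)
  expect_identical(asm2$verdict, "insufficient")
  expect_equal(asm2$n_reads, 0)

  # fewer than 2 usable reads -> insufficient
  one <- sim$records[grepl("S", sim$records$cigar) & sim$records$mapped, ][1, ]
  attr(one, "reference") <- sim$genome
  ct1 <- gutevol:::clip_table(one)
  asm3 <- assemble_junction(one, list(site = ct1$junction[1],
                                      element = truth$element[1]),
                            sim$genome$is_library)
  expect_identical(asm3$verdict, "insufficient")
})

test_that("voting accepts >=2-method sites, quantifies them, and is monotone", {
  sim <- fix_is_sim()
  calls <- sim$calls
  truth <- sim$truth
  expect_equal(nrow(calls), nrow(truth))
  expect_true(all(calls$n_votes >= 2))
  m <- match(calls$element, truth$element)
  expect_true(all(abs(calls$site - truth$position[m]) <= 5))
  expect_true(all(abs(calls$frequency - truth$realized_frequency[m]) <= 0.07))

  # monotone: removing the discordant channel never adds accepted calls
  empty_dc <- detect_discordant(sim$records, sim$genome$is_library)[0L, ]
  without <- vote_and_quantify(sim$records, sim$genome$is_library,
                               discordant_cands = empty_dc)
  expect_true(all(without$site %in% calls$site))

  # frequency arithmetic on a constructed 65/35 junction
  g <- sim$genome
  syn <- synthetic_is_records(g, 12000L, "IS1", n_junction_per_side = 65L,
                              n_span = 35L)
  vc <- vote_and_quantify(syn, g$is_library)
  expect_equal(nrow(vc), 1)
  expect_equal(vc$junction_reads, 130L)
  expect_equal(vc$spanning_reads, 35L)
  expect_equal(vc$frequency, 65 / (65 + 35))
})

test_that("variant-free simulations produce zero accepted IS calls", {
  sim <- fix_is_sim()
  null_rec <- fix_null_sim()
  expect_equal(nrow(vote_and_quantify(null_rec, sim$genome$is_library)), 0)
})

test_that("coverage ratio estimates prophage-gain frequency across carriers", {
  g <- fix_genome()
  ph <- g$prophages[1, ]
  run_gain <- function(freq, seed) {
    popn <- plant_variants(g, variant_spec("prophage_gain", ph$start, freq,
                                           element = ph$name, end = ph$end),
                           seed = seed)
    rs <- simulate_reads(popn, coverage = 200, seed = seed + 100, error_rate = 0.001)
    rec <- align_reads(trim_pairs(rs), g, 21)
    estimate_region_gain(rec, list(name = ph$name, start = ph$start, end = ph$end))
  }
  expect_equal(run_gain(0, 1)$frequency, 0)
  # the ratio is clamped at 1; coverage noise can leave it marginally below
  expect_lt(abs(run_gain(1, 2)$frequency - 1), 0.05)
  half <- run_gain(0.5, 3)
  expect_lt(abs(half$frequency - 0.5), 0.05)
})
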