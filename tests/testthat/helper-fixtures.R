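# Shared fixtures. The heavier simulations are built lazily once per test run
# and cached, so several test files can reuse the same alignments.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[name]]
}

table_old <- function() {
  read_mutation_table(system.file("extdata", "table1_old.tsv", package = "gutevol"))
}

table_young <- function() {
  read_mutation_table(system.file("extdata", "table2_young.tsv", package = "gutevol"))
}

ARROW <- "\u2192"
DELTA_CH <- "\u0394"

# small reusable genome
fix_genome <- function() cached("genome12k", generate_genome(
  12000, 0.5, n_is_elements = 4, n_prophages = 1, seed = 42))

# cohort genome sized for the full old-mouse table
fix_cohort_genome <- function() cached("genome25k", generate_genome(
  25000, 0.5, n_is_elements = 6, n_prophages = 2, seed = 11))

# mouse-A4 variant set planted at printed frequencies, sequenced at depth 400
# with resident-strain contamination, plus the full pipeline result
fix_a4 <- function() cached("a4", {
  g <- fix_cohort_genome()
  spec <- plan_cohort_variants(table_old(), g, seed = 4)
  a4 <- spec[spec$mouse == "A4", ]
  resident <- generate_genome(20000, 0.5, n_is_elements = 2, n_prophages = 0,
                              seed = 77, n_plasmids = 2)
  sim <- simulate_cohort(a4, g, coverage = 400, seed = 9, error_rate = 0.001,
                         contamination = list(genome = resident, fraction = 0.15))
  res <- run_sample_pipeline(sim$reads[["A4"]], g, resident = resident)
  list(genome = g, spec = a4, truth = sim$truth, result = res)
})

# one population carrying six IS insertions at the six distinct reported
# frequencies, depth 400; detection uses a single alignment run
fix_is_sim <- function() cached("is_sim", {
  g <- generate_genome(30000, 0.5, n_is_elements = 6, n_prophages = 0, seed = 13)
  gaps <- gutevol:::intergenic_gaps(g, 60)
  gaps <- gaps[order(-(gaps$end - gaps$start)), ]
  freqs <- c(0.06, 0.10, 0.11, 0.16, 0.19, 0.65)
  els <- names(g$is_library)
  vars <- do.call(rbind, lapply(seq_along(freqs), function(i) {
    variant_spec("is_insertion", gaps$start[i] + 25L, freqs[i], element = els[i])
  }))
  popn <- plant_variants(g, vars, seed = 3)
  rs <- simulate_reads(popn, coverage = 400, seed = 8, error_rate = 0.001)
  rec <- align_reads(trim_pairs(rs), g, 21)
  list(genome = g, truth = popn$truth, records = rec,
       calls = vote_and_quantify(rec, g$is_library))
})

# variant-free control on the same genome
fix_null_sim <- function() cached("null_sim", {
  g <- fix_is_sim()$genome
  rs <- simulate_reads(plant_variants(g, g_empty_variants(), seed = 1),
                       coverage = 200, seed = 21, error_rate = 0.001)
  align_reads(trim_pairs(rs), g, 21)
})

g_empty_variants <- function() {
  data.frame(kind = character(0), position = integer(0), ref = character(0),
             alt = character(0), element = character(0), end = integer(0),
             frequency = numeric(0))
}

# population with one low and one intermediate SNP, for binomial checks
fix_snp_sim <- function() cached("snp_sim", {
  g <- fix_genome()
  gaps <- gutevol:::intergenic_gaps(g, 60)
  p1 <- gaps$start[2] + 20L; p2 <- gaps$start[4] + 20L
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"),
                                substr(g$sequence, p, p))[1]
  vars <- rbind(variant_spec("snp", p1, 0.10, ref = substr(g$sequence, p1, p1),
                             alt = alt_of(p1)),
                variant_spec("snp", p2, 0.50, ref = substr(g$sequence, p2, p2),
                             alt = alt_of(p2)))
  popn <- plant_variants(g, vars, seed = 5)
  rs <- simulate_reads(popn, coverage = 400, seed = 6, error_rate = 0)
  rec <- align_reads(trim_pairs(rs), g, 21)
  list(genome = g, truth = popn$truth, records = rec,
       pileup = build_pileup(rec, g))
})

# hand-built pileup from per-allele strand counts at one position
make_pileup <- function(genome, pos, ref_pos_n, ref_neg_n, alt, alt_pos_n,
                        alt_neg_n, bq = 35L, alt_bq = 35L, event = "base",
                        margin = 100L) {
  ref <- substr(genome$sequence, pos, pos)
  mk <- function(allele, strand, n, q, ev) {
    if (n == 0L) return(NULL)
    data.table::data.table(pos = pos, allele = allele, event = ev, bq = q,
                           strand = strand, margin = margin)[rep(1L, n)]
  }
  rows <- data.table::rbindlist(list(
    mk(ref, "+", ref_pos_n, bq, "base"),
    mk(ref, "-", ref_neg_n, bq, "base"),
    mk(alt, "+", alt_pos_n, alt_bq, event),
    mk(alt, "-", alt_neg_n, alt_bq, event)
  ))
  rows$hq <- rows$bq >= 30L
  structure(list(obs = rows, reference = genome, min_mapq = 20, min_baseq = 30),
            class = "pileup")
}

# tiny genome with designed genes for annotation tests
annot_genome <- function() cached("annot_genome", {
  set.seed(99)
  pre <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  # gene1 (+): ATG AAA CGT GGA TTT ... pad to 30 codons
  body1 <- paste0("ATGAAACGTGGATTT",
                  paste(rep("GCT", 25), collapse = ""))
  mid <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  # gene2 (-): reverse strand; reverse complement of ATG CCC AGA TAA
  body2 <- revcomp(paste0("ATGCCCAGATCC", paste(rep("GAA", 20), collapse = "")))
  post <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  seqn <- paste0(pre, body1, mid, body2, post)
  g1s <- nchar(pre) + 1L
  g1e <- g1s + nchar(body1) - 1L
  g2s <- g1e + nchar(mid) + 1L
  g2e <- g2s + nchar(body2) - 1L
  annotated_genome("annot", seqn,
                   genes = data.frame(name = c("alpA", "betB"),
                                      start = c(g1s, g2s), end = c(g1e, g2e),
                                      strand = c("+", "-")),
                   repeats = data.frame(start = 1L, end = 50L))
})

# alignment records crafted around an IS junction: n_junction clipped reads
# per side with element-derived tails, n_span spanning reads
synthetic_is_records <- function(genome, site, element, n_junction_per_side,
                                 n_span, read_len = 250L) {
  el <- genome$is_library[[element]]
  gseq <- genome$sequence
  rows <- list()
  id <- 0L
  for (i in seq_len(n_junction_per_side)) {
    # R-side clip: mapped left flank + element start
    m <- 150L; cl <- read_len - m
    start <- site - m + 1L
    seqn <- paste0(substr(gseq, start, site), substr(el, 1L, cl))
    id <- id + 1L
    rows[[length(rows) + 1L]] <- data.table::data.table(
      run = "syn", qname = sprintf("j%04d", id), mate = 1L, rname = genome$name,
      pos = start, strand = "+", mapq = 60L,
      cigar = paste0(m, "M", cl, "S"), seq = seqn,
      qual = strrep("I", read_len), mapped = TRUE)
    # L-side clip: element end + mapped right flank
    id <- id + 1L
    seqn2 <- paste0(substr(el, nchar(el) - cl + 1L, nchar(el)),
                    substr(gseq, site + 1L, site + m))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      run = "syn", qname = sprintf("j%04d", id), mate = 1L, rname = genome$name,
      pos = site + 1L, strand = "-", mapq = 60L,
      cigar = paste0(cl, "S", m, "M"), seq = seqn2,
      qual = strrep("I", read_len), mapped = TRUE)
  }
  for (i in seq_len(n_span)) {
    start <- site - 125L + (i %% 50L)
    id <- id + 1L
    rows[[length(rows) + 1L]] <- data.table::data.table(
      run = "syn", qname = sprintf("s%04d", id), mate = 1L, rname = genome$name,
      pos = start, strand = if (i %% 2L) "+" else "-", mapq = 60L,
      cigar = paste0(read_len, "M"),
      seq = substr(gseq, start, start + read_len - 1L),
      qual = strrep("I", read_len), mapped = TRUE)
  }
  rec <- data.table::rbindlist(rows)
  data.table::setorder(rec, pos)
  data.table::setattr(rec, "reference", genome)
  data.table::setattr(rec, "class", c("alignment_set", class(rec)))
  rec[]
}

# brute-force Mann-Whitney oracle: U by pairwise counting, exact p by
# enumerating all assignments of the pooled values to group A
mw_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  U1 <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U2 <- n1 * n2 - U1
  pool <- c(a, b)
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) {
    aa <- pool[ii]; bb <- pool[-ii]
    u1 <- sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
    min(u1, n1 * n2 - u1)
  })
  obs <- min(U1, U2)
  list(U = obs, p_exact = mean(us <= obs))
}
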