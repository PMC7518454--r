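# End-to-end per-sample orchestration: QC -> partition -> multi-run alignment
# -> per-run calling -> masking -> consensus -> annotation, plus IS detection
# and prophage-gain estimation.

# breakpoint positions = clip clusters with enough support (structural
# junction signature: IS insertions, inversion edges, large deletions);
# min_clip of 30 keeps the short clips that small indels leave near read
# ends from masking a genuine polymorphism
detect_breakpoints <- function(records, min_support = 5L, min_clip = 30L,
                               cluster_window = 5L) {
  ct <- clip_table(records)
  ct <- ct[ct$clip_len >= min_clip, ]
  if (nrow(ct) == 0L) return(integer(0))
  j <- sort(ct$junction)
  cluster <- cumsum(c(1L, diff(j) > cluster_window))
  sizes <- tapply(j, cluster, length)
  mids <- tapply(j, cluster, function(x) as.integer(round(stats::median(x))))
  as.integer(mids[sizes >= min_support])
}

#' Run the full polymorphism-calling pipeline on one sample
#'
#' Trims read pairs, optionally partitions them against the resident strain
#' and keeps the invader bin, aligns the surviving pairs in several
#' independent runs (different seed lengths), calls variants per run with
#' both callers (their call sets are pooled per run), masks repeat and
#' breakpoint regions, merges runs under the consensus rule, detects IS
#' insertions by evidence voting, estimates prophage-interval frequencies
#' from coverage, and annotates everything into a report-layout mutation
#' table.
#'
#' @param rs a `read_set`.
#' @param invader `annotated_genome` of the focal strain (the alignment
#'   reference).
#' @param resident optional `annotated_genome` of the resident strain (turns
#'   on read partitioning).
#' @param seed_lengths one aligner seed length per run.
#' @param qc [qc_params()] for trimming.
#' @param min_runs,min_mean_freq consensus thresholds (see [merge_runs()]).
#' @param call_prophages estimate coverage-based gain frequency for every
#'   annotated prophage interval.
#' @param keep_records keep per-run alignment records in the result (memory).
#' @return list: `n_input`, `n_trimmed`, `n_invader`, `run_calls`,
#'   `breakpoints`, `mask`, `consensus`, `is_calls`, `prophage_gains`,
#'   `mutations` (annotated report rows), and optionally `records`.
#' @export
run_sample_pipeline <- function(rs, invader, resident = NULL,
                                seed_lengths = c(17, 21, 25),
                                qc = qc_params(), min_runs = 2,
                                min_mean_freq = 0.05, call_prophages = TRUE,
                                keep_records = FALSE) {
  n_input <- n_pairs(rs)
  trimmed <- trim_pairs(rs, qc)
  n_trimmed <- n_pairs(trimmed)
  if (!is.null(resident)) {
    part <- partition_reads(trimmed, invader, resident)
    sample_reads <- part$bins$invader
  } else {
    sample_reads <- trimmed
  }
  n_invader <- n_pairs(sample_reads)

  run_calls <- list()
  main_records <- NULL
  for (ri in seq_along(seed_lengths)) {
    lab <- sprintf("seed%d", seed_lengths[ri])
    rec <- align_reads(sample_reads, invader, seed_length = seed_lengths[ri],
                       run_label = lab)
    p <- build_pileup(rec, invader)
    cn <- call_naive(p, run_label = lab)
    cp <- call_polymode(p, run_label = lab)
    # pool the two callers within a run (frequencies from the naive caller
    # where both emit the same variant)
    pooled <- rbind(cn, cp[!paste(cp$pos, cp$type, cp$alt) %in%
                             paste(cn$pos, cn$type, cn$alt), ])
    data.table::setorder(pooled, pos)
    run_calls[[lab]] <- pooled
    if (ri == 2L || length(seed_lengths) == 1L) main_records <- rec
    rm(p)
  }

  is_calls <- vote_and_quantify(main_records, invader$is_library)
  breakpoints <- unique(c(detect_breakpoints(main_records),
                          is_calls$site, is_calls$site + 1L))
  mask <- make_mask(invader, breakpoints)
  run_calls_masked <- lapply(run_calls, apply_mask, mask = mask)
  consensus <- merge_runs(run_calls_masked, genome = invader,
                          n_runs_total = length(seed_lengths),
                          min_runs = min_runs, min_mean_freq = min_mean_freq)

  prophage_gains <- NULL
  if (call_prophages && nrow(invader$prophages)) {
    prophage_gains <- do.call(rbind, lapply(seq_len(nrow(invader$prophages)),
      function(i) estimate_region_gain(main_records, invader$prophages[i, ])))
  }

  mutations <- annotate_variants(consensus, invader)
  if (nrow(is_calls)) {
    mutations <- rbind(mutations, do.call(rbind, lapply(seq_len(nrow(is_calls)),
      function(i) {
        r <- annotate_variant(list(element = is_calls$element[i],
                                   pos = is_calls$site[i],
                                   frequency = is_calls$frequency[i]), invader)
        r$frequency <- round(r$frequency, 2)
        r
      })))
  }
  out <- list(n_input = n_input, n_trimmed = n_trimmed, n_invader = n_invader,
              run_calls = run_calls_masked, breakpoints = breakpoints,
              mask = mask, consensus = consensus, is_calls = is_calls,
              prophage_gains = prophage_gains, mutations = mutations)
  if (keep_records) out$records <- main_records
  out
}
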