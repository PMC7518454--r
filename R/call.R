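# Polymorphism calling from pileups, repeat/breakpoint masking, and the
# multi-run consensus rule.

# Tabulate candidate alternate alleles (snp/ins/del) per position from the
# high-quality observations of a pileup. Returns a data.table with per-strand
# support and quality depth. Indel alleles use margin-restricted counts
# (numerator and denominator limited to reads whose alignment extends at
# least `indel_margin` bp past the position): a read ending within a few
# bases of an indel cannot express it, so unrestricted depth would bias
# indel frequencies downward.
alt_allele_table <- function(p, indel_margin = 12L) {
  obs <- p$obs
  ref <- p$reference$sequence
  depth_tab <- obs[obs$event %in% c("base", "del_span") & obs$hq,
                   list(depth = .N), by = "pos"]
  depth_tab_m <- obs[obs$event %in% c("base", "del_span") & obs$hq &
                       obs$margin >= indel_margin,
                     list(depth_m = .N), by = "pos"]
  ev <- obs[obs$hq & obs$event %in% c("base", "ins", "del"), ]
  ev <- ev[!(ev$event %in% c("ins", "del") & ev$margin < indel_margin), ]
  if (nrow(ev) == 0L) {
    return(data.table::data.table(pos = integer(0), type = character(0),
                                  ref = character(0), alt = character(0),
                                  pos_count = integer(0), neg_count = integer(0),
                                  depth = integer(0)))
  }
  ev$refbase <- substring(ref, ev$pos, ev$pos)
  ev <- ev[!(ev$event == "base" & ev$allele == ev$refbase), ]
  if (nrow(ev) == 0L) {
    return(data.table::data.table(pos = integer(0), type = character(0),
                                  ref = character(0), alt = character(0),
                                  pos_count = integer(0), neg_count = integer(0),
                                  depth = integer(0)))
  }
  ev$type <- c(base = "snp", ins = "insertion", del = "deletion")[ev$event]
  counts <- ev[, list(pos_count = sum(strand == "+"),
                      neg_count = sum(strand == "-")),
               by = c("pos", "type", "allele", "refbase")]
  data.table::setnames(counts, c("allele", "refbase"), c("alt", "ref"))
  counts <- merge(counts, depth_tab, by = "pos", all.x = TRUE)
  counts <- merge(counts, depth_tab_m, by = "pos", all.x = TRUE)
  counts$depth[is.na(counts$depth)] <- 0L
  counts$depth_m[is.na(counts$depth_m)] <- 0L
  indel <- counts$type %in% c("insertion", "deletion")
  counts$depth[indel] <- counts$depth_m[indel]
  counts$depth_m <- NULL
  counts
}

# reference strand counts at positions of interest (for the exact test)
ref_strand_counts <- function(p, positions) {
  obs <- p$obs
  sel <- obs[obs$hq & obs$event == "base" & obs$pos %in% positions, ]
  sel$refbase <- substring(p$reference$sequence, sel$pos, sel$pos)
  sel <- sel[sel$allele == sel$refbase, ]
  out <- sel[, list(ref_pos = sum(strand == "+"), ref_neg = sum(strand == "-")),
             by = "pos"]
  out
}

finish_calls <- function(counts, run_label) {
  data.table::data.table(
    run = run_label, pos = counts$pos, type = counts$type,
    ref = counts$ref, alt = counts$alt,
    frequency = (counts$pos_count + counts$neg_count) / counts$depth,
    pos_count = counts$pos_count, neg_count = counts$neg_count,
    depth = counts$depth)
}

#' Naive filtered pileup caller
#'
#' Emits a SNP/indel call iff (a) high-quality alternate observations reach
#' `min_fraction` of the quality-read depth, (b) at least `min_quality_reads`
#' high-quality alternate observations are present on the positive strand
#' *and* on the negative strand, and (c) the strand-bias ratio
#' (positive/negative) lies strictly inside (`bias_low`, `bias_high`).
#'
#' @param p a `pileup` built with the calling thresholds (MQ >= 20 records,
#'   BQ >= 30 flagged as high quality).
#' @param min_fraction minimum alternate fraction of quality reads.
#' @param min_quality_reads per-strand minimum of high-quality alternate reads.
#' @param bias_low,bias_high strict bounds on the positive/negative ratio.
#' @param run_label label recorded on each call.
#' @return data.table of calls: `pos`, `type`, `ref`, `alt`, `frequency`,
#'   per-strand support and quality depth.
#' @export
call_naive <- function(p, min_fraction = 0.03, min_quality_reads = 5,
                       bias_low = 0.2, bias_high = 5.0, run_label = "run1") {
  counts <- alt_allele_table(p)
  if (nrow(counts) == 0L) return(finish_calls(counts, run_label))
  supp <- counts$pos_count + counts$neg_count
  keep <- supp >= min_fraction * counts$depth &
    counts$pos_count >= min_quality_reads &
    counts$neg_count >= min_quality_reads
  ratio <- counts$pos_count / counts$neg_count
  keep <- keep & ratio > bias_low & ratio < bias_high
  finish_calls(counts[keep, ], run_label)
}

#' Polymorphism-mode caller
#'
#' Emits a call iff the quality-read depth reaches `min_coverage`, the
#' alternate fraction reaches `min_freq`, and a two-sided exact test
#' ([stats::fisher.test]) of the 2x2 allele-by-strand table shows no
#' significant strand bias (p >= `bias_alpha`).
#'
#' @param p a `pileup`.
#' @param min_coverage minimum quality-read depth at the position.
#' @param min_freq minimum alternate fraction.
#' @param bias_alpha significance level below which a call is rejected for
#'   strand bias.
#' @param run_label label recorded on each call.
#' @return data.table of calls (same layout as [call_naive()]).
#' @export
call_polymode <- function(p, min_coverage = 5, min_freq = 0.05,
                          bias_alpha = 0.05, run_label = "run1") {
  counts <- alt_allele_table(p)
  if (nrow(counts) == 0L) return(finish_calls(counts, run_label))
  supp <- counts$pos_count + counts$neg_count
  counts <- counts[counts$depth >= min_coverage & supp >= min_freq * counts$depth, ]
  if (nrow(counts) == 0L) return(finish_calls(counts, run_label))
  refs <- ref_strand_counts(p, unique(counts$pos))
  counts <- merge(counts, refs, by = "pos", all.x = TRUE)
  counts$ref_pos[is.na(counts$ref_pos)] <- 0L
  counts$ref_neg[is.na(counts$ref_neg)] <- 0L
  pval <- vapply(seq_len(nrow(counts)), function(i) {
    tab <- matrix(c(counts$pos_count[i], counts$neg_count[i],
                    counts$ref_pos[i], counts$ref_neg[i]), nrow = 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  keep <- pval >= bias_alpha
  counts$ref_pos <- counts$ref_neg <- NULL
  finish_calls(counts[keep, ], run_label)
}

#' Build a mask of repeat and breakpoint regions
#'
#' Repeat intervals come from the genome annotation; breakpoint regions are
#' +/- `breakpoint_pad` bp around accepted structural junctions (IS insertion
#' sites, inversion edges, clip clusters), where clusters of false-positive
#' SNPs are expected.
#'
#' @param genome an `annotated_genome`.
#' @param breakpoints integer vector of junction positions.
#' @param breakpoint_pad padding around each junction (bp).
#' @return a data.frame of 1-based closed `start`/`end` intervals
#'   (class `mask_set`).
#' @export
make_mask <- function(genome, breakpoints = integer(0), breakpoint_pad = 10) {
  m <- genome$repeats[, c("start", "end")]
  if (length(breakpoints)) {
    m <- rbind(m, data.frame(start = pmax(1L, as.integer(breakpoints) - breakpoint_pad),
                             end = pmin(genome_length(genome),
                                        as.integer(breakpoints) + breakpoint_pad)))
  }
  structure(m, class = c("mask_set", "data.frame"))
}

#' Remove calls falling inside masked intervals
#'
#' @param calls a call table ([call_naive()], [call_polymode()] or
#'   [merge_runs()] output).
#' @param mask a [make_mask()] interval set.
#' @return the calls outside every mask interval.
#' @export
apply_mask <- function(calls, mask) {
  if (nrow(calls) == 0L || is.null(mask) || nrow(mask) == 0L) return(calls)
  calls[!pos_in_intervals(calls$pos, mask), ]
}

# Shift an indel call to its leftmost equivalent position (left alignment),
# so the same event is keyed identically across alignment runs.
left_normalize <- function(pos, type, alt, genome) {
  if (type == "insertion") {
    seqn <- sub("^\\+", "", alt)
    n <- nchar(seqn)
    while (pos > 1L) {
      last <- substr(seqn, n, n)
      if (substring(genome, pos, pos) != last) break
      seqn <- paste0(last, substr(seqn, 1L, n - 1L))
      pos <- pos - 1L
    }
    list(pos = pos, alt = paste0("+", seqn))
  } else if (type == "deletion") {
    len <- as.integer(sub("^-", "", alt))
    while (pos > 1L &&
           substring(genome, pos - 1L, pos - 1L) ==
           substring(genome, pos + len - 1L, pos + len - 1L)) {
      pos <- pos - 1L
    }
    list(pos = pos, alt = alt)
  } else {
    list(pos = pos, alt = alt)
  }
}

#' Merge per-run call sets under the consensus rule
#'
#' A consensus variant is emitted iff it was identified in at least
#' `min_runs` runs and its frequency averaged over *all* `n_runs_total` runs
#' (a run that did not call it contributing 0) reaches `min_mean_freq`.
#' Indels are matched across runs after left-alignment normalisation.
#'
#' @param run_calls list (length >= 2) of per-run call tables.
#' @param genome an `annotated_genome` (for indel normalisation; defaults to
#'   no normalisation if omitted).
#' @param n_runs_total number of alignment runs performed (denominator of the
#'   average; defaults to `length(run_calls)`).
#' @param min_runs minimum number of runs that must identify a variant.
#' @param min_mean_freq minimum mean frequency across all runs.
#' @param average `"total"` divides by `n_runs_total` (absent runs count 0);
#'   `"detected"` divides by the number of detecting runs.
#' @return data.table of consensus variants: `pos`, `type`, `ref`, `alt`,
#'   `mean_frequency`, `n_supporting_runs`, plus one `freq_<run>` column per
#'   run.
#' @export
merge_runs <- function(run_calls, genome = NULL, n_runs_total = NULL,
                       min_runs = 2, min_mean_freq = 0.05,
                       average = c("total", "detected")) {
  average <- match.arg(average)
  if (!is.list(run_calls) || length(run_calls) < 2L) {
    stop("input error: merge_runs needs at least 2 per-run call lists")
  }
  n_runs_total <- n_runs_total %||% length(run_calls)
  labels <- vapply(seq_along(run_calls), function(i) {
    rc <- run_calls[[i]]
    if (nrow(rc) && !is.null(rc$run)) as.character(rc$run[1]) else paste0("run", i)
  }, character(1))
  if (anyDuplicated(labels)) stop("input error: run labels must be distinct")

  norm <- function(rc) {
    if (nrow(rc) == 0L || is.null(genome)) return(rc)
    for (i in which(rc$type %in% c("insertion", "deletion"))) {
      ln <- left_normalize(rc$pos[i], rc$type[i], rc$alt[i], genome$sequence)
      rc$pos[i] <- ln$pos; rc$alt[i] <- ln$alt
    }
    rc
  }
  all_calls <- data.table::rbindlist(lapply(seq_along(run_calls), function(i) {
    rc <- norm(data.table::as.data.table(run_calls[[i]]))
    if (nrow(rc) == 0L) return(NULL)
    data.table::data.table(label = labels[i], pos = rc$pos, type = rc$type,
                           ref = rc$ref, alt = rc$alt, frequency = rc$frequency)
  }))
  if (is.null(all_calls) || nrow(all_calls) == 0L) {
    return(data.table::data.table(pos = integer(0), type = character(0),
                                  ref = character(0), alt = character(0),
                                  mean_frequency = numeric(0),
                                  n_supporting_runs = integer(0)))
  }
  agg <- all_calls[, list(n_supporting_runs = .N, total_freq = sum(frequency)),
                   by = c("pos", "type", "ref", "alt")]
  denom <- if (average == "total") n_runs_total else agg$n_supporting_runs
  agg$mean_frequency <- agg$total_freq / denom
  wide <- data.table::dcast(all_calls, pos + type + ref + alt ~ label,
                            value.var = "frequency", fill = 0)
  data.table::setnames(wide, setdiff(names(wide), c("pos", "type", "ref", "alt")),
                       paste0("freq_", setdiff(names(wide), c("pos", "type", "ref", "alt"))))
  out <- merge(agg, wide, by = c("pos", "type", "ref", "alt"))
  out$total_freq <- NULL
  out <- out[out$n_supporting_runs >= min_runs & out$mean_frequency >= min_mean_freq, ]
  data.table::setorder(out, pos)
  out[]
}
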