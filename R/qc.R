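#' Quality-control parameters for read trimming
#'
#' Defaults mirror common practice for pooled-population libraries: 4 bp
#' sliding windows trimmed from both ends until the window mean quality
#' reaches 20, then a 100 bp minimum length and a minimum 50% of bases at
#' phred >= 20.
#'
#' @param window sliding window size in bp.
#' @param min_window_q minimum mean phred quality of a retained window.
#' @param min_length minimum surviving read length in bp.
#' @param min_q20_fraction minimum fraction of bases at phred >= 20.
#' @return a `qc_params` list.
#' @export
qc_params <- function(window = 4, min_window_q = 20, min_length = 100,
                      min_q20_fraction = 0.5) {
  stopifnot(window >= 1, min_length >= window)
  structure(list(window = as.integer(window), min_window_q = min_window_q,
                 min_length = as.integer(min_length),
                 min_q20_fraction = min_q20_fraction), class = "qc_params")
}

#' Trim a single read by sliding-window quality
#'
#' Windows of `params$window` bp step 1 bp inwards from the 5' end, then from
#' the 3' end of what remains; bases are removed while the window mean quality
#' is below `params$min_window_q`. The survivor is kept only if it is at least
#' `params$min_length` bp long and at least `params$min_q20_fraction` of its
#' bases have phred >= 20. The output is always a contiguous subsequence of
#' the input, and trimming is idempotent.
#'
#' @param bases read sequence (string).
#' @param qualities phred+33 quality string, or integer vector.
#' @param params a [qc_params()] object.
#' @return list with `kept` (logical), and when kept: `bases`, `qualities`
#'   (same representation as input), `start`, `end` (1-based positions of the
#'   retained segment in the input read).
#' @export
trim_read <- function(bases, qualities, params = qc_params()) {
  qint <- if (is.character(qualities)) utf8ToInt(qualities) - 33L else as.integer(qualities)
  n <- length(qint)
  if (n != nchar(bases)) stop("bases and qualities differ in length")
  if (n == 0L) return(list(kept = FALSE))
  w <- params$window
  if (n < w) return(list(kept = FALSE))
  cs <- c(0, cumsum(qint))
  wmean <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w  # mean of window starting at i
  ok <- wmean >= params$min_window_q
  first <- which(ok)
  if (length(first) == 0L) return(list(kept = FALSE))
  s <- first[1L]
  # 3' side: last window (ending at j) with acceptable mean, within [s, n]
  last_ok <- which(ok & seq_along(ok) >= s)
  e <- max(last_ok) + w - 1L
  len <- e - s + 1L
  if (len < params$min_length) return(list(kept = FALSE))
  qseg <- qint[s:e]
  if (mean(qseg >= 20L) < params$min_q20_fraction) return(list(kept = FALSE))
  list(kept = TRUE,
       bases = substr(bases, s, e),
       qualities = if (is.character(qualities)) intToUtf8(qseg + 33L) else qseg,
       start = s, end = e)
}

#' Trim a read pair; discard the pair unless both mates survive
#'
#' Mates are trimmed independently with [trim_read()]; a pair in which either
#' mate is discarded is discarded entirely (so downstream stages only ever see
#' complete pairs).
#'
#' @param r1_bases,r1_qualities,r2_bases,r2_qualities the two mates.
#' @param params a [qc_params()] object.
#' @return list with `kept` and, when kept, the trimmed `r1`/`r2` sub-lists.
#' @export
filter_pair <- function(r1_bases, r1_qualities, r2_bases, r2_qualities,
                        params = qc_params()) {
  t1 <- trim_read(r1_bases, r1_qualities, params)
  if (!t1$kept) return(list(kept = FALSE))
  t2 <- trim_read(r2_bases, r2_qualities, params)
  if (!t2$kept) return(list(kept = FALSE))
  list(kept = TRUE, r1 = t1, r2 = t2)
}

#' Trim every pair of a read set
#'
#' @param rs a `read_set`.
#' @param params a [qc_params()] object.
#' @return the surviving pairs as a trimmed `read_set` (sequences/qualities
#'   replaced by their trimmed segments; `trim_offset1`/`trim_offset2` record
#'   the 0-based offset of each retained segment within the original mate).
#' @export
trim_pairs <- function(rs, params = qc_params()) {
  n <- n_pairs(rs)
  keep <- logical(n)
  s1 <- s2 <- character(n)
  q1 <- q2 <- character(n)
  o1 <- o2 <- integer(n)
  for (i in seq_len(n)) {
    t <- filter_pair(rs$r1_seq[i], rs$r1_qual[i], rs$r2_seq[i], rs$r2_qual[i], params)
    if (t$kept) {
      keep[i] <- TRUE
      s1[i] <- t$r1$bases; q1[i] <- t$r1$qualities; o1[i] <- t$r1$start - 1L
      s2[i] <- t$r2$bases; q2[i] <- t$r2$qualities; o2[i] <- t$r2$start - 1L
    }
  }
  out <- subset_pairs(rs, which(keep))
  out$r1_seq <- s1[keep]; out$r1_qual <- q1[keep]
  out$r2_seq <- s2[keep]; out$r2_qual <- q2[keep]
  out$trim_offset1 <- o1[keep]; out$trim_offset2 <- o2[keep]
  out
}

# k-mer dictionary over a set of reference sequences (both strands).
# Returns list(kmers=character vector, ref=integer ref id per kmer entry).
build_kmer_dict <- function(seqs, k) {
  kml <- lapply(seqs, function(s) unique(c(seq_kmers(s, k), seq_kmers(revcomp(s), k))))
  data.frame(kmer = unlist(kml, use.names = FALSE),
             ref = rep.int(seq_along(seqs), lengths(kml)))
}

# per-reference unique k-mer sets (both strands); a k-mer present in several
# references scores for each of them, so identical tracts tie
build_kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) unique(c(seq_kmers(s, k), seq_kmers(revcomp(s), k))))
}

#' Partition read pairs among invader, resident, plasmid and unassigned bins
#'
#' Both mates of each pair are decomposed into k-mers and scored against each
#' reference (invader chromosome; resident chromosome; resident plasmids
#' pooled) by the number of shared k-mers. A pair is binned with the strictly
#' highest-scoring reference if that score reaches `min_score`; ties and
#' sub-threshold scores go to `unassigned`, so reads matching neither strain
#' are quarantined rather than double-counted.
#'
#' @param rs a `read_set`.
#' @param invader `annotated_genome` of the focal strain.
#' @param resident `annotated_genome` of the resident strain (or `NULL`).
#' @param plasmids named character vector of plasmid sequences (defaults to
#'   `resident$plasmids`).
#' @param k k-mer size (must not exceed the read length).
#' @param min_score minimum shared-k-mer count for assignment.
#' @param chunk_size pairs scored per internal chunk (memory control).
#' @return a `partition_result`: list of `read_set` bins (`invader`,
#'   `resident`, `plasmid`, `unassigned`) plus a `scores` matrix.
#' @export
partition_reads <- function(rs, invader, resident = NULL, plasmids = NULL,
                            k = 21, min_score = 10, chunk_size = 4000) {
  rl <- min(nchar(c(rs$r1_seq, rs$r2_seq)))
  if (k > rl) stop("parameter error: k exceeds the shortest read length")
  if (is.null(plasmids) && !is.null(resident)) plasmids <- resident$plasmids
  refs <- list(invader = invader$sequence)
  if (!is.null(resident)) refs$resident <- resident$sequence
  plasmid_seq <- if (length(plasmids)) paste(plasmids, collapse = strrep("N", k)) else NULL
  if (!is.null(plasmid_seq)) refs$plasmid <- plasmid_seq
  sets <- build_kmer_sets(unname(unlist(refs)), k)
  nref <- length(refs)

  n <- n_pairs(rs)
  scores <- matrix(0L, n, nref, dimnames = list(NULL, names(refs)))
  for (lo in seq(1L, n, by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, n)
    idx <- lo:hi
    km1 <- lapply(rs$r1_seq[idx], seq_kmers, k = k)
    km2 <- lapply(rs$r2_seq[idx], seq_kmers, k = k)
    pair_id <- c(rep.int(idx, lengths(km1)), rep.int(idx, lengths(km2)))
    kms <- c(unlist(km1, use.names = FALSE), unlist(km2, use.names = FALSE))
    for (r in seq_len(nref)) {
      found <- kms %in% sets[[r]]
      if (any(found)) {
        tab <- rowsum(found + 0L, factor(pair_id, levels = idx))
        scores[idx, r] <- scores[idx, r] + as.integer(tab)
      }
    }
  }
  # shared k-mers (present in >1 reference) count for each, so identical
  # regions produce ties, which fall through to unassigned
  best <- max.col(scores, ties.method = "first")
  top <- scores[cbind(seq_len(n), best)]
  n_at_top <- rowSums(scores == top)
  bin <- ifelse(top >= min_score & n_at_top == 1L, names(refs)[best], "unassigned")
  bins <- lapply(c("invader", "resident", "plasmid", "unassigned"),
                 function(b) subset_pairs(rs, which(bin == b)))
  names(bins) <- c("invader", "resident", "plasmid", "unassigned")
  structure(list(bins = bins, scores = scores, bin = bin), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  sizes <- vapply(x$bins, n_pairs, integer(1))
  cat("<partition_result> pairs per bin:\n")
  print(sizes)
  invisible(x)
}

#' Write partitioned bins as four FASTQ pairs
#'
#' Files are named `<prefix>.<bin>.R1.fastq` / `.R2.fastq` for the four bins.
#'
#' @param pr a `partition_result`.
#' @param prefix output path prefix (typically the sample name).
#' @return invisibly, the paths written.
#' @export
write_partition <- function(pr, prefix) {
  paths <- character(0)
  for (b in names(pr$bins)) {
    if (n_pairs(pr$bins[[b]]) == 0L) next
    paths <- c(paths, write_fastq_pair(pr$bins[[b]], paste0(prefix, ".", b)))
  }
  invisible(paths)
}
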