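#' Simulate paired-end reads from a haplotype population
#'
#' Draws a Poisson number of fragments (expected pairs =
#' `coverage * genome_length / (2 * read_length)`), samples source haplotypes
#' by weight, and emits 2 x `read_length` bp read pairs (mate 2 reverse
#' complemented). Base qualities follow a two-state model: a high-quality
#' state whose phred score matches `error_rate`, and low-quality (Q10) tails
#' of geometric length appended to read ends, sequenced at 10% error, so
#' quality trimming has realistic work to do. Optionally a fraction of extra
#' pairs is drawn from a contaminating resident genome and its plasmids;
#' every pair carries exactly one truth tag.
#'
#' @param population a `hap_population` from [plant_variants()], or an
#'   `annotated_genome` (treated as a single-haplotype population).
#' @param coverage target fold-coverage of the focal genome.
#' @param read_length read length in bp (default 250).
#' @param fragment_mean,fragment_sd insert-size distribution (bp).
#' @param error_rate per-base sequencing error rate in the high-quality state.
#' @param contamination `NULL`, or `list(genome = <annotated_genome>,
#'   fraction = <fraction of all pairs>)`.
#' @param seed integer RNG seed.
#' @param tail_prob probability that a read end carries a degraded Q10 tail.
#' @return an object of class `read_set`: data.frame-like list with per-pair
#'   sequences, qualities, truth tags (`invader:hap<i>`, `resident`,
#'   `plasmid:<name>`) and fragment coordinates.
#' @export
simulate_reads <- function(population, coverage, read_length = 250,
                           fragment_mean = 500, fragment_sd = 60,
                           error_rate = 0.001, contamination = NULL,
                           seed = 1, tail_prob = 0.2) {
  if (inherits(population, "annotated_genome")) {
    population <- structure(list(haplotypes = population$sequence, weights = 1,
                                 truth = NULL, genome = population),
                            class = "hap_population")
  }
  if (length(population$haplotypes) == 0L) stop("input error: empty population")
  stopifnot(coverage > 0, read_length <= fragment_mean)
  L <- genome_length(population$genome)

  with_seed(seed, {
    n_inv <- stats::rpois(1, coverage * L / (2 * read_length))
    # fragments are sampled from the pooled DNA, i.e. proportional to cell
    # weight times haplotype length, so per-base coverage is uniform across
    # haplotypes of unequal length (prophage presence/absence, insertions)
    src_hap <- sample.int(length(population$haplotypes), n_inv, replace = TRUE,
                          prob = population$weights * nchar(population$haplotypes))
    src_seq_id <- rep("invader", n_inv)
    tags <- paste0("invader:hap", src_hap)
    seq_pool <- population$haplotypes
    pool_id <- src_hap

    if (!is.null(contamination) && contamination$fraction > 0) {
      frac <- contamination$fraction
      res <- contamination$genome
      n_cont <- stats::rpois(1, n_inv * frac / (1 - frac))
      cont_seqs <- c(setNames(res$sequence, "resident"), res$plasmids)
      cont_tags <- c("resident", paste0("plasmid:", names(res$plasmids)))
      pick <- sample.int(length(cont_seqs), n_cont, replace = TRUE,
                         prob = nchar(cont_seqs))
      seq_pool <- c(seq_pool, cont_seqs)
      pool_id <- c(pool_id, length(population$haplotypes) + pick)
      tags <- c(tags, cont_tags[pick])
      n_inv <- n_inv + n_cont
    }

    n <- length(pool_id)
    if (n == 0L) stop("input error: no fragments drawn")
    src_len <- nchar(seq_pool)[pool_id]
    flen <- pmax(read_length, pmin(src_len,
             as.integer(round(stats::rnorm(n, fragment_mean, fragment_sd)))))
    fstart <- 1L + as.integer(floor(stats::runif(n) * (src_len - flen + 1L)))
    hapseq <- seq_pool[pool_id]
    r1 <- substr(hapseq, fstart, fstart + read_length - 1L)
    r2 <- revcomp(substr(hapseq, fstart + flen - read_length, fstart + flen - 1L))

    qh <- if (error_rate <= 0) 40L else max(2L, min(40L, as.integer(round(-10 * log10(error_rate)))))
    mk_mate <- function(seqs) {
      nn <- length(seqs)
      rl <- nchar(seqs)
      # degraded tails: 3' commonly, 5' rarely (a quarter of the 3' rate)
      t3 <- ifelse(stats::runif(nn) < tail_prob, pmin(rl - 30L, stats::rgeom(nn, 1 / 40) + 5L), 0L)
      t5 <- ifelse(stats::runif(nn) < tail_prob / 4, pmin(rl - 30L - t3, stats::rgeom(nn, 1 / 15) + 3L), 0L)
      t3 <- pmax(t3, 0L); t5 <- pmax(t5, 0L)
      quals <- vapply(seq_len(nn), function(i) {
        q <- rep.int(qh, rl[i])
        if (t5[i] > 0) q[seq_len(t5[i])] <- 10L
        if (t3[i] > 0) q[(rl[i] - t3[i] + 1L):rl[i]] <- 10L
        intToUtf8(q + 33L)
      }, character(1))
      # sequencing errors: error_rate in the high state, 0.1 in Q10 tails;
      # error_rate = 0 means a strictly error-free instrument everywhere
      n_err_hi <- stats::rbinom(nn, pmax(rl - t3 - t5, 0L), if (error_rate > 0) error_rate else 0)
      n_err_lo <- stats::rbinom(nn, t3 + t5, if (error_rate > 0) 0.1 else 0)
      for (i in which(n_err_hi + n_err_lo > 0L)) {
        hi_idx <- setdiff(seq_len(rl[i]),
                          c(seq_len(t5[i]), if (t3[i] > 0) (rl[i] - t3[i] + 1L):rl[i]))
        lo_idx <- setdiff(seq_len(rl[i]), hi_idx)
        pos <- c(if (n_err_hi[i] > 0 && length(hi_idx))
                   hi_idx[sample.int(length(hi_idx), min(n_err_hi[i], length(hi_idx)))],
                 if (n_err_lo[i] > 0 && length(lo_idx))
                   lo_idx[sample.int(length(lo_idx), min(n_err_lo[i], length(lo_idx)))])
        for (p in pos) {
          old <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- sample(setdiff(BASES, old), 1)
        }
      }
      list(seq = seqs, qual = quals)
    }
    m1 <- mk_mate(r1)
    m2 <- mk_mate(r2)

    structure(list(
      id = sprintf("frag%06d", seq_len(n)),
      r1_seq = m1$seq, r1_qual = m1$qual,
      r2_seq = m2$seq, r2_qual = m2$qual,
      source = tags, hap = ifelse(grepl("^invader", tags), pool_id, NA_integer_),
      frag_start = ifelse(grepl("^invader", tags), fstart, NA_integer_),
      frag_len = flen,
      read_length = read_length,
      genome = population$genome,
      truth = population$truth
    ), class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d read pairs (%d bp), truth tags: %s\n",
              length(x$id), x$read_length,
              paste(names(table(sub(":.*", "", x$source))), collapse = ", ")))
  invisible(x)
}

n_pairs <- function(rs) length(rs$id)

# subset a read_set by pair index
subset_pairs <- function(rs, idx) {
  out <- rs
  for (f in c("id", "r1_seq", "r1_qual", "r2_seq", "r2_qual", "source",
              "hap", "frag_start", "frag_len")) {
    out[[f]] <- rs[[f]][idx]
  }
  out
}

#' Write a read set as a FASTQ pair plus truth-tag table
#'
#' Emits `<prefix>.R1.fastq`, `<prefix>.R2.fastq` (phred+33) and
#' `<prefix>.truth.tsv` (pair id, truth tag). Byte-identical for identical
#' simulations.
#'
#' @param rs a `read_set`.
#' @param prefix output path prefix.
#' @return invisibly, the three paths.
#' @export
write_fastq_pair <- function(rs, prefix) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  p1 <- paste0(prefix, ".R1.fastq"); p2 <- paste0(prefix, ".R2.fastq")
  pt <- paste0(prefix, ".truth.tsv")
  write_one(rs$r1_seq, rs$r1_qual, paste0(rs$id, "/1"), p1)
  write_one(rs$r2_seq, rs$r2_qual, paste0(rs$id, "/2"), p2)
  utils::write.table(data.frame(id = rs$id, source = rs$source),
                     pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, pt))
}

#' Read a FASTQ pair into a read set
#'
#' @param prefix path prefix as used by [write_fastq_pair()].
#' @param genome optional `annotated_genome` to attach.
#' @return a `read_set` (truth tags restored if the truth table is present).
#' @export
read_fastq_pair <- function(prefix, genome = NULL) {
  rd <- function(path) {
    # readQualityScaledDNAStringSet warns about dropping the (unused) mcols
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    list(seq = as.character(x), qual = as.character(Biostrings::quality(x)))
  }
  m1 <- rd(paste0(prefix, ".R1.fastq"))
  m2 <- rd(paste0(prefix, ".R2.fastq"))
  ids <- sub("/1$", "", names(m1$seq))
  pt <- paste0(prefix, ".truth.tsv")
  src <- if (file.exists(pt)) utils::read.delim(pt)$source else rep(NA_character_, length(ids))
  structure(list(id = ids, r1_seq = unname(m1$seq), r1_qual = unname(m1$qual),
                 r2_seq = unname(m2$seq), r2_qual = unname(m2$qual),
                 source = src, hap = NA_integer_, frag_start = NA_integer_,
                 frag_len = NA_integer_,
                 read_length = max(nchar(m1$seq)), genome = genome, truth = NULL),
            class = "read_set")
}
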