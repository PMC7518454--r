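# Internal helpers shared across modules.

.datatable.aware <- TRUE

BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# All k-mers of a single sequence, as a character vector (1-based start order).
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

# Number of mismatching characters between equal-length string pairs,
# vectorised over pairs via one flat comparison.
count_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  la <- nchar(a)
  if (any(la != nchar(b))) stop("count_mismatches: unequal string lengths")
  av <- unlist(strsplit(a, "", fixed = TRUE), use.names = FALSE)
  bv <- unlist(strsplit(b, "", fixed = TRUE), use.names = FALSE)
  idx <- rep.int(seq_along(a), la)
  out <- integer(length(a))
  tab <- rowsum((av != bv) + 0L, idx)
  out[as.integer(rownames(tab))] <- as.integer(tab)
  out
}

# Phred+33 string <-> integer qualities.
qual_to_int <- function(q) {
  if (length(q) == 1L) utf8ToInt(q) - 33L else lapply(q, function(x) utf8ToInt(x) - 33L)
}

int_to_qual <- function(q) {
  vapply(q, function(x) intToUtf8(x + 33L), character(1))
}

# Does 1-based closed interval [s1,e1] overlap [s2,e2]?
intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

# Position(s) falling in any of the 1-based closed intervals (data.frame start/end).
pos_in_intervals <- function(pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (pos >= intervals$start[i] & pos <= intervals$end[i])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
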