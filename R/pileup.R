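# Per-position pileups from alignment records.

#' Build a pileup from alignment records
#'
#' One observation row per aligned base (or indel token) per record.
#' Records below `min_mapq` are excluded entirely; observations below
#' `min_baseq` are retained but flagged (`hq = FALSE`) so callers can apply
#' quality-read counts. Insertions attach to the reference base immediately
#' left of the inserted sequence (token `+SEQ`); deletions emit a `*`
#' placeholder on every deleted position plus a `-N` event token on the first
#' deleted position.
#'
#' @param records an `alignment_set` (must be coordinate-sorted, as produced
#'   by [align_reads()] / [read_alignment_file()]).
#' @param reference an `annotated_genome` (defaults to the records'
#'   `reference` attribute).
#' @param min_mapq minimum mapping quality for a record to contribute.
#' @param min_baseq minimum base quality for the `hq` flag.
#' @return a `pileup` object: list with `obs` (data.table: `pos`, `obs`,
#'   `event`, `bq`, `strand`, `hq`) and the filter parameters.
#' @export
build_pileup <- function(records, reference = NULL, min_mapq = 20, min_baseq = 30) {
  reference <- reference %||% attr(records, "reference")
  rec <- records[records$mapped & records$mapq >= min_mapq, ]
  if (nrow(rec) > 1L && is.unsorted(rec$pos)) {
    stop("ordering error: records must be coordinate-sorted")
  }
  simple <- grepl("^[0-9]+M$", rec$cigar)

  obs_chunks <- list()
  if (any(simple)) {
    sr <- rec[simple, ]
    lens <- nchar(sr$seq)
    offv <- sequence(lens)
    posv <- rep.int(sr$pos, lens) + offv - 1L
    basev <- unlist(strsplit(sr$seq, "", fixed = TRUE), use.names = FALSE)
    bqv <- utf8ToInt(paste(sr$qual, collapse = "")) - 33L
    strandv <- rep.int(sr$strand, lens)
    marginv <- pmin(offv - 1L, rep.int(lens, lens) - offv)
    obs_chunks[[1]] <- data.table::data.table(
      pos = posv, allele = basev, event = "base", bq = bqv, strand = strandv,
      margin = marginv)
  }
  if (any(!simple)) {
    cr <- rec[!simple, ]
    lst <- vector("list", nrow(cr))
    for (j in seq_len(nrow(cr))) {
      lst[[j]] <- pileup_one_record(cr$pos[j], cr$cigar[j], cr$seq[j],
                                    cr$qual[j], cr$strand[j])
    }
    obs_chunks[[length(obs_chunks) + 1L]] <- data.table::rbindlist(lst)
  }
  obs <- if (length(obs_chunks)) data.table::rbindlist(obs_chunks) else
    data.table::data.table(pos = integer(0), allele = character(0),
                           event = character(0), bq = integer(0),
                           strand = character(0), margin = integer(0))
  obs$hq <- obs$bq >= min_baseq
  data.table::setkey(obs, pos)
  structure(list(obs = obs, reference = reference,
                 min_mapq = min_mapq, min_baseq = min_baseq),
            class = "pileup")
}

# observations contributed by one record with a non-trivial cigar; `margin`
# is the distance from each observation to the nearer end of the record's
# aligned reference span (an indel can only be expressed by reads whose
# alignment extends well past it)
pileup_one_record <- function(pos, cigar, seq, qual, strand) {
  ops <- parse_cigar(cigar)
  qint <- utf8ToInt(qual) - 33L
  span_end <- pos + sum(ops$len[ops$op %in% c("M", "D")]) - 1L
  marg <- function(p) pmin(p - pos, span_end - p)
  rpos <- pos            # reference cursor
  qpos <- 1L             # read cursor
  out <- list()
  prev_q <- 30L
  for (r in seq_len(nrow(ops))) {
    op <- ops$op[r]; ln <- ops$len[r]
    if (op == "M") {
      p <- rpos:(rpos + ln - 1L)
      out[[length(out) + 1L]] <- data.table::data.table(
        pos = p, allele = substring(seq, qpos:(qpos + ln - 1L), qpos:(qpos + ln - 1L)),
        event = "base", bq = qint[qpos:(qpos + ln - 1L)], strand = strand,
        margin = marg(p))
      prev_q <- qint[qpos + ln - 1L]
      rpos <- rpos + ln; qpos <- qpos + ln
    } else if (op == "I") {
      insq <- min(qint[qpos:(qpos + ln - 1L)])
      out[[length(out) + 1L]] <- data.table::data.table(
        pos = rpos - 1L, allele = paste0("+", substr(seq, qpos, qpos + ln - 1L)),
        event = "ins", bq = insq, strand = strand, margin = marg(rpos - 1L))
      qpos <- qpos + ln
    } else if (op == "D") {
      dq <- min(prev_q, if (qpos <= length(qint)) qint[qpos] else prev_q)
      out[[length(out) + 1L]] <- data.table::data.table(
        pos = rpos, allele = paste0("-", ln), event = "del", bq = dq,
        strand = strand, margin = marg(rpos))
      out[[length(out) + 1L]] <- data.table::data.table(
        pos = rpos:(rpos + ln - 1L), allele = "*", event = "del_span", bq = dq,
        strand = strand, margin = marg(rpos:(rpos + ln - 1L)))
      rpos <- rpos + ln
    } else if (op %in% c("S", "H")) {
      if (op == "S") qpos <- qpos + ln
    } else {
      stop(sprintf("unsupported cigar op '%s'", op))
    }
  }
  data.table::rbindlist(out)
}

parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDSH]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDSH]", cigar))[[1]]
  if (length(toks) == 0L || nchar(paste(toks, collapse = "")) != nchar(cigar)) {
    stop(sprintf("malformed cigar '%s'", cigar))
  }
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

#' Depth and observations of one pileup column
#'
#' @param p a `pileup`.
#' @param position 1-based reference position.
#' @return list with `depth` (all aligned observations), `hq_depth`
#'   (observations at or above the base-quality threshold) and the
#'   observation table.
#' @export
pileup_column <- function(p, position) {
  col <- p$obs[p$obs$pos == position & p$obs$event %in% c("base", "del_span"), ]
  evs <- p$obs[p$obs$pos == position & !(p$obs$event %in% c("base", "del_span")), ]
  list(depth = nrow(col), hq_depth = sum(col$hq), observations = col, events = evs)
}

#' Per-position depth of a pileup
#'
#' @param p a `pileup`.
#' @param hq_only count only observations at or above the base-quality
#'   threshold.
#' @return data.table with `pos` and `depth`.
#' @export
pileup_depth <- function(p, hq_only = FALSE) {
  obs <- p$obs[p$obs$event %in% c("base", "del_span"), ]
  if (hq_only) obs <- obs[obs$hq, ]
  out <- obs[, list(depth = .N), by = "pos"]
  data.table::setorder(out, pos)
  out[]
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d observations over %d positions (MQ>=%d, BQ>=%d flagged)\n",
              nrow(x$obs), length(unique(x$obs$pos)), x$min_mapq, x$min_baseq))
  invisible(x)
}

#' Write alignment records to a SAM file
#'
#' Coordinate-sorted SAM with `@HD`/`@SQ` headers; sequences and qualities
#' are stored in reference orientation (mate and strand recorded in FLAG).
#'
#' @param records an `alignment_set`.
#' @param path output path.
#' @param reference an `annotated_genome` (defaults to the records' attribute).
#' @return invisibly, `path`.
#' @export
write_sam <- function(records, path, reference = NULL) {
  reference <- reference %||% attr(records, "reference")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", reference$name, genome_length(reference)))
  rec <- records[order(!records$mapped, records$pos), ]
  flag <- 1L + ifelse(rec$mate == 1L, 64L, 128L) +
    ifelse(rec$mapped & rec$strand == "-", 16L, 0L) +
    ifelse(rec$mapped, 0L, 4L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                   rec$qname, flag,
                   ifelse(rec$mapped, rec$rname, "*"),
                   ifelse(rec$mapped, rec$pos, 0L),
                   ifelse(rec$mapped, rec$mapq, 0L),
                   ifelse(rec$mapped, rec$cigar, "*"),
                   rec$seq, rec$qual)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read alignment records from a SAM/BAM file
#'
#' Imports via [Rsamtools] (SAM is converted to BAM internally), keeping
#' position, strand, cigar, mapping quality, sequence and base qualities.
#' Records naming a reference sequence other than the supplied genome are a
#' parse error.
#'
#' @param path SAM or BAM file.
#' @param reference an `annotated_genome` the records must refer to.
#' @param run_label label to record on the imported records.
#' @return an `alignment_set` (coordinate-sorted).
#' @export
read_alignment_file <- function(path, reference, run_label = basename(path)) {
  is_sam <- !grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    tmp <- tempfile(fileext = ".bam")
    tryCatch(Rsamtools::asBam(path, destination = sub("\\.bam$", "", tmp),
                              overwrite = TRUE, indexDestination = FALSE),
             error = function(e) stop(sprintf("parse error in '%s': %s", path,
                                              conditionMessage(e))))
  } else path
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "seq", "qual")))[[1]]
  rn <- as.character(res$rname)
  if (any(!is.na(rn) & rn != reference$name)) {
    bad <- unique(rn[!is.na(rn) & rn != reference$name])
    stop(sprintf("parse error: reference name(s) %s absent from the genome",
                 paste(bad, collapse = ", ")))
  }
  mapped <- !bitwAnd(res$flag, 4L)
  mate <- ifelse(bitwAnd(res$flag, 128L) > 0L, 2L, 1L)
  rec <- data.table::data.table(
    run = run_label, qname = res$qname, mate = mate, rname = reference$name,
    pos = ifelse(mapped, res$pos, NA_integer_),
    strand = ifelse(mapped, ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+"),
                    NA_character_),
    mapq = ifelse(mapped, res$mapq, NA_integer_),
    cigar = ifelse(mapped, res$cigar, NA_character_),
    seq = as.character(res$seq), qual = as.character(res$qual),
    mapped = mapped)
  data.table::setorder(rec, pos, na.last = TRUE)
  data.table::setattr(rec, "reference", reference)
  data.table::setattr(rec, "class", c("alignment_set", class(rec)))
  rec[]
}
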