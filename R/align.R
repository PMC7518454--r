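# Minimal deterministic seed-and-extend aligner.
#
# Strategy: exact k-mer seeds at the left end, right end and middle of each
# read (both orientations) nominate a candidate diagonal; candidates are
# verified in bulk by mismatch counting. Reads failing ungapped verification
# are resolved one at a time: a pair of anchors on different diagonals implies
# an indel (placed by minimising mismatches, ties broken leftwards, i.e.
# left-aligned); a single anchor with a garbage tail is soft-clipped
# (structural junctions, genome edges). Mapping quality is two-valued:
# 60 for unique seed placement, 0 when only ambiguous (repetitive) seeds hit.

#' Construct a read set from raw vectors
#'
#' Convenience constructor used for hand-built fixtures; [simulate_reads()]
#' is the usual source of read sets.
#'
#' @param r1_seq,r1_qual,r2_seq,r2_qual mate sequences and phred+33 qualities.
#' @param id pair identifiers.
#' @param genome optional `annotated_genome` to attach.
#' @param source optional truth tags.
#' @return a `read_set`.
#' @export
read_pair_set <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                          id = sprintf("pair%04d", seq_along(r1_seq)),
                          genome = NULL, source = NA_character_) {
  stopifnot(length(r1_seq) == length(r2_seq))
  structure(list(id = id, r1_seq = r1_seq, r1_qual = r1_qual,
                 r2_seq = r2_seq, r2_qual = r2_qual,
                 source = rep_len(source, length(r1_seq)),
                 hap = NA_integer_, frag_start = NA_integer_, frag_len = NA_integer_,
                 read_length = max(nchar(c(r1_seq, r2_seq))), genome = genome,
                 truth = NULL), class = "read_set")
}

# k-mer index of the forward strand of one sequence
build_seed_index <- function(sequence, k) {
  km <- seq_kmers(sequence, k)
  amb <- duplicated(km) | duplicated(km, fromLast = TRUE)
  list(kmers = km, amb = amb, k = k)
}

# look up seeds: returns list(pos = first genome position or NA, amb = logical)
seed_lookup <- function(idx, seeds) {
  hit <- match(seeds, idx$kmers)
  list(pos = hit, amb = ifelse(is.na(hit), NA, idx$amb[hit]))
}

#' Align the reads of a read set to a reference genome
#'
#' @param rs a `read_set` (typically QC-trimmed).
#' @param reference an `annotated_genome`.
#' @param seed_length exact-seed length in bp.
#' @param max_mismatch_fraction maximum mismatch fraction for an accepted
#'   (possibly gapped) alignment.
#' @param run_label label recorded on every record (identifies the alignment
#'   run when several parameterisations are merged downstream).
#' @return an `alignment_set`: a [data.table::data.table] with one row per
#'   mate (`qname`, `mate`, `rname`, `pos`, `strand`, `mapq`, `cigar`, `seq`,
#'   `qual`, `mapped`), sequences stored in reference orientation, unmapped
#'   mates kept with `mapped = FALSE`. Attribute `reference` carries the
#'   genome.
#' @export
align_reads <- function(rs, reference, seed_length = 21,
                        max_mismatch_fraction = 0.1, run_label = "run1") {
  k <- as.integer(seed_length)
  genome <- reference$sequence
  L <- nchar(genome)
  idx <- build_seed_index(genome, k)

  seqs <- c(rs$r1_seq, rs$r2_seq)
  quals <- c(rs$r1_qual, rs$r2_qual)
  qname <- c(rs$id, rs$id)
  mate <- rep(c(1L, 2L), each = n_pairs(rs))
  n <- length(seqs)
  len <- nchar(seqs)
  if (any(len < k)) stop("parameter error: seed length exceeds a read length")

  fwd <- seqs
  rev <- revcomp(seqs)
  orient_seq <- list(F = fwd, R = rev)

  # anchors[[orient]][[off]] = list(pos, amb); offsets L=1, M=mid, R=len-k+1
  offs <- list(L = rep.int(1L, n),
               M = pmax(1L, (len - k) %/% 2L + 1L),
               R = len - k + 1L)
  anchors <- list()
  for (or in c("F", "R")) {
    anchors[[or]] <- list()
    for (of in c("L", "M", "R")) {
      sd <- substr(orient_seq[[or]], offs[[of]], offs[[of]] + k - 1L)
      anchors[[or]][[of]] <- seed_lookup(idx, sd)
    }
  }

  pos <- rep(NA_integer_, n); strand <- rep(NA_character_, n)
  mapq <- rep(NA_integer_, n); cigar <- rep(NA_character_, n)
  resolved <- logical(n)

  maxmm <- pmax(2L, floor(max_mismatch_fraction * len))

  # bulk ungapped passes
  for (pass in list(c("F", "L"), c("R", "L"), c("F", "R"), c("R", "R"),
                    c("F", "M"), c("R", "M"))) {
    or <- pass[1]; of <- pass[2]
    an <- anchors[[or]][[of]]
    cand <- an$pos - offs[[of]] + 1L
    try_idx <- which(!resolved & !is.na(an$pos) & !an$amb &
                     cand >= 1L & cand + len - 1L <= L)
    if (length(try_idx) == 0L) next
    rd <- orient_seq[[or]][try_idx]
    rf <- substring(genome, cand[try_idx], cand[try_idx] + len[try_idx] - 1L)
    mm <- count_mismatches(rd, rf)
    head_mm <- count_mismatches(substr(rd, 1L, 10L), substr(rf, 1L, 10L))
    tail_mm <- count_mismatches(substr(rd, len[try_idx] - 9L, len[try_idx]),
                                substr(rf, len[try_idx] - 9L, len[try_idx]))
    ok <- mm <= maxmm[try_idx] & head_mm <= 3L & tail_mm <= 3L
    acc <- try_idx[ok]
    pos[acc] <- cand[try_idx][ok]
    strand[acc] <- if (or == "F") "+" else "-"
    mapq[acc] <- 60L
    cigar[acc] <- paste0(len[acc], "M")
    resolved[acc] <- TRUE
  }

  # per-read gapped / clipped resolution for reads with at least one unique anchor
  todo <- which(!resolved)
  for (i in todo) {
    res <- resolve_read_gapped(i, orient_seq, anchors, offs, len[i], genome, L,
                               maxmm[i], k)
    if (!is.null(res)) {
      pos[i] <- res$pos; strand[i] <- res$strand
      mapq[i] <- res$mapq; cigar[i] <- res$cigar
      resolved[i] <- TRUE
    }
  }

  # ambiguous-only placement (repetitive seeds): first hit, mapq 0
  todo <- which(!resolved)
  for (or in c("F", "R")) {
    an <- anchors[[or]][["L"]]
    cand <- an$pos
    try_idx <- todo[!resolved[todo] & !is.na(an$pos[todo]) & an$amb[todo] &
                    cand[todo] + len[todo] - 1L <= L]
    if (length(try_idx) == 0L) next
    rd <- orient_seq[[or]][try_idx]
    rf <- substring(genome, cand[try_idx], cand[try_idx] + len[try_idx] - 1L)
    mm <- count_mismatches(rd, rf)
    ok <- mm <= maxmm[try_idx]
    acc <- try_idx[ok]
    pos[acc] <- cand[try_idx][ok]
    strand[acc] <- if (or == "F") "+" else "-"
    mapq[acc] <- 0L
    cigar[acc] <- paste0(len[acc], "M")
    resolved[acc] <- TRUE
  }

  mapped <- resolved
  out_seq <- ifelse(!mapped | strand == "+" | is.na(strand), seqs, rev)
  out_qual <- ifelse(!mapped | strand == "+" | is.na(strand), quals,
                     vapply(quals, function(q) intToUtf8(rev(utf8ToInt(q))), character(1)))
  rec <- data.table::data.table(
    run = run_label, qname = qname, mate = mate, rname = reference$name,
    pos = pos, strand = strand, mapq = mapq, cigar = cigar,
    seq = out_seq, qual = out_qual, mapped = mapped)
  data.table::setorder(rec, pos, na.last = TRUE)
  data.table::setattr(rec, "reference", reference)
  data.table::setattr(rec, "class", c("alignment_set", class(rec)))
  rec[]
}

# Resolve one read using its stored anchors: indel placement from an anchor
# pair on different diagonals, else soft-clip around a single anchor.
resolve_read_gapped <- function(i, orient_seq, anchors, offs, n, genome, L,
                                maxmm, k) {
  best <- NULL
  for (or in c("F", "R")) {
    ans <- list()
    for (of in c("L", "M", "R")) {
      a <- anchors[[or]][[of]]
      if (!is.na(a$pos[i]) && !a$amb[i]) {
        ans[[of]] <- c(off = offs[[of]][i], pos = a$pos[i])
      }
    }
    if (length(ans) == 0L) next
    read <- substr(orient_seq[[or]][i], 1L, n)
    a_int <- utf8ToInt(read)
    diag_of <- vapply(ans, function(x) x["pos"] - x["off"] + 1L, numeric(1))

    # indel attempt: two anchors, distinct diagonals, shift <= 20 bp
    if (length(unique(diag_of)) >= 2L) {
      o_sorted <- ans[order(vapply(ans, `[`, numeric(1), "off"))]
      d1 <- o_sorted[[1]]["pos"] - o_sorted[[1]]["off"] + 1L
      d2 <- o_sorted[[length(o_sorted)]]["pos"] - o_sorted[[length(o_sorted)]]["off"] + 1L
      delta <- as.integer(d2 - d1)
      if (delta != 0L && abs(delta) <= 20L && d1 >= 1L && d1 + n + max(delta, 0L) - 1L <= L) {
        cand <- place_indel(a_int, genome, as.integer(d1), n, delta)
        if (!is.null(cand) && cand$mm <= maxmm) {
          return(list(pos = as.integer(d1), strand = if (or == "F") "+" else "-",
                      mapq = 60L, cigar = cand$cigar))
        }
      }
    }

    # single-diagonal rescue: a small indel near one read end leaves only one
    # anchored diagonal; scan deltas up to 15 bp on both interpretations of
    # the anchor (prefix or suffix diagonal) before giving up and clipping
    dtab <- table(diag_of)
    d <- as.integer(names(dtab)[which.max(dtab)])
    ungapped_mm <- {
      if (d >= 1L && d + n - 1L <= L) {
        sum(a_int != utf8ToInt(substr(genome, d, d + n - 1L)))
      } else Inf
    }
    best_res <- NULL
    for (delta in as.vector(rbind(-(1:15), 1:15))) {
      for (d1 in unique(c(d, d - delta))) {
        if (d1 < 1L || d1 + n + max(delta, 0L) - 1L > L) next
        cand <- place_indel(a_int, genome, as.integer(d1), n, as.integer(delta))
        if (!is.null(cand) && cand$mm <= max(2L, maxmm %/% 2L) &&
            cand$mm + 2L < ungapped_mm &&
            (is.null(best_res) || cand$mm < best_res$mm)) {
          best_res <- c(cand, list(pos = as.integer(d1)))
        }
      }
      if (!is.null(best_res) && best_res$mm <= 2L) break
    }
    if (!is.null(best_res)) {
      return(list(pos = best_res$pos, strand = if (or == "F") "+" else "-",
                  mapq = 60L, cigar = best_res$cigar))
    }

    # clip attempt around the anchor whose diagonal is most supported
    anchor_off <- as.integer(ans[[which(diag_of == d)[1]]]["off"])
    cl <- clip_extend(a_int, genome, d, n, L, anchor_off, k)
    if (!is.null(cl)) {
      cl$strand <- if (or == "F") "+" else "-"
      cl$mapq <- 60L
      if (is.null(best) || cl$mapped_len > best$mapped_len) best <- cl
    }
  }
  if (!is.null(best)) {
    best[c("pos", "strand", "mapq", "cigar")]
  } else NULL
}

# Place a single indel of signed length delta (+=deletion, -=insertion) on
# diagonal d1; split point chosen to minimise mismatches, ties to the left.
place_indel <- function(a_int, genome, d1, n, delta) {
  if (delta > 0L) {           # deletion of delta reference bases
    b_int <- utf8ToInt(substr(genome, d1, d1 + n + delta - 1L))
    pre <- cumsum(a_int != b_int[seq_len(n)])
    suf_v <- a_int != b_int[(delta + 1L):(delta + n)]
    suf <- rev(cumsum(rev(suf_v)))          # suf[m+1] = mismatches of read (m+1..n)
    m_range <- 1L:(n - 1L)
    tot <- pre[m_range] + c(suf[-1], 0)[m_range]
    m <- m_range[which.min(tot)]
    list(mm = tot[which.min(tot)],
         cigar = paste0(m, "M", delta, "D", n - m, "M"))
  } else {                    # insertion of -delta read bases
    ins <- -delta
    if (n - ins < 2L) return(NULL)
    b_int <- utf8ToInt(substr(genome, d1, d1 + n - ins - 1L))
    nb <- n - ins
    pre <- cumsum(a_int[seq_len(nb)] != b_int)
    suf_v <- a_int[(ins + 1L):n] != b_int
    suf <- rev(cumsum(rev(suf_v)))
    m_range <- 1L:(nb - 1L)
    tot <- pre[m_range] + c(suf[-1], 0)[m_range]
    m <- m_range[which.min(tot)]
    list(mm = tot[which.min(tot)],
         cigar = paste0(m, "M", ins, "I", n - m - ins, "M"))
  }
}

# Extend an anchored read along diagonal d, soft-clipping garbage tails
# (structural junctions, reference edges). Returns NULL if fewer than 30
# aligned bases survive.
clip_extend <- function(a_int, genome, d, n, L, anchor_off, k) {
  lo <- max(1L, 1L - (d - 1L))            # first read offset on the reference
  hi <- min(n, L - d + 1L)
  if (hi - lo + 1L < 30L) return(NULL)
  b_int <- utf8ToInt(substr(genome, d + lo - 1L, d + hi - 1L))
  mmv <- a_int[lo:hi] != b_int
  a0 <- anchor_off - lo + 1L              # anchor start in mmv coordinates
  a1 <- min(a0 + k - 1L, length(mmv))
  if (a0 < 1L) { a0 <- 1L }
  # walk outwards from the anchor; stop when 4 of the last 8 bases mismatch
  run_ok <- function(ix) {
    bad <- 0L
    lim <- integer(0)
    window <- integer(0)
    for (j in ix) {
      window <- c(window, mmv[j])
      if (length(window) > 8L) window <- window[-1]
      if (sum(window) >= 4L) return(j)
      lim <- j
    }
    NA_integer_
  }
  stop_r <- run_ok(if (a1 < length(mmv)) (a1 + 1L):length(mmv) else integer(0))
  stop_l <- run_ok(if (a0 > 1L) (a0 - 1L):1L else integer(0))
  e <- if (is.na(stop_r)) length(mmv) else stop_r - 8L
  s <- if (is.na(stop_l)) 1L else stop_l + 8L
  s <- max(1L, min(s, a0)); e <- min(length(mmv), max(e, a1))
  # require a clean 10-base run at each mapped end (isolated chance matches
  # inside junction sequence must not be kept), then extend to the maximal
  # exact match so the clip boundary sits at the last agreeing base
  while (s < e && mmv[s]) s <- s + 1L
  while (e > s && mmv[e]) e <- e - 1L
  while (s <= e - 10L && any(mmv[s:(s + 9L)])) s <- s + 1L
  while (e >= s + 10L && any(mmv[(e - 9L):e])) e <- e - 1L
  while (s < e && mmv[s]) s <- s + 1L
  while (e > s && mmv[e]) e <- e - 1L
  while (s > 1L && !mmv[s - 1L]) s <- s - 1L
  while (e < length(mmv) && !mmv[e + 1L]) e <- e + 1L
  mlen <- e - s + 1L
  if (mlen < 30L) return(NULL)
  if (sum(mmv[s:e]) > max(2L, floor(0.1 * mlen))) return(NULL)
  rs_off <- lo + s - 1L                   # read offset where the match starts
  re_off <- lo + e - 1L
  cig <- paste0(if (rs_off > 1L) paste0(rs_off - 1L, "S") else "",
                mlen, "M",
                if (re_off < n) paste0(n - re_off, "S") else "")
  list(pos = d + rs_off - 1L, cigar = cig, mapped_len = mlen)
}
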