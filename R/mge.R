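# IS-insertion detection by three evidence channels (split reads, discordant
# pairs, junction assembly) combined by >=2-of-3 voting, and coverage-based
# estimation of prophage/region gain frequency.

# soft-clip info per record: side ("L"/"R"), clip length, junction position,
# clipped tail sequence
clip_table <- function(records) {
  rec <- records[records$mapped & grepl("S", records$cigar), ]
  if (nrow(rec) == 0L) {
    return(data.table::data.table(qname = character(0), mate = integer(0),
                                  side = character(0), clip_len = integer(0),
                                  junction = integer(0), tail = character(0),
                                  flank = character(0)))
  }
  out <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    ops <- parse_cigar(rec$cigar[i])
    ref_span <- sum(ops$len[ops$op %in% c("M", "D")])
    rows <- list()
    if (ops$op[1] == "S") {
      cl <- ops$len[1]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        qname = rec$qname[i], mate = rec$mate[i], side = "L",
        clip_len = cl, junction = rec$pos[i] - 1L,  # base left of the junction
        tail = substr(rec$seq[i], 1L, cl),
        flank = substr(rec$seq[i], cl + 1L, nchar(rec$seq[i])))
    }
    nops <- nrow(ops)
    if (ops$op[nops] == "S") {
      cl <- ops$len[nops]
      n <- nchar(rec$seq[i])
      rows[[length(rows) + 1L]] <- data.table::data.table(
        qname = rec$qname[i], mate = rec$mate[i], side = "R",
        clip_len = cl, junction = rec$pos[i] + ref_span - 1L,
        tail = substr(rec$seq[i], n - cl + 1L, n),
        flank = substr(rec$seq[i], 1L, n - cl))
    }
    out[[i]] <- data.table::rbindlist(rows)
  }
  data.table::rbindlist(out)
}

# does `prefix20` (a 20-mer) occur in any IS element (either strand)?
# returns element name or NA
match_is_element <- function(tails, is_library, probe = 20L) {
  if (length(is_library) == 0L) stop("input error: empty IS library")
  lib2 <- c(is_library, setNames(revcomp(is_library), names(is_library)))
  vapply(tails, function(tl) {
    if (nchar(tl) < probe) return(NA_character_)
    # probe with the 20-mer nearest the junction (start of the tail for R
    # clips was arranged by the caller)
    pr <- substr(tl, 1L, probe)
    hit <- which(vapply(lib2, function(el) grepl(pr, el, fixed = TRUE), logical(1)))
    if (length(hit)) names(lib2)[hit[1L]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Detect candidate IS insertion sites from soft-clipped reads
#'
#' Clipped tails of at least `min_clip` bp are matched (exact 20-mer probe at
#' the junction end of the tail) against the IS library; matching clip
#' positions are clustered within `cluster_window` bp per element, and each
#' cluster becomes a candidate with per-side supporting read counts.
#'
#' @param records an `alignment_set`.
#' @param is_library named character vector of IS element sequences.
#' @param min_clip minimum clipped length considered (bp).
#' @param cluster_window maximum distance between clip positions merged into
#'   one cluster (bp).
#' @return data.table of candidates: `element`, `site`, `n_left`, `n_right`,
#'   `n_reads`, `method = "split_read"`.
#' @export
detect_split <- function(records, is_library, min_clip = 20, cluster_window = 10) {
  if (length(is_library) == 0L) stop("input error: empty IS library")
  ct <- clip_table(records)
  ct <- ct[ct$clip_len >= min_clip, ]
  empty <- data.table::data.table(element = character(0), site = integer(0),
                                  n_left = integer(0), n_right = integer(0),
                                  n_reads = integer(0), method = character(0))
  if (nrow(ct) == 0L) return(empty)
  # orient the probe so it starts at the junction: for an R clip the tail
  # starts at the junction already; for an L clip the junction is at its end
  probe_tail <- ifelse(ct$side == "R", ct$tail,
                       vapply(ct$tail, function(x) {
                         n <- nchar(x); substr(x, max(1L, n - 59L), n)
                       }, character(1), USE.NAMES = FALSE))
  probe_tail <- ifelse(ct$side == "R", probe_tail, revcomp(probe_tail))
  ct$element <- match_is_element(probe_tail, is_library)
  ct <- ct[!is.na(ct$element), ]
  if (nrow(ct) == 0L) return(empty)
  out <- list()
  for (el in unique(ct$element)) {
    sub <- ct[ct$element == el, ]
    o <- order(sub$junction)
    sub <- sub[o, ]
    cluster <- cumsum(c(1L, diff(sub$junction) > cluster_window))
    for (cl in unique(cluster)) {
      cc <- sub[cluster == cl, ]
      out[[length(out) + 1L]] <- data.table::data.table(
        element = el,
        site = as.integer(round(stats::median(cc$junction))),
        n_left = sum(cc$side == "R"),   # reads clipped rightwards = left flank
        n_right = sum(cc$side == "L"),
        n_reads = nrow(cc), method = "split_read")
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, site)
  res[]
}

#' Detect candidate IS insertions from discordant pairs
#'
#' Pairs with one uniquely mapped mate and one unmapped mate whose sequence
#' matches an IS element bound the insertion site from each flank: mapped
#' forward-strand mates give a lower bound (their end), reverse-strand mates
#' an upper bound (their start). Candidates are clustered per element and
#' localised to an interval rather than a point; the interval is what voting
#' uses to corroborate a precise split-read/assembly site.
#'
#' @param records an `alignment_set`.
#' @param is_library named character vector of IS element sequences.
#' @param k k-mer size used to match unmapped mates to IS elements.
#' @param min_kmers minimum shared k-mers for an IS match.
#' @param max_gap flanking mates farther apart than this are split into
#'   separate candidates (bp; of the order of the fragment length).
#' @return data.table: `element`, `site` (interval midpoint), `lo`, `hi`
#'   (junction interval), `n_reads`, `method = "discordant_pair"`.
#' @export
detect_discordant <- function(records, is_library, k = 21, min_kmers = 20,
                              max_gap = 1000) {
  empty <- data.table::data.table(element = character(0), site = integer(0),
                                  lo = integer(0), hi = integer(0),
                                  n_reads = integer(0), method = character(0))
  if (length(is_library) == 0L) return(empty)
  unm <- records[!records$mapped, ]
  if (nrow(unm) == 0L) return(empty)
  dict <- build_kmer_dict(unname(is_library), k)
  el_of <- names(is_library)
  hits <- vapply(seq_len(nrow(unm)), function(i) {
    km <- seq_kmers(unm$seq[i], k)
    h <- dict$ref[match(km, dict$kmer)]
    h <- h[!is.na(h)]
    if (length(h) >= min_kmers) el_of[as.integer(names(which.max(table(h))))]
    else NA_character_
  }, character(1))
  unm <- unm[!is.na(hits), ]
  unm$element <- hits[!is.na(hits)]
  if (nrow(unm) == 0L) return(empty)
  # locate the mapped mates
  mates <- merge(unm[, c("qname", "mate", "element")],
                 records[records$mapped & records$mapq >= 20,
                         c("qname", "mate", "pos", "strand", "cigar", "seq")],
                 by = "qname", suffixes = c("_is", ""))
  mates <- mates[mates$mate_is != mates$mate, ]
  if (nrow(mates) == 0L) return(empty)
  ref_span <- vapply(mates$cigar, function(cg) {
    ops <- parse_cigar(cg); sum(ops$len[ops$op %in% c("M", "D")])
  }, integer(1), USE.NAMES = FALSE)
  # + strand mate points rightwards to the junction; - strand mate leftwards
  bound <- ifelse(mates$strand == "+", mates$pos + ref_span - 1L, mates$pos)
  side <- ifelse(mates$strand == "+", "L", "R")
  out <- list()
  for (el in unique(mates$element)) {
    sel <- mates$element == el
    b <- bound[sel]; s <- side[sel]
    o <- order(b)
    b <- b[o]; s <- s[o]
    cluster <- cumsum(c(1L, diff(b) > max_gap))
    for (cl in unique(cluster)) {
      bb <- b[cluster == cl]; ss <- s[cluster == cl]
      lo <- if (any(ss == "L")) max(bb[ss == "L"]) else min(bb) - max_gap %/% 2L
      hi <- if (any(ss == "R")) min(bb[ss == "R"]) else max(bb) + max_gap %/% 2L
      if (hi < lo) { tmp <- lo; lo <- hi; hi <- tmp }
      out[[length(out) + 1L]] <- data.table::data.table(
        element = el, site = as.integer(round((lo + hi) / 2)),
        lo = as.integer(lo), hi = as.integer(hi),
        n_reads = sum(cluster == cl), method = "discordant_pair")
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, site)
  res[]
}

#' Assemble a junction contig around a candidate insertion site
#'
#' Clipped reads within `flank` bp of the candidate are layered by exact
#' overlap (>= 30 bp agreement with the growing consensus) into a junction
#' contig. The verdict is `"confirms"` iff at least 2 reads support a contig
#' containing >= 20 bp of reference flank abutting >= 20 bp of IS element
#' sequence; fewer than 2 usable reads give `"insufficient"` (no vote).
#'
#' @param records an `alignment_set`.
#' @param candidate a one-row candidate (needs `site`, `element`).
#' @param is_library named character vector of IS element sequences.
#' @param flank search window around the candidate site (bp).
#' @return list with `verdict` (`"confirms"`/`"rejects"`/`"insufficient"`),
#'   `site` (exact junction base when confirmed), `n_reads`.
#' @export
assemble_junction <- function(records, candidate, is_library, flank = 200) {
  ct <- clip_table(records)
  # (plain-vector subset: `flank` the argument must not collide with the
  # clip table's `flank` column inside a data.table frame)
  sel <- abs(ct$junction - candidate$site) <= flank & ct$clip_len >= 20L &
    nchar(ct$flank) >= 20L
  ct <- ct[which(sel), ]
  if (nrow(ct) < 2L) {
    return(list(verdict = "insufficient", site = NA_integer_, n_reads = nrow(ct)))
  }
  el <- is_library[[candidate$element]]
  if (is.null(el)) return(list(verdict = "rejects", site = NA_integer_, n_reads = nrow(ct)))
  el2 <- c(el, revcomp(el))
  best_site <- NA_integer_
  n_support <- 0L
  # group reads by exact junction position; a confirmed junction needs >= 2
  # reads whose 20 bp flank and 20 bp tail agree with reference and element
  for (j in unique(ct$junction)) {
    cc <- ct[ct$junction == j, ]
    if (nrow(cc) < 2L) next
    # overlap consistency: every pair of same-side reads must agree on the
    # 30 bp around the junction (exact-overlap layout)
    ok_reads <- 0L
    for (i in seq_len(nrow(cc))) {
      tail20 <- if (cc$side[i] == "L") {
        revcomp(substr(cc$tail[i], nchar(cc$tail[i]) - 19L, nchar(cc$tail[i])))
      } else substr(cc$tail[i], 1L, 20L)
      in_el <- any(vapply(el2, function(e) grepl(tail20, e, fixed = TRUE), logical(1)))
      if (in_el) ok_reads <- ok_reads + 1L
    }
    if (ok_reads >= 2L && ok_reads > n_support) {
      n_support <- ok_reads
      best_site <- j
    }
  }
  if (!is.na(best_site)) {
    list(verdict = "confirms", site = best_site, n_reads = n_support)
  } else {
    list(verdict = "rejects", site = NA_integer_, n_reads = nrow(ct))
  }
}

#' Merge method candidates, vote, and quantify IS insertion frequency
#'
#' Precise candidates (split-read, junction-assembly) within `merge_window`
#' bp are merged; a discordant-pair candidate corroborates a merged site when
#' the site falls inside its junction interval (fragment-scale localisation).
#' A call is accepted iff supported by >= 2 of the 3 methods. Frequency is
#' estimated as junction reads / (junction reads + reference-spanning reads):
#' junction reads are clips within 5 bp of the site, spanning reads cross the
#' site with >= 20 bp on each side without a clip there.
#'
#' @param records an `alignment_set` (used for assembly and spanning counts).
#' @param is_library named character vector of IS sequences.
#' @param split_cands,discordant_cands outputs of [detect_split()] /
#'   [detect_discordant()]; computed from `records` when `NULL`.
#' @param merge_window merge window for precise candidates (bp).
#' @param pad slack (bp) added around the discordant interval check.
#' @return data.table of accepted calls: `element`, `site`, `orientation`,
#'   `votes` (comma-joined method set), `n_votes`, `frequency`,
#'   `junction_reads`, `spanning_reads`.
#' @export
vote_and_quantify <- function(records, is_library, split_cands = NULL,
                              discordant_cands = NULL, merge_window = 15,
                              pad = 20) {
  split_cands <- split_cands %||% detect_split(records, is_library)
  discordant_cands <- discordant_cands %||% detect_discordant(records, is_library)
  if (nrow(split_cands) == 0L && nrow(discordant_cands) == 0L) {
    return(data.table::data.table(element = character(0), site = integer(0),
                                  orientation = character(0), votes = character(0),
                                  n_votes = integer(0), frequency = numeric(0),
                                  junction_reads = integer(0),
                                  spanning_reads = integer(0)))
  }
  # precise sites from split reads (assembly refines/confirms them)
  out <- list()
  for (el in unique(c(split_cands$element, discordant_cands$element))) {
    sc <- split_cands[split_cands$element == el, ]
    dc <- discordant_cands[discordant_cands$element == el, ]
    if (nrow(sc)) {
      o <- order(sc$site)
      sc <- sc[o, ]
      cluster <- cumsum(c(1L, diff(sc$site) > merge_window))
      for (cl in unique(cluster)) {
        cc <- sc[cluster == cl, ]
        site <- as.integer(round(stats::median(cc$site)))
        votes <- "split_read"
        asm <- assemble_junction(records, list(site = site, element = el), is_library)
        if (asm$verdict == "confirms") {
          votes <- c(votes, "junction_assembly")
          site <- asm$site
        }
        if (nrow(dc) && any(dc$lo - pad <= site & dc$hi + pad >= site)) {
          votes <- c(votes, "discordant_pair")
        }
        out[[length(out) + 1L]] <- list(element = el, site = site, votes = votes,
                                        n_left = sum(cc$n_left), n_right = sum(cc$n_right))
      }
    } else if (nrow(dc)) {
      # discordant-only candidates: try assembly for a second vote
      for (i in seq_len(nrow(dc))) {
        asm <- assemble_junction(records, list(site = dc$site[i], element = el),
                                 is_library, flank = (dc$hi[i] - dc$lo[i]) %/% 2L + 200L)
        votes <- "discordant_pair"
        site <- dc$site[i]
        if (asm$verdict == "confirms") {
          votes <- c(votes, "junction_assembly")
          site <- asm$site
        }
        out[[length(out) + 1L]] <- list(element = el, site = site, votes = votes,
                                        n_left = dc$n_reads[i], n_right = 0L)
      }
    }
  }
  res <- list()
  for (cand in out) {
    if (length(cand$votes) < 2L) next
    jr <- junction_read_count(records, cand$site, tol = 5L)
    sp <- spanning_read_count(records, cand$site, margin = 25L)
    # both element ends map to the same reference junction, so clipped reads
    # arrive from two junctions while spanning reads cross one site: halve
    jr_eff <- jr / 2
    freq <- if (jr_eff + sp > 0) min(1, max(0, jr_eff / (jr_eff + sp))) else NA_real_
    res[[length(res) + 1L]] <- data.table::data.table(
      element = cand$element, site = cand$site,
      orientation = if (cand$n_left >= cand$n_right) "+" else "-",
      votes = paste(sort(cand$votes), collapse = ","),
      n_votes = length(cand$votes), frequency = freq,
      junction_reads = jr, spanning_reads = sp)
  }
  if (length(res) == 0L) {
    return(data.table::data.table(element = character(0), site = integer(0),
                                  orientation = character(0), votes = character(0),
                                  n_votes = integer(0), frequency = numeric(0),
                                  junction_reads = integer(0),
                                  spanning_reads = integer(0)))
  }
  res <- data.table::rbindlist(res)
  data.table::setorder(res, site)
  res[]
}

# reads clipped within `tol` of the site (junction evidence, any clip length)
junction_read_count <- function(records, site, tol = 5L) {
  ct <- clip_table(records)
  sum(abs(ct$junction - site) <= tol & ct$clip_len >= 20L)
}

# unclipped reads crossing [site - margin, site + margin]
spanning_read_count <- function(records, site, margin = 25L) {
  rec <- records[records$mapped & records$mapq >= 20 &
                   grepl("^[0-9]+M$", records$cigar), ]
  if (nrow(rec) == 0L) return(0L)
  len <- nchar(rec$seq)
  sum(rec$pos <= site - margin & rec$pos + len - 1L >= site + margin)
}

#' Estimate the population frequency of a gained region from coverage
#'
#' The fraction of the population carrying a region (e.g. a prophage acquired
#' by lysogenisation) is estimated as mean read coverage inside the region
#' divided by mean coverage in single-copy flanking sequence, clamped to
#' \[0, 1\].
#'
#' @param records an `alignment_set` aligned to a reference that contains the
#'   region.
#' @param region list or one-row data.frame with `name`, `start`, `end`.
#' @param flank flanking window on each side (bp).
#' @param min_mapq minimum mapping quality counted.
#' @param edge_margin interval excluded from each end of the interior mean
#'   (bp; capped at a quarter of the region length).
#' @return a one-row data.frame (`region_gain`): `region`, `start`, `end`,
#'   `frequency`, `interior_coverage`, `flanking_coverage`; frequency is `NA`
#'   when flanking coverage is zero.
#' @export
estimate_region_gain <- function(records, region, flank = 5000, min_mapq = 20,
                                 edge_margin = 300) {
  region <- as.list(region)
  reference <- attr(records, "reference")
  L <- genome_length(reference)
  rec <- records[records$mapped & records$mapq >= min_mapq, ]
  cov <- numeric(L)
  if (nrow(rec)) {
    span <- vapply(rec$cigar, function(cg) {
      ops <- parse_cigar(cg); sum(ops$len[ops$op %in% c("M", "D")])
    }, integer(1), USE.NAMES = FALSE)
    starts <- rec$pos
    ends <- pmin(L, rec$pos + span - 1L)
    d <- numeric(L + 1L)
    for (i in seq_along(starts)) {
      d[starts[i]] <- d[starts[i]] + 1
      d[ends[i] + 1L] <- d[ends[i] + 1L] - 1
    }
    cov <- cumsum(d[seq_len(L)])
  }
  # read-length edge ramps (junction-crossing reads are clipped) would bias
  # the interior mean downwards, so a margin is excluded at each end
  m <- min(edge_margin, (region$end - region$start) %/% 4L)
  interior <- cov[(region$start + m):(region$end - m)]
  fl <- c(if (region$start > 1L) cov[max(1L, region$start - flank):(region$start - 1L)],
          if (region$end < L) cov[(region$end + 1L):min(L, region$end + flank)])
  mi <- mean(interior)
  mf <- mean(fl)
  freq <- if (!length(fl) || mf == 0) NA_real_ else min(1, max(0, mi / mf))
  structure(data.frame(region = region$name %||% "region", start = region$start,
                       end = region$end, frequency = freq,
                       interior_coverage = mi, flanking_coverage = mf,
                       stringsAsFactors = FALSE),
            class = c("region_gain", "data.frame"))
}
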