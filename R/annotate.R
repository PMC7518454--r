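# Gene-context annotation of consensus variants, IS calls and region gains,
# producing mutation records in the standard report layout
# (position, mutation, gene, annotation, frequency).

ARROW_R <- "\u2192"  # right arrow
ARROW_L <- "\u2190"  # left arrow
DELTA <- "\u0394"    # capital delta

gene_at <- function(genome, pos) {
  g <- genome$genes
  hit <- which(g$start <= pos & g$end >= pos)
  if (length(hit)) g[hit[1L], ] else NULL
}

# "ymgF>/ymgD<"-style intergenic context: flanking genes in genomic order
intergenic_context <- function(genome, pos) {
  g <- genome$genes[order(genome$genes$start), ]
  arrow <- function(strand) if (strand == "+") ARROW_R else ARROW_L
  left <- g[g$end < pos, ]
  right <- g[g$start > pos, ]
  ln <- if (nrow(left)) paste0(left$name[nrow(left)], arrow(left$strand[nrow(left)])) else "-"
  rn <- if (nrow(right)) paste0(right$name[1L], arrow(right$strand[1L])) else "-"
  paste0(ln, "/", rn)
}

aa_of <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

# codon containing `pos` of a gene; returns list(codon, offset_in_codon 1..3)
# in the gene's reading direction
codon_at <- function(genome, gene, pos) {
  seq <- genome$sequence
  if (gene$strand == "+") {
    off <- pos - gene$start
    ci <- off %/% 3L
    cs <- gene$start + 3L * ci
    list(codon = substr(seq, cs, cs + 2L), within = off %% 3L + 1L)
  } else {
    off <- gene$end - pos
    ci <- off %/% 3L
    ce <- gene$end - 3L * ci
    list(codon = revcomp(substr(seq, ce - 2L, ce)), within = off %% 3L + 1L)
  }
}

snp_effect <- function(genome, gene, pos, alt) {
  cd <- codon_at(genome, gene, pos)
  alt_cd <- cd$codon
  alt_base <- if (gene$strand == "+") alt else revcomp(alt)
  substr(alt_cd, cd$within, cd$within) <- alt_base
  aa1 <- aa_of(cd$codon); aa2 <- aa_of(alt_cd)
  if (aa1 == aa2) "Synonymous" else paste(aa1, ARROW_R, aa2)
}

#' Annotate a variant against the genome annotation
#'
#' Translates a consensus variant, IS call or region gain into a mutation
#' record row: position inside a gene gives a codon-level effect (synonymous,
#' amino-acid change written `X (arrow) Y` with `*` for stop, frameshift for
#' indels whose length is not a multiple of 3, codon insertion/deletion for
#' in-frame indels, partial gene deletion for large or boundary-crossing
#' deletions, gene interrupted for IS insertions); a position between genes
#' is intergenic, reported with its flanking genes and strands in genomic
#' order. Pure function of (variant, annotation).
#'
#' @param variant a one-row consensus variant (`pos`, `type`, `ref`, `alt`,
#'   `mean_frequency`), an `is_call` row (`element`, `pos`, `frequency`), a
#'   region-gain row (`region`, `frequency`), or an inversion
#'   (`type = "inversion"`, `pos`, `end`).
#' @param genome an `annotated_genome`.
#' @return one-row data.frame: `position`, `mutation`, `gene`, `annotation`,
#'   `frequency`.
#' @export
annotate_variant <- function(variant, genome) {
  v <- as.list(variant)
  L <- genome_length(genome)
  freq <- v$frequency %||% v$mean_frequency %||% NA_real_

  if (!is.null(v$region)) {                      # prophage / region gain
    return(data.frame(position = v$pos %||% NA_integer_, mutation = v$region,
                      gene = "", annotation = "Prophage", frequency = freq,
                      stringsAsFactors = FALSE))
  }
  if (!is.null(v$element) && (is.null(v$type) || identical(v$type, "is_insertion"))) {
    pos <- v$pos
    if (pos < 1L || pos > L) stop("coordinate error: variant outside genome")
    gene <- gene_at(genome, pos)
    return(data.frame(position = pos, mutation = v$element,
                      gene = if (is.null(gene)) intergenic_context(genome, pos) else gene$name,
                      annotation = if (is.null(gene)) "Intergenic" else "Gene interrupted",
                      frequency = freq, stringsAsFactors = FALSE))
  }

  pos <- v$pos
  if (is.null(pos) || pos < 1L || pos > L) stop("coordinate error: variant outside genome")
  type <- v$type

  if (identical(type, "inversion")) {
    len <- v$end - pos + 1L
    genes <- genome$genes
    inside <- any(intervals_overlap(pos, v$end, genes$start, genes$end))
    return(data.frame(position = pos,
                      mutation = paste("Inversion", len, "bp"),
                      gene = if (inside) "" else intergenic_context(genome, pos),
                      annotation = if (inside) "Gene interrupted" else "Intergenic",
                      frequency = freq, stringsAsFactors = FALSE))
  }

  gene <- gene_at(genome, pos)
  if (identical(type, "snp")) {
    mutation <- paste(v$ref, ARROW_R, v$alt)
    if (is.null(gene)) {
      return(data.frame(position = pos, mutation = mutation,
                        gene = intergenic_context(genome, pos),
                        annotation = "Intergenic", frequency = freq,
                        stringsAsFactors = FALSE))
    }
    eff <- snp_effect(genome, gene, pos, v$alt)
    return(data.frame(position = pos, mutation = mutation, gene = gene$name,
                      annotation = eff, frequency = freq, stringsAsFactors = FALSE))
  }
  if (identical(type, "insertion")) {
    seqn <- sub("^\\+", "", v$alt)
    len <- nchar(seqn)
    mutation <- paste0("+", len, " ", seqn)
    if (is.null(gene)) {
      return(data.frame(position = pos, mutation = mutation,
                        gene = intergenic_context(genome, pos),
                        annotation = "Intergenic", frequency = freq,
                        stringsAsFactors = FALSE))
    }
    ann <- if (len %% 3L == 0L) "Codon insertion" else "Frameshift"
    return(data.frame(position = pos, mutation = mutation, gene = gene$name,
                      annotation = ann, frequency = freq, stringsAsFactors = FALSE))
  }
  if (identical(type, "deletion")) {
    len <- if (!is.null(v$alt) && grepl("^-", v$alt)) as.integer(sub("^-", "", v$alt))
           else (v$end - pos + 1L)
    dend <- pos + len - 1L
    mutation <- paste(DELTA, len, "bp")
    if (is.null(gene)) {
      genes <- genome$genes
      hit <- which(intervals_overlap(pos, dend, genes$start, genes$end))
      if (length(hit)) {
        return(data.frame(position = pos, mutation = mutation,
                          gene = genes$name[hit[1L]],
                          annotation = "Partial gene deletion", frequency = freq,
                          stringsAsFactors = FALSE))
      }
      return(data.frame(position = pos, mutation = mutation,
                        gene = intergenic_context(genome, pos),
                        annotation = "Intergenic", frequency = freq,
                        stringsAsFactors = FALSE))
    }
    ann <- if (dend > gene$end || len > 30L) "Partial gene deletion"
           else if (len %% 3L == 0L) "Codons deleted"
           else "Frameshift"
    return(data.frame(position = pos, mutation = mutation, gene = gene$name,
                      annotation = ann, frequency = freq, stringsAsFactors = FALSE))
  }
  stop(sprintf("unknown variant type '%s'", type %||% "NULL"))
}

#' Annotate a table of consensus variants
#'
#' @param consensus output of [merge_runs()].
#' @param genome an `annotated_genome`.
#' @return data.frame of mutation records (one per variant), frequencies
#'   rounded to 2 decimals for table output.
#' @export
annotate_variants <- function(consensus, genome) {
  if (nrow(consensus) == 0L) {
    return(data.frame(position = integer(0), mutation = character(0),
                      gene = character(0), annotation = character(0),
                      frequency = numeric(0)))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(consensus)), function(i) {
    annotate_variant(consensus[i, ], genome)
  }))
  out$frequency <- round(out$frequency, 2)
  out
}

#' Write consensus variants as a minimal VCF
#'
#' Records carry `AF` (mean frequency), `NRUNS` (supporting runs) and the
#' per-run frequencies in INFO. Indel records follow VCF's anchored-allele
#' convention (the base left of the event is prepended), converting from the
#' internal 1-based closed representation at this boundary.
#'
#' @param consensus output of [merge_runs()].
#' @param genome an `annotated_genome`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(consensus, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", genome$name, genome_length(genome)),
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Mean frequency across runs\">",
           "##INFO=<ID=NRUNS,Number=1,Type=Integer,Description=\"Supporting runs\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(0)
  if (nrow(consensus)) {
    seqs <- genome$sequence
    lines <- vapply(seq_len(nrow(consensus)), function(i) {
      v <- consensus[i, ]
      if (v$type == "snp") {
        posv <- v$pos; refv <- v$ref; altv <- v$alt
      } else if (v$type == "insertion") {
        posv <- v$pos; refv <- substr(seqs, v$pos, v$pos)
        altv <- paste0(refv, sub("^\\+", "", v$alt))
      } else {
        len <- as.integer(sub("^-", "", v$alt))
        posv <- v$pos - 1L
        refv <- substr(seqs, v$pos - 1L, v$pos + len - 1L)
        altv <- substr(seqs, v$pos - 1L, v$pos - 1L)
      }
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.4f;NRUNS=%d",
              genome$name, posv, refv, altv, v$mean_frequency, v$n_supporting_runs)
    }, character(1))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
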