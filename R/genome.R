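#' Construct an annotated reference genome
#'
#' The central coordinate frame for the whole pipeline: a single chromosome
#' sequence plus gene, repeat and prophage annotation, a library of known IS
#' elements, and optional plasmid sequences. All coordinates are 1-based,
#' closed intervals.
#'
#' @param name genome identifier.
#' @param sequence chromosome sequence (single string, A/C/G/T).
#' @param genes data.frame with columns `name`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`); may have zero rows.
#' @param repeats data.frame with columns `start`, `end` (repetitive intervals).
#' @param is_library named character vector of IS-element sequences.
#' @param prophages data.frame with columns `name`, `start`, `end`:
#'   prophage intervals on this chromosome.
#' @param plasmids named character vector of plasmid sequences.
#' @return an object of class `annotated_genome`.
#' @export
annotated_genome <- function(name, sequence, genes = NULL, repeats = NULL,
                             is_library = character(0), prophages = NULL,
                             plasmids = character(0)) {
  empty_feat <- function(cols) {
    setNames(as.data.frame(rep(list(integer(0)), length(cols))), cols)
  }
  genes <- genes %||% empty_feat(c("name", "start", "end", "strand"))
  repeats <- repeats %||% empty_feat(c("start", "end"))
  prophages <- prophages %||% empty_feat(c("name", "start", "end"))
  g <- structure(list(
    name = name,
    sequence = toupper(sequence),
    genes = as.data.frame(genes),
    repeats = as.data.frame(repeats),
    is_library = is_library,
    prophages = as.data.frame(prophages),
    plasmids = plasmids
  ), class = "annotated_genome")
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  L <- nchar(g$sequence)
  chk <- function(df, what) {
    if (nrow(df) == 0L) return(invisible())
    if (any(df$start < 1L | df$end > L | df$start > df$end)) {
      stop(sprintf("%s intervals out of bounds for genome of length %d", what, L))
    }
  }
  chk(g$genes, "gene")
  chk(g$repeats, "repeat")
  chk(g$prophages, "prophage")
  if (anyDuplicated(g$genes$name)) stop("duplicate gene names")
  if (anyDuplicated(names(g$is_library))) stop("duplicate IS element names")
  if (anyDuplicated(g$prophages$name)) stop("duplicate prophage names")
  invisible(g)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %d genes, %d repeat intervals,\n",
              x$name, format(nchar(x$sequence), big.mark = ","),
              nrow(x$genes), nrow(x$repeats)))
  cat(sprintf("  %d IS elements in library, %d prophages, %d plasmids\n",
              length(x$is_library), nrow(x$prophages), length(x$plasmids)))
  invisible(x)
}

#' Length of the chromosome sequence
#' @param g an `annotated_genome`.
#' @return integer length in bp.
#' @export
genome_length <- function(g) nchar(g$sequence)

#' Generate a random annotated genome
#'
#' Lays out non-overlapping genes (lengths multiples of 3) separated by
#' intergenic gaps, one pair of identical repeat copies (a collapsed-repeat
#' trap for the masking stage), a set of prophage intervals, an IS-element
#' library and optional plasmids. Deterministic for a fixed seed.
#'
#' Gaps are sized so that the realised genic fraction tracks `gene_fraction`;
#' generation fails with a sizing error when the requested fraction cannot be
#' packed together with the reserved repeat/prophage zones.
#'
#' @param length chromosome length in bp (>= 10000).
#' @param gene_fraction target fraction of the chromosome covered by genes,
#'   in (0, 1).
#' @param n_is_elements number of IS elements in the library.
#' @param n_prophages number of prophage intervals to annotate.
#' @param seed integer RNG seed.
#' @param n_plasmids number of plasmid sequences.
#' @param is_length approximate IS element length (bp).
#' @param prophage_length prophage interval length (bp).
#' @param plasmid_length plasmid length (bp).
#' @return an [annotated_genome()].
#' @examples
#' g <- generate_genome(20000, 0.6, n_is_elements = 2, n_prophages = 1, seed = 1)
#' g
#' @export
generate_genome <- function(length, gene_fraction, n_is_elements = 3,
                            n_prophages = 2, seed = 1, n_plasmids = 0,
                            is_length = 1200, prophage_length = 3000,
                            plasmid_length = 4000) {
  stopifnot(length >= 10000, gene_fraction > 0, gene_fraction < 1)
  with_seed(seed, {
    rep_len <- 400L
    # Reserved non-genic zones: repeat copy A near the start, copy B near the
    # end, prophages spread over the interior.
    rep_a <- c(101L, 100L + rep_len)
    rep_b <- c(length - 499L - rep_len + 1L, length - 499L)
    gene_lo <- rep_a[2] + 101L
    gene_hi <- rep_b[1] - 101L
    span <- gene_hi - gene_lo + 1L
    if (n_prophages > 0 && n_prophages * (prophage_length + 400L) > span %/% 2L) {
      stop("sizing error: prophage intervals do not fit in the requested length")
    }
    prophages <- NULL
    if (n_prophages > 0) {
      slot <- span %/% (n_prophages + 1L)
      starts <- gene_lo + slot * seq_len(n_prophages) - prophage_length %/% 2L
      prophages <- data.frame(
        name = c("Nef", "KingRac", paste0("phage", seq_len(max(0, n_prophages - 2))))[seq_len(n_prophages)],
        start = as.integer(starts),
        end = as.integer(starts + prophage_length - 1L)
      )
    }
    reserved_bp <- 2L * rep_len + n_prophages * prophage_length
    target_gene_bp <- round(gene_fraction * length)
    available <- length - reserved_bp - 1200L
    # Genes cannot be packed tighter than ~60 bp minimum gaps allow.
    if (target_gene_bp > 0.92 * available) {
      stop("sizing error: gene_fraction too high for this length with the requested features")
    }
    slack <- available / target_gene_bp - 1  # mean gap per gene bp

    genes <- list()
    cursor <- gene_lo
    gene_bp <- 0L
    i <- 0L
    while (gene_bp < target_gene_bp && cursor < gene_hi - 400L) {
      glen <- 3L * sample(100:500, 1)
      # skip over prophage zones (keep genes out of mobile intervals so that
      # prophage loss/gain edits never collide with genic variants)
      if (!is.null(prophages)) {
        hit <- which(intervals_overlap(cursor, cursor + glen - 1L,
                                       prophages$start - 100L, prophages$end + 100L))
        if (base::length(hit) > 0) {
          cursor <- max(prophages$end[hit]) + 101L
          next
        }
      }
      if (cursor + glen - 1L > gene_hi) break
      i <- i + 1L
      genes[[i]] <- data.frame(name = sprintf("gene%03d", i),
                               start = cursor, end = cursor + glen - 1L,
                               strand = sample(c("+", "-"), 1))
      gene_bp <- gene_bp + glen
      gap <- max(60L, as.integer(round(glen * slack + stats::rnorm(1, 0, 20))))
      cursor <- cursor + glen + gap
    }
    genes <- do.call(rbind, genes)
    if (is.null(genes) || gene_bp < target_gene_bp - 0.1 * length) {
      stop("sizing error: could not reach the requested gene_fraction")
    }

    sequence <- random_dna(length)
    # identical repeat copies
    copy <- substr(sequence, rep_a[1], rep_a[2])
    substr(sequence, rep_b[1], rep_b[2]) <- copy
    repeats <- data.frame(start = c(rep_a[1], rep_b[1]), end = c(rep_a[2], rep_b[2]))

    is_names <- c("IS1", "IS2", "IS3", "IS5", "IS10", "IS150",
                  paste0("ISX", seq_len(max(0, n_is_elements - 6))))[seq_len(n_is_elements)]
    is_library <- setNames(
      vapply(seq_len(n_is_elements),
             function(i) random_dna(is_length + sample(-100:100, 1)), character(1)),
      is_names)
    if (n_is_elements == 0) is_library <- character(0)

    plasmids <- character(0)
    if (n_plasmids > 0) {
      plasmids <- setNames(
        vapply(seq_len(n_plasmids), function(i) random_dna(plasmid_length), character(1)),
        paste0("plasmid", seq_len(n_plasmids)))
    }

    annotated_genome(name = sprintf("synthetic_%d", seed), sequence = sequence,
                     genes = genes, repeats = repeats, is_library = is_library,
                     prophages = prophages, plasmids = plasmids)
  })
}

#' Intergenic gaps between consecutive genes
#'
#' @param g an `annotated_genome`.
#' @param min_width smallest gap width (bp) to report.
#' @return data.frame of 1-based closed `start`/`end` intervals with the
#'   flanking gene names (`left`, `right`); useful for placing intergenic
#'   variants.
#' @export
intergenic_gaps <- function(g, min_width = 1L) {
  genes <- g$genes[order(g$genes$start), ]
  if (nrow(genes) < 2L) return(data.frame(start = integer(0), end = integer(0)))
  s <- genes$end[-nrow(genes)] + 1L
  e <- genes$start[-1L] - 1L
  keep <- e - s + 1L >= min_width
  data.frame(start = s[keep], end = e[keep],
             left = genes$name[-nrow(genes)][keep], right = genes$name[-1L][keep])
}

#' Write a genome to FASTA and GFF3 files
#'
#' Writes `<prefix>.fasta` (chromosome plus plasmid sequences),
#' `<prefix>.gff3` (genes, repeats and prophages; converted to the GFF3
#' 1-based convention, which matches the internal one) and
#' `<prefix>.is_library.fasta`.
#'
#' @param g an `annotated_genome`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_genome <- function(g, prefix) {
  seqs <- Biostrings::DNAStringSet(c(setNames(g$sequence, g$name), g$plasmids))
  fa <- paste0(prefix, ".fasta")
  Biostrings::writeXStringSet(seqs, fa)
  feats <- rbind(
    if (nrow(g$genes)) data.frame(type = "gene", start = g$genes$start, end = g$genes$end,
                                  strand = g$genes$strand, name = g$genes$name),
    if (nrow(g$repeats)) data.frame(type = "repeat_region", start = g$repeats$start,
                                    end = g$repeats$end, strand = "+",
                                    name = paste0("repeat", seq_len(nrow(g$repeats)))),
    if (nrow(g$prophages)) data.frame(type = "prophage", start = g$prophages$start,
                                      end = g$prophages$end, strand = "+",
                                      name = g$prophages$name))
  gff <- paste0(prefix, ".gff3")
  if (!is.null(feats) && nrow(feats)) {
    gr <- GenomicRanges::GRanges(
      seqnames = g$name,
      ranges = IRanges::IRanges(start = feats$start, end = feats$end),
      strand = feats$strand, type = feats$type, ID = feats$name, Name = feats$name)
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff)
  }
  isfa <- paste0(prefix, ".is_library.fasta")
  if (length(g$is_library)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$is_library), isfa)
  }
  invisible(c(fa, gff, isfa))
}

#' Read a genome from FASTA and GFF3 files
#'
#' Counterpart of [write_genome()]. The first FASTA record is taken as the
#' chromosome; further records are plasmids.
#'
#' @param prefix path prefix used by [write_genome()].
#' @return an `annotated_genome`.
#' @export
read_genome <- function(prefix) {
  seqs <- Biostrings::readDNAStringSet(paste0(prefix, ".fasta"))
  gff_path <- paste0(prefix, ".gff3")
  genes <- repeats <- prophages <- NULL
  if (file.exists(gff_path)) {
    gr <- tryCatch(rtracklayer::import(gff_path, format = "gff3"), error = function(e) NULL)
    if (!is.null(gr) && length(gr)) {
      df <- as.data.frame(gr)
      ty <- as.character(df$type)
      if (any(ty == "gene")) {
        gdf <- df[ty == "gene", ]
        genes <- data.frame(name = as.character(gdf$Name), start = gdf$start,
                            end = gdf$end, strand = as.character(gdf$strand))
      }
      if (any(ty == "repeat_region")) {
        rdf <- df[ty == "repeat_region", ]
        repeats <- data.frame(start = rdf$start, end = rdf$end)
      }
      if (any(ty == "prophage")) {
        pdf <- df[ty == "prophage", ]
        prophages <- data.frame(name = as.character(pdf$Name), start = pdf$start, end = pdf$end)
      }
    }
  }
  is_path <- paste0(prefix, ".is_library.fasta")
  is_library <- character(0)
  if (file.exists(is_path)) {
    isl <- Biostrings::readDNAStringSet(is_path)
    is_library <- setNames(as.character(isl), names(isl))
  }
  plasmids <- character(0)
  if (length(seqs) > 1L) {
    plasmids <- setNames(as.character(seqs[-1L]), names(seqs)[-1L])
  }
  annotated_genome(name = names(seqs)[1L], sequence = as.character(seqs[[1L]]),
                   genes = genes, repeats = repeats, is_library = is_library,
                   prophages = prophages, plasmids = plasmids)
}
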