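# Cohort-level simulation: translate a report-layout mutation table into
# planted-variant specifications on a synthetic genome, simulate per-mouse
# read sets, and emit truth tables in the same column layout.

parse_mutation_string <- function(mutation, annotation) {
  if (annotation == "Prophage") return(list(kind = "prophage_gain", element = mutation))
  if (grepl("^IS", mutation)) return(list(kind = "is_insertion", element = mutation))
  if (grepl("^Inversion", mutation)) {
    len <- as.integer(sub("^Inversion ([0-9]+) bp$", "\\1", mutation))
    return(list(kind = "inversion", len = len))
  }
  if (grepl("^\\+", mutation)) {
    seqn <- sub("^\\+[0-9]+ ?", "", mutation)
    return(list(kind = "insertion", seq = gsub(" ", "", seqn)))
  }
  if (grepl("^\u0394", mutation)) {
    len <- as.integer(sub("^\u0394 ([0-9]+) bp$", "\\1", mutation))
    return(list(kind = "deletion", len = len))
  }
  if (grepl("\u2192", mutation)) {
    parts <- strsplit(mutation, " \u2192 ")[[1]]
    return(list(kind = "snp", ref = parts[1], alt = parts[2]))
  }
  stop(sprintf("cannot parse mutation descriptor '%s'", mutation))
}

# find a genic SNP site with the requested effect class
find_genic_snp <- function(genome, synonymous, forbidden, margin = 300L) {
  genes <- genome$genes
  for (try in seq_len(2000L)) {
    gi <- sample.int(nrow(genes), 1L)
    gene <- genes[gi, ]
    pos <- sample(gene$start:gene$end, 1L)
    if (pos_in_intervals(pos, forbidden)) next
    ref <- substring(genome$sequence, pos, pos)
    for (alt in sample(setdiff(BASES, ref))) {
      eff <- snp_effect(genome, gene, pos, alt)
      if (synonymous == (eff == "Synonymous")) {
        return(list(pos = pos, ref = ref, alt = alt))
      }
    }
  }
  stop("could not place a genic SNP with the requested effect")
}

find_intergenic_site <- function(genome, width, forbidden, margin = 25L) {
  gaps <- intergenic_gaps(genome, min_width = width + 2L * margin)
  if (nrow(gaps) == 0L) stop("no intergenic gap wide enough")
  for (try in seq_len(2000L)) {
    gi <- sample.int(nrow(gaps), 1L)
    s <- gaps$start[gi] + margin
    e <- gaps$end[gi] - margin - width + 1L
    if (e < s) next
    pos <- sample(s:e, 1L)
    if (!any(pos_in_intervals(c(pos, pos + width - 1L), forbidden))) return(pos)
  }
  stop("could not place an intergenic site")
}

find_genic_interval <- function(genome, width, forbidden, inside_only = TRUE) {
  genes <- genome$genes
  ok <- genes$end - genes$start + 1L >= width + 20L
  if (!any(ok)) stop("no gene long enough")
  for (try in seq_len(2000L)) {
    gene <- genes[sample(which(ok), 1L), ]
    s <- gene$start + 10L
    e <- gene$end - 10L - width + 1L
    if (e < s) next
    pos <- sample(s:e, 1L)
    if (!any(pos_in_intervals(c(pos, pos + width - 1L), forbidden))) return(pos)
  }
  stop("could not place a genic interval")
}

#' Map a report-layout mutation table onto a synthetic genome
#'
#' Each distinct site of the table (same position and mutation descriptor
#' shared across mice) is assigned a position on the synthetic genome whose
#' context reproduces the table's annotation class: intergenic records go to
#' intergenic gaps, synonymous/amino-acid-changing SNPs to genic sites with
#' that effect (the actual ref/alt bases follow the synthetic sequence),
#' indels and IS insertions to genic or intergenic sites as annotated, and
#' prophage rows to the genome's annotated prophage intervals. Combined
#' multi-phage rows and rows without a numeric frequency are skipped.
#'
#' @param table data.frame in report layout (`mouse`, `cohort`, `position`,
#'   `mutation`, `gene`, `annotation`, `frequency`).
#' @param genome an [annotated_genome()] with enough genes/gaps/prophages.
#' @param seed integer RNG seed for site placement.
#' @return a cohort spec: data.frame with `mouse`, `cohort`, `kind`,
#'   `position`, `ref`, `alt`, `element`, `end`, `frequency` and
#'   `table_position` (the original coordinate).
#' @export
plan_cohort_variants <- function(table, genome, seed = 1) {
  with_seed(seed, {
    keep <- !is.na(table$frequency) & !grepl("\\+.*Prophage|Prophage.*\\+", paste(table$mutation, table$annotation)) &
      !(table$annotation == "Prophage" & grepl("\\+", table$mutation))
    table <- table[keep, ]
    key <- paste(table$position, table$mutation)
    sites <- new.env(parent = emptyenv())
    forbidden <- data.frame(start = integer(0), end = integer(0))
    reserve <- function(s, e, pad = 150L) {
      forbidden <<- rbind(forbidden, data.frame(start = s - pad, end = e + pad))
    }
    # keep planted sites away from annotated repeats and prophages
    if (nrow(genome$repeats)) for (i in seq_len(nrow(genome$repeats)))
      reserve(genome$repeats$start[i], genome$repeats$end[i], 50L)
    if (nrow(genome$prophages)) for (i in seq_len(nrow(genome$prophages)))
      reserve(genome$prophages$start[i], genome$prophages$end[i], 50L)

    rows <- vector("list", nrow(table))
    for (i in seq_len(nrow(table))) {
      k <- key[i]
      if (!is.null(sites[[k]])) {
        site <- sites[[k]]
      } else {
        pm <- parse_mutation_string(table$mutation[i], table$annotation[i])
        ann <- table$annotation[i]
        site <- switch(pm$kind,
          snp = {
            if (ann == "Intergenic") {
              pos <- find_intergenic_site(genome, 1L, forbidden)
              ref <- substring(genome$sequence, pos, pos)
              list(kind = "snp", pos = pos, ref = ref,
                   alt = sample(setdiff(BASES, ref), 1L), end = NA_integer_,
                   element = NA_character_)
            } else {
              gs <- find_genic_snp(genome, synonymous = (ann == "Synonymous"), forbidden)
              list(kind = "snp", pos = gs$pos, ref = gs$ref, alt = gs$alt,
                   end = NA_integer_, element = NA_character_)
            }
          },
          insertion = {
            pos <- if (ann == "Intergenic") find_intergenic_site(genome, 1L, forbidden)
                   else find_genic_interval(genome, 1L, forbidden)
            list(kind = "insertion", pos = pos, ref = NA_character_, alt = pm$seq,
                 end = NA_integer_, element = NA_character_)
          },
          deletion = {
            pos <- if (ann == "Intergenic") find_intergenic_site(genome, pm$len, forbidden)
                   else find_genic_interval(genome, pm$len, forbidden)
            list(kind = "deletion", pos = pos, ref = NA_character_,
                 alt = NA_character_, end = pos + pm$len - 1L,
                 element = NA_character_)
          },
          is_insertion = {
            if (!pm$element %in% names(genome$is_library)) {
              stop(sprintf("IS element '%s' missing from the genome library", pm$element))
            }
            pos <- if (ann == "Intergenic") find_intergenic_site(genome, 1L, forbidden)
                   else find_genic_interval(genome, 1L, forbidden)
            list(kind = "is_insertion", pos = pos, ref = NA_character_,
                 alt = NA_character_, end = NA_integer_, element = pm$element)
          },
          inversion = {
            pos <- find_intergenic_site(genome, pm$len, forbidden)
            list(kind = "inversion", pos = pos, ref = NA_character_,
                 alt = NA_character_, end = pos + pm$len - 1L,
                 element = NA_character_)
          },
          prophage_gain = {
            ph <- genome$prophages[genome$prophages$name == pm$element, ]
            if (nrow(ph) == 0L) stop(sprintf("prophage '%s' not annotated", pm$element))
            list(kind = "prophage_gain", pos = ph$start, ref = NA_character_,
                 alt = NA_character_, end = ph$end, element = pm$element)
          })
        fp <- c(site$pos, if (is.na(site$end)) site$pos else site$end)
        if (site$kind != "prophage_gain") reserve(fp[1], fp[2])
        sites[[k]] <- site
      }
      rows[[i]] <- data.frame(
        mouse = table$mouse[i], cohort = table$cohort[i], kind = site$kind,
        position = site$pos, ref = site$ref, alt = site$alt,
        element = site$element, end = site$end, frequency = table$frequency[i],
        table_position = table$position[i], stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Draw a random cohort specification from category rates
#'
#' Per-mouse mutation counts are Poisson-distributed with the given per-mouse
#' rates; sites are placed like [plan_cohort_variants()] and frequencies are
#' drawn uniformly on \[0.05, 0.95\] (rounded to 0.01).
#'
#' @param genome an `annotated_genome`.
#' @param mice character vector of mouse ids.
#' @param cohort cohort label for all mice.
#' @param rates named list of per-mouse Poisson rates with any of
#'   `is`, `snp_genic`, `snp_intergenic`, `insertion`, `deletion`.
#' @param seed integer RNG seed.
#' @return a cohort spec data.frame (see [plan_cohort_variants()]).
#' @export
sample_cohort_spec <- function(genome, mice, cohort, rates, seed = 1) {
  with_seed(seed, {
    rows <- list()
    forbidden <- data.frame(start = integer(0), end = integer(0))
    for (m in mice) {
      for (kind in names(rates)) {
        nk <- stats::rpois(1, rates[[kind]])
        for (j in seq_len(nk)) {
          freq <- round(stats::runif(1, 0.05, 0.95), 2)
          row <- switch(kind,
            is = {
              el <- sample(names(genome$is_library), 1L)
              pos <- find_intergenic_site(genome, 1L, forbidden)
              data.frame(mouse = m, cohort = cohort, kind = "is_insertion",
                         position = pos, ref = NA, alt = NA, element = el,
                         end = NA_integer_, frequency = freq,
                         table_position = pos)
            },
            snp_genic = {
              gs <- find_genic_snp(genome, synonymous = FALSE, forbidden)
              data.frame(mouse = m, cohort = cohort, kind = "snp",
                         position = gs$pos, ref = gs$ref, alt = gs$alt,
                         element = NA, end = NA_integer_, frequency = freq,
                         table_position = gs$pos)
            },
            snp_intergenic = {
              pos <- find_intergenic_site(genome, 1L, forbidden)
              ref <- substring(genome$sequence, pos, pos)
              data.frame(mouse = m, cohort = cohort, kind = "snp",
                         position = pos, ref = ref,
                         alt = sample(setdiff(BASES, ref), 1L),
                         element = NA, end = NA_integer_, frequency = freq,
                         table_position = pos)
            },
            insertion = {
              pos <- find_intergenic_site(genome, 1L, forbidden)
              data.frame(mouse = m, cohort = cohort, kind = "insertion",
                         position = pos, ref = NA,
                         alt = random_dna(sample(1:6, 1L)),
                         element = NA, end = NA_integer_, frequency = freq,
                         table_position = pos)
            },
            deletion = {
              len <- sample(1:12, 1L)
              pos <- find_intergenic_site(genome, len, forbidden)
              data.frame(mouse = m, cohort = cohort, kind = "deletion",
                         position = pos, ref = NA, alt = NA, element = NA,
                         end = pos + len - 1L, frequency = freq,
                         table_position = pos)
            })
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(mouse = character(0), cohort = character(0),
                        kind = character(0), position = integer(0),
                        ref = character(0), alt = character(0),
                        element = character(0), end = integer(0),
                        frequency = numeric(0), table_position = integer(0)))
    }
    do.call(rbind, rows)
  })
}

# truth record (report layout) for one planted variant, annotated against the
# genome
truth_record <- function(spec_row, realized, genome) {
  v <- switch(spec_row$kind,
    snp = list(type = "snp", pos = spec_row$position, ref = spec_row$ref,
               alt = spec_row$alt),
    insertion = list(type = "insertion", pos = spec_row$position,
                     alt = paste0("+", spec_row$alt)),
    deletion = list(type = "deletion", pos = spec_row$position,
                    alt = paste0("-", spec_row$end - spec_row$position + 1L)),
    is_insertion = list(element = spec_row$element, pos = spec_row$position),
    inversion = list(type = "inversion", pos = spec_row$position,
                     end = spec_row$end),
    prophage_gain = list(region = spec_row$element, pos = spec_row$position))
  rec <- annotate_variant(v, genome)
  data.frame(mouse = spec_row$mouse, cohort = spec_row$cohort,
             position = rec$position, mutation = rec$mutation, gene = rec$gene,
             annotation = rec$annotation, frequency = realized,
             stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(mouse = character(0), cohort = character(0), position = integer(0),
             mutation = character(0), gene = character(0),
             annotation = character(0), frequency = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate per-mouse read sets for a whole cohort
#'
#' For each mouse in the spec, plants its variants into a haplotype
#' population, simulates a paired-end read set, and collects a cohort truth
#' table in the report layout (the same columns as the packaged mutation
#' tables). Optionally writes per-mouse FASTQ pairs and the truth TSV to a
#' directory.
#'
#' @param cohort_spec output of [plan_cohort_variants()] or
#'   [sample_cohort_spec()]; its `mouse` column defines the cohort (a mouse
#'   with zero variant rows still gets a read set if listed in `mice`).
#' @param genome an `annotated_genome`.
#' @param coverage per-mouse fold coverage.
#' @param mice mice to simulate (default: those in the spec).
#' @param seed integer RNG seed (per-mouse seeds are derived from it).
#' @param out_dir optional output directory for FASTQ/truth files.
#' @param n_haplotypes population size per mouse.
#' @param ... passed to [simulate_reads()].
#' @return list with `reads` (named list of `read_set`), `truth` (report
#'   layout data.frame; zero rows with a valid header when the spec is
#'   empty).
#' @export
simulate_cohort <- function(cohort_spec, genome, coverage = 50, mice = NULL,
                            seed = 1, out_dir = NULL, n_haplotypes = 100, ...) {
  mice <- mice %||% unique(cohort_spec$mouse)
  if (length(mice) < 1L) stop("cohort spec names no mice")
  reads <- list()
  truth <- list()
  for (mi in seq_along(mice)) {
    m <- mice[mi]
    sub <- cohort_spec[cohort_spec$mouse == m, , drop = FALSE]
    vars <- sub[, c("kind", "position", "ref", "alt", "element", "end", "frequency")]
    popn <- plant_variants(genome, vars, n_haplotypes = n_haplotypes,
                           seed = seed * 1000L + mi)
    rs <- simulate_reads(popn, coverage = coverage, seed = seed * 1000L + 500L + mi, ...)
    reads[[m]] <- rs
    if (nrow(sub)) {
      truth[[m]] <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
        truth_record(sub[i, ], popn$truth$realized_frequency[i], genome)
      }))
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE)) else empty_truth()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in names(reads)) write_fastq_pair(reads[[m]], file.path(out_dir, m))
    utils::write.table(truth_df, file.path(out_dir, "cohort_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  list(reads = reads, truth = truth_df)
}
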