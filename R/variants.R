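#' Describe a variant to plant in a synthetic population
#'
#' Builds one row of a planted-variant specification, the emulated analogue of
#' one row of a mutation table (position, mutation, population frequency).
#'
#' @param kind one of `"snp"`, `"insertion"`, `"deletion"`, `"is_insertion"`,
#'   `"inversion"`, `"prophage_gain"`.
#' @param position 1-based reference position (left junction for insertions
#'   and IS insertions; interval start for deletions, inversions and prophage
#'   gains).
#' @param frequency target population frequency in \[0, 1\].
#' @param ref reference allele (snp).
#' @param alt alternate allele (snp) or inserted sequence (insertion).
#' @param element IS-element or prophage name (is_insertion, prophage_gain).
#' @param end interval end (deletion, inversion, prophage_gain); defaults to
#'   `position` for 1 bp deletions.
#' @return a one-row data.frame.
#' @export
variant_spec <- function(kind, position, frequency, ref = NA_character_,
                         alt = NA_character_, element = NA_character_,
                         end = NA_integer_) {
  kind <- match.arg(kind, c("snp", "insertion", "deletion", "is_insertion",
                            "inversion", "prophage_gain"))
  stopifnot(frequency >= 0, frequency <= 1)
  if (kind == "snp" && !is.na(ref) && !is.na(alt) && ref == alt) {
    stop("snp alt allele must differ from ref allele")
  }
  data.frame(kind = kind, position = as.integer(position),
             ref = ref, alt = alt, element = element,
             end = as.integer(end), frequency = frequency,
             stringsAsFactors = FALSE)
}

# Reference footprint of a variant (interval whose bases are touched on a
# carrier haplotype; for prophage gains, on a non-carrier).
variant_footprint <- function(v) {
  end <- switch(v$kind,
    snp = v$position,
    insertion = v$position,
    is_insertion = v$position,
    deletion = if (is.na(v$end)) v$position else v$end,
    inversion = v$end,
    prophage_gain = v$end)
  c(v$position, end)
}

#' Plant variants into a haplotype population
#'
#' Builds `n_haplotypes` full-length haplotype sequences from the reference
#' chromosome, each variant carried by a random subset of haplotypes whose
#' size is `round(frequency * n_haplotypes)`, so realised frequencies are
#' exact multiples of `1/n_haplotypes`. Prophage gains are modelled as
#' presence/absence of the annotated prophage interval: carriers keep it,
#' non-carriers have it deleted (lysogenised vs. phage-free sub-population,
#' with reference coordinates following the lysogen).
#'
#' @param genome an [annotated_genome()].
#' @param variants data.frame of [variant_spec()] rows.
#' @param n_haplotypes population size (default 100).
#' @param seed integer RNG seed.
#' @return an object of class `hap_population`: list with `haplotypes`
#'   (character vector), `weights`, `truth` (data.frame with realised
#'   frequencies and carrier sets) and `genome`.
#' @export
plant_variants <- function(genome, variants, n_haplotypes = 100, seed = 1) {
  L <- genome_length(genome)
  if (nrow(variants)) {
    fp <- t(vapply(seq_len(nrow(variants)),
                   function(i) variant_footprint(variants[i, ]), numeric(2)))
    if (any(variants$position < 1L | fp[, 2] > L)) {
      stop("variant positions outside the genome")
    }
  }
  with_seed(seed, {
    n <- n_haplotypes
    carriers <- vector("list", nrow(variants))
    realized <- numeric(nrow(variants))
    for (i in seq_len(nrow(variants))) {
      k <- round(variants$frequency[i] * n)
      carriers[[i]] <- sort(sample.int(n, k))
      realized[i] <- k / n
    }

    # conflict check: no two variants may touch the same base on one haplotype
    if (nrow(variants) > 1L) {
      for (i in seq_len(nrow(variants) - 1L)) {
        for (j in (i + 1L):nrow(variants)) {
          hap_i <- if (variants$kind[i] == "prophage_gain") setdiff(seq_len(n), carriers[[i]]) else carriers[[i]]
          hap_j <- if (variants$kind[j] == "prophage_gain") setdiff(seq_len(n), carriers[[j]]) else carriers[[j]]
          if (length(intersect(hap_i, hap_j)) == 0L) next
          fi <- variant_footprint(variants[i, ])
          fj <- variant_footprint(variants[j, ])
          if (intervals_overlap(fi[1], fi[2], fj[1], fj[2])) {
            stop(sprintf("conflict error: variants %d and %d overlap base(s) on a shared haplotype", i, j))
          }
        }
      }
    }

    haplotypes <- rep(genome$sequence, n)
    if (nrow(variants)) {
      # apply right-to-left so earlier coordinates stay valid
      ord <- order(variants$position, decreasing = TRUE)
      for (i in ord) {
        v <- variants[i, ]
        targets <- if (v$kind == "prophage_gain") setdiff(seq_len(n), carriers[[i]]) else carriers[[i]]
        if (length(targets) == 0L) next
        haplotypes[targets] <- apply_edit(haplotypes[targets], v, genome)
      }
    }
    truth <- cbind(variants,
                   data.frame(realized_frequency = realized))
    truth$carriers <- I(carriers)
    structure(list(haplotypes = haplotypes, weights = rep(1 / n, n),
                   truth = truth, genome = genome),
              class = "hap_population")
  })
}

# Apply one edit to a set of haplotype strings (all sharing reference
# coordinates at and beyond the edit position).
apply_edit <- function(haps, v, genome) {
  p <- v$position
  switch(v$kind,
    snp = {
      if (!is.na(v$ref) && substr(genome$sequence, p, p) != v$ref) {
        stop(sprintf("snp ref allele mismatch at %d (genome has %s)", p,
                     substr(genome$sequence, p, p)))
      }
      alt <- v$alt
      if (is.na(alt)) stop("snp needs an alt allele")
      `substr<-`(haps, p, p, value = strrep(alt, 1L))
    },
    insertion = {
      paste0(substr(haps, 1L, p), v$alt, substr(haps, p + 1L, nchar(haps)))
    },
    deletion = {
      e <- if (is.na(v$end)) p else v$end
      paste0(substr(haps, 1L, p - 1L), substr(haps, e + 1L, nchar(haps)))
    },
    is_insertion = {
      el <- genome$is_library[[v$element]]
      if (is.null(el)) stop(sprintf("IS element '%s' not in library", v$element))
      paste0(substr(haps, 1L, p), el, substr(haps, p + 1L, nchar(haps)))
    },
    inversion = {
      inv <- revcomp(substr(haps[1L], p, v$end))
      `substr<-`(haps, p, v$end, value = inv)
    },
    prophage_gain = {
      # applied to NON-carriers: remove the prophage interval
      paste0(substr(haps, 1L, p - 1L), substr(haps, v$end + 1L, nchar(haps)))
    })
}

#' @export
print.hap_population <- function(x, ...) {
  cat(sprintf("<hap_population> %d haplotypes of ~%s bp, %d planted variants\n",
              length(x$haplotypes), format(nchar(x$haplotypes[1]), big.mark = ","),
              nrow(x$truth)))
  invisible(x)
}
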