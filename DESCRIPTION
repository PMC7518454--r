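Package: gutevol
Title: Within-Host Evolution Analysis of Invading Gut Bacteria from Pooled Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect and summarise within-host evolution of an invading
    bacterial strain from pooled population sequencing of faecal samples.
    Provides a synthetic-cohort simulator (annotated genomes, haplotype
    populations with planted SNPs, indels, IS-element insertions, inversions
    and prophage gains, and paired-end reads with truth tables), sliding-window
    quality trimming and multi-reference read partitioning, a deterministic
    seed-and-extend aligner with SAM import/export, per-position pileups, two
    polymorphism callers with strand-bias and repeat/breakpoint filters merged
    under a multi-run consensus rule, evidence-voting detection of insertion
    sequence (IS) transpositions, coverage-based prophage-gain frequency
    estimation, and mutation-spectrum cohort statistics (per-mouse category
    counts, mean and standard error, tie-corrected Mann-Whitney U tests,
    coding/synonymous ratios and neutral-marker frequency series).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Rsamtools,
    data.table,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
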