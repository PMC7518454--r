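# Mutation-spectrum classification and cohort statistics: per-mouse category
# counts, mean +/- SEM, tie-corrected Mann-Whitney U, coding/synonymous
# ratios, site-frequency summaries and neutral-marker frequency series.

CATEGORIES <- c("IS", "intergenic", "synonymous", "coding", "indel",
                "structural", "prophage")

#' Read a mutation table (report-layout TSV)
#'
#' Columns: `mouse`, `cohort`, `position`, `mutation`, `gene`, `annotation`,
#' `frequency`. The packaged example tables of an old-mouse and a young-mouse
#' cohort are available via
#' `system.file("extdata", "table1_old.tsv", package = "gutevol")` and
#' `"table2_young.tsv"`.
#'
#' @param path TSV file path.
#' @return data.frame of mutation records.
#' @export
read_mutation_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    colClasses = c(frequency = "numeric"))
}

#' Classify a mutation record into spectrum categories
#'
#' Categories overlap by design: an IS insertion in an intergenic region is
#' both `IS` and `intergenic`; a gene-interrupting IS is `IS` and `coding`; a
#' genic frameshift is `coding` and `indel`. Rules:
#' * `IS`: any IS-element insertion, wherever it lands.
#' * `intergenic`: any record in an intergenic context (including IS
#'   insertions, indels and inversions there).
#' * `synonymous`: a synonymous SNP inside a gene.
#' * `coding`: any in-gene record that is not synonymous (amino-acid change,
#'   frameshift, in-frame codon insertion/deletion, partial gene deletion,
#'   gene-interrupting insertion).
#' * `indel`: any insertion or deletion of bases, excluding IS insertions and
#'   inversions.
#' * `structural`: inversions.
#' * `prophage`: prophage gains; these carry no other label and are excluded
#'   from total mutation counts.
#'
#' @param records data.frame of mutation records (`mutation`, `annotation`
#'   columns).
#' @return logical matrix, one row per record, one column per category.
#' @export
classify_mutations <- function(records) {
  mut <- as.character(records$mutation)
  ann <- as.character(records$annotation)
  if (any(is.na(mut) | is.na(ann))) stop("classification error: unannotated record")
  prophage <- ann == "Prophage"
  is_el <- grepl("^IS", mut) & !prophage
  intergenic <- ann == "Intergenic" & !prophage
  synonymous <- ann == "Synonymous" & !prophage
  structural <- grepl("^Inversion", mut) & !prophage
  indel <- grepl("^[+\u0394]", mut) & !prophage
  genic <- !prophage & !intergenic
  coding <- genic & !synonymous & !structural
  out <- cbind(IS = is_el, intergenic = intergenic, synonymous = synonymous,
               coding = coding, indel = indel, structural = structural,
               prophage = prophage)
  rownames(out) <- NULL
  out
}

#' Per-mouse mutation counts by category
#'
#' @param records data.frame of mutation records with `mouse` (and optionally
#'   `cohort`) columns.
#' @param cohort restrict to one cohort label (`"old"`/`"young"`); `NULL`
#'   keeps all records.
#' @param mice optional character vector of mice that must appear (zero rows
#'   for mice without records).
#' @return data.frame: one row per mouse (ordered by id), columns `mouse`,
#'   `total` (non-prophage records) and the seven categories.
#' @export
cohort_counts <- function(records, cohort = NULL, mice = NULL) {
  if (!is.null(cohort)) {
    if (!cohort %in% records$cohort) stop(sprintf("input error: unknown cohort '%s'", cohort))
    records <- records[records$cohort == cohort, ]
  }
  cls <- classify_mutations(records)
  mice <- mice %||% sort(unique(records$mouse))
  out <- data.frame(mouse = mice, total = 0L, stringsAsFactors = FALSE)
  for (cat in CATEGORIES) out[[cat]] <- 0L
  for (i in seq_along(mice)) {
    sel <- records$mouse == mice[i]
    out$total[i] <- sum(sel & !cls[, "prophage"])
    for (cat in CATEGORIES) out[[cat]][i] <- sum(cls[sel, cat])
  }
  out
}

#' Mean and standard error of the mean
#'
#' SEM uses the sample standard deviation (n - 1 denominator) divided by
#' sqrt(n).
#'
#' @param values numeric vector (n >= 2).
#' @return named numeric vector `c(mean, sem)`.
#' @export
mean_sem <- function(values) {
  n <- length(values)
  if (n < 2L) stop("SEM undefined error: need at least 2 values")
  c(mean = mean(values), sem = stats::sd(values) / sqrt(n))
}

#' Two-sided Mann-Whitney U test (midranks, tie-corrected normal p)
#'
#' Ranks use midranks for ties; U1 = R1 - n1(n1+1)/2 and the reported U is
#' min(U1, U2). The two-sided p-value uses the normal approximation with tie
#' correction and a continuity correction of 1/2.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return a `group_comparison` list: `mean_a`, `sem_a`, `mean_b`, `sem_b`,
#'   `U`, `U1`, `U2`, `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("input error: empty group")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))            # midranks
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  p <- if (sigma2 <= 0) 1 else {
    z <- (U - n1 * n2 / 2 + 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(z))
  }
  structure(list(
    mean_a = mean(a), sem_a = if (n1 > 1) stats::sd(a) / sqrt(n1) else NA_real_,
    mean_b = mean(b), sem_b = if (n2 > 1) stats::sd(b) / sqrt(n2) else NA_real_,
    U = U, U1 = U1, U2 = U2, p_value = p, n_a = n1, n_b = n2),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group A: %.1f +/- %.1f (n=%d); group B: %.1f +/- %.1f (n=%d)\n",
              x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b))
  cat(sprintf("two-sided Mann-Whitney U = %.1f, p = %.2g\n", x$U, x$p_value))
  invisible(x)
}

#' Cohort-level coding/synonymous mutation ratio
#'
#' @param counts a [cohort_counts()] table.
#' @return ratio of summed coding to summed synonymous counts (2-decimal
#'   rounding is applied for report output by the caller); `NA` with a
#'   warning when the cohort has no synonymous mutations.
#' @export
coding_syn_ratio <- function(counts) {
  syn <- sum(counts$synonymous)
  if (syn == 0L) {
    warning(sprintf("undefined coding/synonymous ratio (coding=%d, synonymous=0)",
                    sum(counts$coding)))
    return(NA_real_)
  }
  sum(counts$coding) / syn
}

#' Summarise recurrence of one mutation site across a cohort
#'
#' Scans records matching a mutation descriptor and gene context and reports
#' in how many mice its frequency exceeds a threshold, and the maximum
#' frequency reached.
#'
#' @param records data.frame of mutation records.
#' @param mutation_pattern regular expression on the `mutation` column (e.g.
#'   `"^IS5$"`).
#' @param gene_pattern regular expression on the `gene` column.
#' @param threshold frequency threshold in \[0, 1\].
#' @param cohort optional cohort restriction.
#' @return list: `n_mice_above` (mice with frequency > threshold),
#'   `max_frequency` (`NA` when nothing matches), `n_records`.
#' @export
site_frequency_summary <- function(records, mutation_pattern, gene_pattern = ".",
                                   threshold = 0.05, cohort = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!is.null(cohort)) records <- records[records$cohort == cohort, ]
  sel <- grepl(mutation_pattern, records$mutation) & grepl(gene_pattern, records$gene)
  m <- records[sel, ]
  if (nrow(m) == 0L) {
    return(list(n_mice_above = 0L, max_frequency = NA_real_, n_records = 0L))
  }
  above <- tapply(m$frequency, m$mouse, function(f) any(f > threshold))
  list(n_mice_above = sum(above), max_frequency = max(m$frequency),
       n_records = nrow(m))
}

#' Neutral-marker frequency series with binomial SEM
#'
#' For each timepoint, frequency = positive/total and
#' SEM = sqrt(f (1 - f) / total); plotting attaches +/- 2 SEM error bars.
#'
#' @param counts data.frame with columns `day`, `positive`, `total`.
#' @return a `marker_series` data.frame with `frequency` and `sem` columns;
#'   timepoints with `total = 0` are flagged missing (`NA`).
#' @export
marker_series <- function(counts) {
  f <- ifelse(counts$total > 0, counts$positive / counts$total, NA_real_)
  sem <- ifelse(counts$total > 0, sqrt(f * (1 - f) / counts$total), NA_real_)
  structure(data.frame(day = counts$day, positive = counts$positive,
                       total = counts$total, frequency = f, sem = sem),
            class = c("marker_series", "data.frame"))
}

#' @export
plot.marker_series <- function(x, ..., bar_sem = 2) {
  graphics::plot(x$day, x$frequency, type = "b", pch = 19, ylim = c(0, 1),
                 xlab = "day", ylab = "marker frequency", ...)
  ok <- !is.na(x$sem)
  graphics::arrows(x$day[ok], pmax(0, x$frequency[ok] - bar_sem * x$sem[ok]),
                   x$day[ok], pmin(1, x$frequency[ok] + bar_sem * x$sem[ok]),
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Full cohort comparison of the mutation spectrum
#'
#' Computes per-mouse counts for two cohorts and, for total mutations and
#' each category, the group means, SEMs and the two-sided Mann-Whitney U
#' test, plus the cohort coding/synonymous ratios.
#'
#' @param old_records,young_records mutation-record data.frames (e.g. from
#'   [read_mutation_table()]).
#' @param categories categories to compare (default: total + the six
#'   mutation categories, prophage excluded).
#' @return a `spectrum_comparison` list: `counts_old`, `counts_young`,
#'   `comparison` (data.frame: category, means, SEMs, U, p), `ratio_old`,
#'   `ratio_young`.
#' @export
compare_spectra <- function(old_records, young_records,
                            categories = c("total", "IS", "intergenic",
                                           "synonymous", "coding", "indel")) {
  co <- cohort_counts(old_records)
  cy <- cohort_counts(young_records)
  rows <- lapply(categories, function(cat) {
    gc <- mann_whitney(co[[cat]], cy[[cat]])
    data.frame(category = cat,
               mean_old = gc$mean_a, sem_old = gc$sem_a,
               mean_young = gc$mean_b, sem_young = gc$sem_b,
               U = gc$U, p_value = gc$p_value, stringsAsFactors = FALSE)
  })
  structure(list(counts_old = co, counts_young = cy,
                 comparison = do.call(rbind, rows),
                 ratio_old = coding_syn_ratio(co),
                 ratio_young = coding_syn_ratio(cy)),
            class = "spectrum_comparison")
}

#' @export
print.spectrum_comparison <- function(x, ...) {
  cmp <- x$comparison
  cmp$mean_old <- sprintf("%.1f +/- %.1f", cmp$mean_old, cmp$sem_old)
  cmp$mean_young <- sprintf("%.1f +/- %.1f", cmp$mean_young, cmp$sem_young)
  cmp$U <- sprintf("%.1f", cmp$U)
  cmp$p_value <- sprintf("%.2g", cmp$p_value)
  print(cmp[, c("category", "mean_old", "mean_young", "U", "p_value")],
        row.names = FALSE)
  cat(sprintf("coding/synonymous ratio: %.2f (old), %.2f (young)\n",
              x$ratio_old, x$ratio_young))
  invisible(x)
}
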