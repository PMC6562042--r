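#' Positional decile distributions
#'
#' Counts and fractions of mutations across the 10 positional bins: CDS
#' deciles, internal-exon deciles, or 20-codon bins of the first 200 codons
#' (the latter restricted to CDS longer than 200 codons). Optionally
#' stratified (e.g. by substitution class or study); per-stratum fractions
#' are normalized within the stratum, and empty strata are omitted.
#'
#' @param annotated Annotated table.
#' @param by `"cds"`, `"internal_exon"` or `"first_200_codons"`.
#' @param stratify_by Optional column name to stratify by.
#' @return Tibble `stratum` (or `"all"`), `bin` (1-10), `count`, `fraction`.
#' @export
positional_distribution <- function(annotated,
                                    by = c("cds", "internal_exon",
                                           "first_200_codons"),
                                    stratify_by = NULL) {
  by <- match.arg(by)
  bin_col <- switch(by, cds = "cds_decile",
                    internal_exon = "internal_exon_decile",
                    first_200_codons = "first200_bin")
  tbl <- annotated[!is.na(annotated[[bin_col]]), ]
  tbl$stratum <- if (is.null(stratify_by)) "all" else
    as.character(tbl[[stratify_by]])
  tbl$bin <- tbl[[bin_col]]
  grid <- tidyr::expand_grid(stratum = unique(tbl$stratum), bin = 1:10)
  tbl |>
    dplyr::count(.data$stratum, .data$bin, name = "count") |>
    dplyr::right_join(grid, by = c("stratum", "bin")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$stratum, .data$bin)
}

#' Per-bin means of a metric with SEM and bin-vs-rest tests
#'
#' Mean and SEM of a numeric column within each positional decile, the
#' difference from the grand mean, and a two-sample t-test of each bin
#' against all other bins.
#'
#' @param annotated Annotated (scored) table.
#' @param metric Column name of the numeric metric.
#' @param by `"cds"` or `"internal_exon"`.
#' @return Tibble per bin: `n`, `mean`, `sem` (NA for n < 2),
#'   `diff_from_mean`, `t`, `p_value`.
#' @export
metric_by_bin <- function(annotated, metric, by = c("cds", "internal_exon")) {
  by <- match.arg(by)
  bin_col <- if (by == "cds") "cds_decile" else "internal_exon_decile"
  tbl <- annotated[!is.na(annotated[[bin_col]]) &
                     is.finite(annotated[[metric]]), ]
  x <- tbl[[metric]]
  bins <- tbl[[bin_col]]
  grand <- mean(x)
  purrr::map_dfr(1:10, function(b) {
    xin <- x[bins == b]
    xout <- x[bins != b]
    tt <- if (length(xin) >= 2 && length(xout) >= 2) {
      tryCatch(stats::t.test(xin, xout), error = function(e) NULL)
    } else NULL
    tibble::tibble(
      bin = b, n = length(xin),
      mean = if (length(xin)) mean(xin) else NA_real_,
      sem = if (length(xin) >= 2) stats::sd(xin) / sqrt(length(xin)) else NA_real_,
      diff_from_mean = if (length(xin)) mean(xin) - grand else NA_real_,
      t = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
      p_value = if (!is.null(tt)) tt$p.value else NA_real_
    )
  })
}

CODONS_PER_AA <- local({
  gc <- Biostrings::getGeneticCode("1")
  tab <- table(gc[gc != "*"])
  stats::setNames(as.integer(tab), names(tab))
})

#' Observed amino-acid distribution of mutations
#'
#' Raw per-amino-acid mutation counts divided by the number of codons per
#' amino acid under the standard genetic code, then renormalized to sum to 1.
#' Stop codons are excluded.
#'
#' @param annotated Annotated table with an `amino_acid` column (filter to
#'   the consequence class of interest first).
#' @return Tibble `amino_acid`, `count`, `normalized_share` (sums to 1).
#' @export
amino_acid_distribution <- function(annotated) {
  tbl <- annotated[!is.na(annotated$amino_acid) &
                     annotated$amino_acid != "*", ]
  out <- tibble::tibble(amino_acid = names(CODONS_PER_AA)) |>
    dplyr::left_join(dplyr::count(tbl, .data$amino_acid, name = "count"),
                     by = "amino_acid") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  per_codon = .data$count / CODONS_PER_AA[.data$amino_acid])
  out$normalized_share <- out$per_codon / sum(out$per_codon)
  dplyr::select(out, -"per_codon")
}

#' Codon usage of a transcriptome's CDS set
#'
#' @param transcripts Transcript-model tibble.
#' @return Named numeric vector of frequencies over the 61 sense codons
#'   (sums to 1).
#' @export
codon_usage <- function(transcripts) {
  counts <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  for (i in seq_len(nrow(transcripts))) {
    cds <- cds_sequence(transcripts[i, ])
    n <- nchar(cds) %/% 3L
    codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    tab <- table(codons[codons %in% SENSE_CODONS])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts / sum(counts)
}

#' Expected amino-acid distribution of synonymous mutations
#'
#' For each sense codon, enumerates its nine single-base substitutions, sums
#' the signature probabilities of those that are synonymous, multiplies by
#' the codon's usage frequency, aggregates to the amino-acid level and
#' normalizes to 1. Amino acids with no synonymous single-base route (Trp,
#' Met) get expected share 0.
#'
#' @param usage Codon usage over the 61 sense codons (see [codon_usage()]).
#' @param signature A [signature_model()].
#' @return Tibble `amino_acid`, `expected_share` (sums to 1).
#' @export
expected_aa_distribution <- function(usage, signature) {
  if (!all(SENSE_CODONS %in% names(usage))) {
    stop("usage must cover all 61 sense codons")
  }
  gc <- Biostrings::getGeneticCode("1")
  likelihood <- vapply(SENSE_CODONS, function(codon) {
    bases <- strsplit(codon, "")[[1]]
    tot <- 0
    for (i in 1:3) {
      for (alt in setdiff(DNA_BASES, bases[i])) {
        mut <- bases
        mut[i] <- alt
        mutc <- paste(mut, collapse = "")
        if (gc[[mutc]] == gc[[codon]]) {
          tot <- tot + signature[[substitution_class(bases[i], alt)]]
        }
      }
    }
    tot
  }, numeric(1))
  mass <- usage[SENSE_CODONS] * likelihood
  aa <- unname(gc[SENSE_CODONS])
  agg <- tapply(mass, aa, sum)
  out <- tibble::tibble(amino_acid = names(CODONS_PER_AA)) |>
    dplyr::mutate(expected_share = as.numeric(agg[.data$amino_acid]))
  out$expected_share[is.na(out$expected_share)] <- 0
  out$expected_share <- out$expected_share / sum(out$expected_share)
  out
}

#' Two-group comparison with scedasticity pretest
#'
#' Two-sided two-sample t-test; an F-test of variance equality at alpha =
#' 0.05 chooses the pooled (Student) vs unpooled (Welch) variant. Also
#' reports the relative difference `100 * (mean_a - mean_b) / mean_b`.
#'
#' @param values_a,values_b Numeric vectors (each n >= 2).
#' @return Tibble `t`, `p_value`, `relative_difference`, `var_equal`.
#' @export
group_compare <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values")
  }
  rel <- 100 * (mean(values_a) - mean(values_b)) / mean(values_b)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    # degenerate: no variance anywhere
    return(tibble::tibble(
      t = if (mean(values_a) == mean(values_b)) 0 else Inf,
      p_value = if (mean(values_a) == mean(values_b)) 1 else 0,
      relative_difference = rel, var_equal = TRUE
    ))
  }
  veq <- stats::var.test(values_a, values_b)$p.value >= 0.05
  tt <- stats::t.test(values_a, values_b, var.equal = veq)
  tibble::tibble(t = unname(tt$statistic), p_value = tt$p.value,
                 relative_difference = rel, var_equal = veq)
}

#' Per-study stratification of the cohort analyses
#'
#' Selects the union of the five studies with the most synonymous mutations
#' and the five studies with the most samples (all studies if fewer than 10
#' exist), and emits the positional distribution — and optionally a
#' metric-by-bin summary — per selected study.
#'
#' @param annotated Annotated table (filter to synonymous first for the
#'   mutation-count ranking to mirror the cohort analyses).
#' @param metric Optional metric column for [metric_by_bin()] per study.
#' @return List with `selected` (tibble of studies and their ranks),
#'   `distributions` (per-study positional distributions, stratum = study)
#'   and `metrics` (NULL unless `metric` given).
#' @export
per_study_stratification <- function(annotated, metric = NULL) {
  by_mut <- annotated |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(n_mutations = dplyr::n(),
                     n_samples = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop")
  top_mut <- by_mut |>
    dplyr::arrange(dplyr::desc(.data$n_mutations)) |>
    dplyr::slice_head(n = 5)
  top_smp <- by_mut |>
    dplyr::arrange(dplyr::desc(.data$n_samples)) |>
    dplyr::slice_head(n = 5)
  selected_ids <- union(top_mut$study_id, top_smp$study_id)
  all_selected <- nrow(by_mut) < 10
  if (all_selected) selected_ids <- by_mut$study_id
  sel <- annotated[annotated$study_id %in% selected_ids, ]
  dists <- positional_distribution(sel, by = "cds", stratify_by = "study_id")
  metrics <- NULL
  if (!is.null(metric)) {
    metrics <- purrr::map_dfr(selected_ids, function(s) {
      dplyr::mutate(metric_by_bin(sel[sel$study_id == s, ], metric),
                    study_id = s, .before = 1)
    })
  }
  list(
    selected = dplyr::filter(by_mut, .data$study_id %in% selected_ids),
    distributions = dists,
    metrics = metrics
  )
}
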