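#' Component table for the composite prioritization score
#'
#' Validates the nine score components. Missing bounded additive components
#' (conservation, FATHMM-MKL, CADD quantile rank, structure quantile rank)
#' impute to 0 — no evidence contributes nothing — and the imputation is
#' flagged.
#'
#' @param frequency Sample count f >= 1.
#' @param signature_p Class probability p in \[0, 1\].
#' @param avg_mutation_load Mean carrier load L >= 1.
#' @param cgc_score Cancer-gene score g (default mapping: 2 if the gene is a
#'   known cancer gene, else 0).
#' @param phastcons Conservation c in \[0, 1\].
#' @param snp_score s: 1 if NOT listed as SNP, 0 if listed.
#' @param fathmm FATHMM-MKL score m in \[0, 1\].
#' @param cadd_qrank,structure_qrank Cohort quantile ranks in \[0, 1\].
#' @return Tibble of validated components plus `imputed` flag.
#' @export
score_components <- function(frequency, signature_p, avg_mutation_load,
                             cgc_score = 0, phastcons = NA_real_,
                             snp_score = 1, fathmm = NA_real_,
                             cadd_qrank = NA_real_,
                             structure_qrank = NA_real_) {
  n <- length(frequency)
  comp <- tibble::tibble(
    frequency = as.numeric(frequency),
    signature_p = rep_len(as.numeric(signature_p), n),
    avg_mutation_load = rep_len(as.numeric(avg_mutation_load), n),
    cgc_score = rep_len(as.numeric(cgc_score), n),
    phastcons = rep_len(as.numeric(phastcons), n),
    snp_score = rep_len(as.numeric(snp_score), n),
    fathmm = rep_len(as.numeric(fathmm), n),
    cadd_qrank = rep_len(as.numeric(cadd_qrank), n),
    structure_qrank = rep_len(as.numeric(structure_qrank), n)
  )
  if (any(comp$frequency < 1, na.rm = TRUE)) stop("frequency must be >= 1")
  if (any(comp$avg_mutation_load < 1, na.rm = TRUE)) {
    stop("avg_mutation_load must be >= 1")
  }
  in01 <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!in01(comp$signature_p)) stop("signature_p must lie in [0, 1]")
  for (f in c("phastcons", "snp_score", "fathmm", "cadd_qrank",
              "structure_qrank")) {
    if (!in01(comp[[f]])) stop(f, " must lie in [0, 1]")
  }
  if (any(!comp$cgc_score %in% c(0, 2) & !is.na(comp$cgc_score))) {
    if (any(comp$cgc_score < 0 | comp$cgc_score > 2, na.rm = TRUE)) {
      stop("cgc_score must lie in [0, 2]")
    }
  }
  imputable <- c("phastcons", "fathmm", "cadd_qrank", "structure_qrank")
  comp$imputed <- rowSums(is.na(comp[imputable])) > 0
  for (f in imputable) comp[[f]][is.na(comp[[f]])] <- 0
  comp
}

ADDITIVE_TERMS <- c("cgc_score", "phastcons", "snp_score", "fathmm",
                    "cadd_qrank", "structure_qrank")

#' @rdname score_components
#' @format NULL
#' @export
SCORE_PARAMETERS <- c("frequency", "signature_normalization", "mutation_load",
                      ADDITIVE_TERMS)

#' Composite prioritization score
#'
#' `S = (log2(f) + 1) * (1 - p) - log10(L) + g + c + s + m + qC + qR`:
#' signature-corrected recurrence, penalized by the (log) average mutation
#' load of the carrier samples, plus the six bounded additive evidence terms.
#'
#' @param comp Component tibble from [score_components()].
#' @return Numeric score vector.
#' @export
synmicdb_score <- function(comp) {
  (log2(comp$frequency) + 1) * (1 - comp$signature_p) -
    log10(comp$avg_mutation_load) +
    comp$cgc_score + comp$phastcons + comp$snp_score + comp$fathmm +
    comp$cadd_qrank + comp$structure_qrank
}

#' Leave-one-out score variants
#'
#' Recomputes the score with each of the nine parameters neutralized:
#' dropping `frequency` replaces the `(log2 f + 1)` factor by 1, dropping the
#' signature normalization replaces the `(1 - p)` multiplier by 1, dropping
#' the mutation load removes the `-log10 L` term, and each additive term is
#' simply removed.
#'
#' @param comp Component tibble from [score_components()].
#' @return Tibble with one column per parameter in `SCORE_PARAMETERS`,
#'   holding the score without that parameter.
#' @export
leave_one_out <- function(comp) {
  full <- synmicdb_score(comp)
  freq_term <- (log2(comp$frequency) + 1) * (1 - comp$signature_p)
  out <- tibble::tibble(
    frequency = full - freq_term + (1 - comp$signature_p),
    signature_normalization = full - freq_term + (log2(comp$frequency) + 1),
    mutation_load = full + log10(comp$avg_mutation_load)
  )
  for (f in ADDITIVE_TERMS) out[[f]] <- full - comp[[f]]
  out
}

#' Retention of the top decile under a leave-one-out ranking
#'
#' Fraction of the mutations in the top 10% of the full score that remain in
#' the top 10% of the leave-one-out score.
#'
#' @param full,loo Aligned score vectors.
#' @param top Fraction defining the top set (default 0.1).
#' @return Scalar in \[0, 1\].
#' @export
top_decile_retention <- function(full, loo, top = 0.1) {
  stopifnot(length(full) == length(loo))
  n <- length(full)
  k <- max(1L, round(top * n))
  top_full <- order(full, decreasing = TRUE)[seq_len(k)]
  top_loo <- order(loo, decreasing = TRUE)[seq_len(k)]
  length(intersect(top_full, top_loo)) / k
}

#' Empirical thresholds of the top score percentiles
#'
#' @param scores Score vector (>= 1 value).
#' @param top_percents Top-percent levels (defaults: 50, 10, 1, 0.1, 0.01).
#' @return Tibble `top_percent`, `threshold` (monotone non-decreasing).
#' @export
percentile_thresholds <- function(scores,
                                  top_percents = c(50, 10, 1, 0.1, 0.01)) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0) stop("need at least one finite score")
  tibble::tibble(
    top_percent = top_percents,
    threshold = unname(stats::quantile(scores, 1 - top_percents / 100))
  )
}

#' Score an annotated cohort
#'
#' Computes cohort-wide CADD and structure quantile ranks, assembles the
#' component table from the annotation columns, and returns the scored table
#' with the composite score, its nine leave-one-out variants and the score
#' percentile within the cohort.
#'
#' @param annotated Annotated synonymous-mutation table (one row per
#'   mutation occurrence; occurrences of one variant share component values).
#' @param structure_score Column name holding the structure score used for
#'   the structure quantile rank (default `"remurna_entropy"`).
#' @param cgc_map Function mapping the logical `cancer_gene` column to the
#'   cancer-gene score (default: 2/0).
#' @return `annotated` with component, `score`, `loo_*` and
#'   `score_percentile` columns appended.
#' @export
score_cohort <- function(annotated, structure_score = "remurna_entropy",
                         cgc_map = function(x) ifelse(x %in% TRUE, 2, 0)) {
  safe_qrank <- function(x) {
    if (is.null(x) || all(!is.finite(x))) rep(NA_real_, nrow(annotated))
    else quantile_rank(x)
  }
  qC <- safe_qrank(annotated$cadd_raw)
  qR <- safe_qrank(annotated[[structure_score]])
  comp <- score_components(
    frequency = annotated$frequency,
    signature_p = annotated$signature_p,
    avg_mutation_load = pmax(1, annotated$avg_mutation_load),
    cgc_score = cgc_map(annotated$cancer_gene),
    phastcons = annotated$phastcons,
    snp_score = ifelse(annotated$snp_flag %in% TRUE, 0, 1),
    fathmm = annotated$fathmm,
    cadd_qrank = qC,
    structure_qrank = qR
  )
  loo <- leave_one_out(comp)
  names(loo) <- paste0("loo_", names(loo))
  # component columns carry the validated/imputed values the score used,
  # overwriting same-named annotation columns (`imputed` flags affected rows)
  out <- annotated
  for (f in names(comp)) out[[f]] <- comp[[f]]
  out <- dplyr::bind_cols(
    out, tibble::tibble(score = synmicdb_score(comp)), loo
  )
  out$score_percentile <- quantile_rank(out$score)
  out
}
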