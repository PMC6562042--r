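#' Export per-mutation sequence windows for external folding tools
#'
#' One record per mutation: the transcript window `flank` nt around the
#' mutated base (truncated at transcript boundaries), the 0-based offset of
#' the mutation within the window, and the coding-strand alleles. Windows
#' shorter than `2*flank + 1` nt are flagged so length-sensitive analyses can
#' drop them.
#'
#' @param annotated Annotated table (`mutation_id`, `transcript_id`,
#'   `cds_pos`, `ref`, `alt`).
#' @param transcripts Transcript-model tibble.
#' @param flank Flank size in nt (default 200).
#' @return Tibble `mutation_id`, `window`, `offset0`, `ref`, `alt`,
#'   `truncated`, `gc_content`, `context` (= flank).
#' @export
export_windows <- function(annotated, transcripts, flank = 200L) {
  rows <- dplyr::distinct(annotated, .data$mutation_id, .data$transcript_id,
                          .data$cds_pos, .data$ref, .data$alt)
  purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    tx <- transcripts[transcripts$transcript_id == r$transcript_id, ]
    w <- extract_window(tx, tx$cds_start + r$cds_pos - 1L, flank)
    at <- substring(w$window, w$offset0 + 1L, w$offset0 + 1L)
    if (at != r$ref) {
      stop("export error: window/ref mismatch for ", r$mutation_id)
    }
    tibble::tibble(
      mutation_id = r$mutation_id, window = w$window, offset0 = w$offset0,
      ref = r$ref, alt = r$alt, truncated = w$truncated,
      gc_content = gc_content(w$window), context = as.integer(flank)
    )
  })
}

#' GC content of sequence windows
#' @param x Character vector of DNA sequences.
#' @return Fraction of G/C bases per sequence.
#' @export
gc_content <- function(x) {
  gc <- nchar(gsub("[^GCgc]", "", x))
  gc / nchar(x)
}

#' Write exported windows as variant-tagged FASTA
#'
#' Record headers are `>mutation_id|offset0|ref>alt`.
#' @param windows Output of [export_windows()].
#' @param path FASTA path.
#' @export
write_window_fasta <- function(windows, path) {
  headers <- sprintf("%s|%d|%s>%s", windows$mutation_id, windows$offset0,
                     windows$ref, windows$alt)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(windows$window, headers)), path)
  invisible(path)
}

#' Ingest RNA-structure aberration scores from external tools
#'
#' Joins remuRNA-style output (`mutation_id`, `remurna_entropy`, optionally
#' `mfe_wt`, `mfe_mut`, `gc_content`) with RNAsnp-style output
#' (`mutation_id`, `rnasnp_dmax`, `rnasnp_pvalue`, optionally
#' `interval_start`, `interval_end`) on `mutation_id`. A mutation present in
#' only one table is retained with NAs for the other; duplicate ids within a
#' table are an error.
#'
#' @param remurna,rnasnp Tibbles (either may be NULL).
#' @param context Flank length (100 or 200) stamped on every row.
#' @return StructureScore tibble, one row per (mutation, context).
#' @export
ingest_scores <- function(remurna = NULL, rnasnp = NULL, context = 200L) {
  check <- function(tbl, need, what) {
    if (is.null(tbl)) return(NULL)
    miss <- setdiff(need, names(tbl))
    if (length(miss)) {
      stop("format error in ", what, " table: missing column(s) ",
           paste(miss, collapse = ", "))
    }
    d <- tbl$mutation_id[duplicated(tbl$mutation_id)]
    if (length(d)) {
      stop("duplicate mutation_id in ", what, " table: ",
           paste(unique(d), collapse = ", "))
    }
    tbl
  }
  remurna <- check(remurna, c("mutation_id", "remurna_entropy"), "remuRNA")
  rnasnp <- check(rnasnp, c("mutation_id", "rnasnp_dmax", "rnasnp_pvalue"),
                  "RNAsnp")
  if (is.null(remurna) && is.null(rnasnp)) stop("no score table supplied")
  out <- if (is.null(remurna)) rnasnp
         else if (is.null(rnasnp)) remurna
         else dplyr::full_join(remurna, rnasnp, by = "mutation_id")
  bad_p <- !is.na(out[["rnasnp_pvalue"]]) &
    (out[["rnasnp_pvalue"]] < 0 | out[["rnasnp_pvalue"]] > 1)
  if (length(bad_p) && any(bad_p)) stop("rnasnp_pvalue outside [0, 1]")
  dplyr::mutate(out, context = as.integer(context))
}

#' Quantile rank of a score vector
#'
#' `rank_i = (number of values <= value_i) / n` over the non-missing values,
#' with ties sharing the mean of their positions; the maximum maps to 1.
#' NAs pass through as NA.
#'
#' @param values Numeric vector (at least one finite value).
#' @return Ranks in (0, 1], same length as `values`.
#' @export
quantile_rank <- function(values) {
  ok <- is.finite(values)
  if (!any(ok)) stop("quantile_rank needs at least one finite value")
  out <- rep(NA_real_, length(values))
  out[ok] <- rank(values[ok], ties.method = "average") / sum(ok)
  out
}

#' Spearman rank correlation over pairwise-complete rows
#'
#' @param score_a,score_b Paired numeric vectors.
#' @return Spearman's rho.
#' @export
rank_correlation <- function(score_a, score_b) {
  ok <- is.finite(score_a) & is.finite(score_b)
  if (sum(ok) < 3L) stop("insufficient data: need >= 3 complete pairs")
  stats::cor(score_a[ok], score_b[ok], method = "spearman")
}

#' Fraction of globally top-percentile scores within each positional bin
#'
#' Takes the global top `percentile`% of mutations by score and computes, per
#' CDS decile, (top-percentile mutations in the bin) / (mutations in the
#' bin). If scores are independent of position, every fraction is about
#' `percentile/100`; the bin-count-weighted mean of the fractions equals the
#' overall top-set share exactly.
#'
#' @param scores Numeric scores (NAs dropped with their bins).
#' @param bins Bin labels (e.g. CDS deciles), aligned with `scores`.
#' @param percentile Top percentile to select (default 5).
#' @return Tibble `bin`, `n`, `n_top`, `fraction` (NA for empty bins).
#' @export
top_percentile_by_bin <- function(scores, bins, percentile = 5) {
  ok <- is.finite(scores) & !is.na(bins)
  scores <- scores[ok]
  bins <- bins[ok]
  n <- length(scores)
  k <- round(n * percentile / 100)
  top <- logical(n)
  if (k > 0) top[order(scores, decreasing = TRUE)[seq_len(k)]] <- TRUE
  all_bins <- if (is.numeric(bins)) seq_len(max(bins)) else sort(unique(bins))
  tibble::tibble(bin = all_bins) |>
    dplyr::left_join(
      tibble::tibble(bin = bins, top = top) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n = dplyr::n(), n_top = sum(.data$top),
                         .groups = "drop"),
      by = "bin") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      n_top = dplyr::coalesce(.data$n_top, 0L),
      fraction = ifelse(.data$n > 0, .data$n_top / .data$n, NA_real_)
    )
}

#' Per-decile means of window GC content and MFE
#'
#' @param windows Tibble with `gc_content`, `mfe` and `cds_decile` columns.
#' @return Tibble per decile: mean and SEM of both metrics.
#' @export
window_summaries <- function(windows) {
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  windows |>
    dplyr::group_by(.data$cds_decile) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_gc = mean(.data$gc_content, na.rm = TRUE),
      sem_gc = sem(stats::na.omit(.data$gc_content)),
      mean_mfe = mean(.data$mfe, na.rm = TRUE),
      sem_mfe = sem(stats::na.omit(.data$mfe)),
      .groups = "drop"
    )
}

#' Structure score across mutation-load bins
#'
#' Bins mutations by the average mutation load of their carrier samples and
#' compares the structure score between adjacent bins with two-sample
#' t-tests.
#'
#' @param scores Structure scores (e.g. remuRNA relative entropy).
#' @param loads Average mutation loads, aligned with `scores`.
#' @param bin_edges Strictly increasing numeric edges (values outside are
#'   dropped).
#' @return List with `bins` (per bin: n, mean, SEM) and `tests` (adjacent-bin
#'   t statistics and p-values; skipped bins flagged).
#' @export
score_by_load_bins <- function(scores, loads, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  ok <- is.finite(scores) & is.finite(loads)
  scores <- scores[ok]; loads <- loads[ok]
  bin <- cut(loads, bin_edges, include.lowest = TRUE)
  keep <- !is.na(bin)
  scores <- scores[keep]; bin <- droplevels(bin[keep])
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  bins <- tibble::tibble(bin = levels(bin)) |>
    dplyr::left_join(
      tibble::tibble(bin = as.character(bin), score = scores) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                         sem = sem(.data$score), .groups = "drop"),
      by = "bin")
  lv <- levels(bin)
  tests <- NULL
  if (length(lv) > 1) {
    tests <- purrr::map_dfr(seq_len(length(lv) - 1L), function(i) {
      a <- scores[bin == lv[i]]
      b <- scores[bin == lv[i + 1L]]
      if (length(a) < 2L || length(b) < 2L) {
        return(tibble::tibble(bin_a = lv[i], bin_b = lv[i + 1L],
                              t = NA_real_, p_value = NA_real_,
                              skipped = TRUE))
      }
      tt <- stats::t.test(a, b)
      tibble::tibble(bin_a = lv[i], bin_b = lv[i + 1L],
                     t = unname(tt$statistic), p_value = tt$p.value,
                     skipped = FALSE)
    })
  }
  list(bins = bins, tests = tests)
}
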