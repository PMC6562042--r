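#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> curate -> annotate -> motifs -> structure ->
#' score -> distributions with one config. Every stage writes its table under
#' `out_dir` and logs its row counts; no stage silently drops rows (curation
#' quarantines rejects with reasons). Rerunning with the same config yields
#' identical outputs.
#'
#' @param config A [synthetic_config()]; the seed governs all randomness.
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run (dependencies of a
#'   requested stage are always run). `"motifs"` may be disabled; the final
#'   table then simply lacks the motif columns.
#' @param motif_catalog Optional curated motif catalog for the motif stage;
#'   default is the small bundled synthetic catalog.
#' @param motif_flank,structure_flank Window flanks (nt).
#' @return Invisibly, a list with the in-memory stage results and `run_log`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("motifs", "structure", "score",
                                    "distributions"),
                         motif_catalog = NULL,
                         motif_flank = 100L, structure_flank = 200L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config = unclass(config)[setdiff(names(config), "signature")],
              signature = as.list(config$signature),
              package_version = as.character(utils::packageVersion("synmut")),
              stages = list())
  note <- function(stage, rows) {
    log$stages[[stage]] <<- rows
  }

  transcriptome <- generate_transcriptome(config)
  write_transcriptome(transcriptome, out_dir)
  mutations <- generate_mutations(config, transcriptome)
  refs <- generate_reference_tables(config, transcriptome, mutations)
  readr::write_tsv(mutations, file.path(out_dir, "mutations_raw.tsv"))
  note("simulate", nrow(mutations))

  cur <- curate_mutations(mutations, transcriptome$transcripts)
  readr::write_tsv(cur$curated, file.path(out_dir, "mutations_curated.tsv"))
  readr::write_tsv(cur$rejected, file.path(out_dir, "mutations_rejected.tsv"))
  readr::write_tsv(cur$log, file.path(out_dir, "curation_log.tsv"))
  note("curate", nrow(cur$curated))

  annotated <- annotate_mutations(cur$curated, transcriptome$transcripts,
                                  config$signature, refs)
  note("annotate", nrow(annotated))

  syn <- annotated[annotated$consequence == "synonymous", ]

  if ("motifs" %in% stages) {
    if (is.null(motif_catalog)) {
      motif_catalog <- read_motif_catalog(
        system.file("extdata", "synthetic_ese_ess_catalog.tsv",
                    package = "synmut"),
        source_name = "synthetic")
    }
    motifs <- scan_mutation_windows(syn, transcriptome$transcripts,
                                    motif_catalog, flank = motif_flank)
    readr::write_tsv(motifs$summary, file.path(out_dir, "motif_summary.tsv"))
    readr::write_tsv(motifs$diffs, file.path(out_dir, "motif_diffs.tsv"))
    annotated <- dplyr::left_join(
      annotated,
      motifs$summary[, c("mutation_id", "n_gain", "n_loss", "any_change")],
      by = "mutation_id")
    note("motifs", nrow(motifs$summary))
  } else motifs <- NULL

  structure_scores <- NULL
  if ("structure" %in% stages) {
    windows <- export_windows(syn, transcriptome$transcripts,
                              flank = structure_flank)
    write_window_fasta(windows, file.path(out_dir, "structure_windows.fa"))
    st <- refs$structure
    st$mutation_id <- paste0(st$chrom, ":", st$pos, ":", st$ref, ">", st$alt)
    keep <- st$mutation_id %in% syn$mutation_id
    structure_scores <- ingest_scores(
      remurna = st[keep, c("mutation_id", "remurna_entropy", "mfe_wt",
                           "mfe_mut")],
      rnasnp = st[keep, c("mutation_id", "rnasnp_dmax", "rnasnp_pvalue")],
      context = structure_flank)
    readr::write_tsv(structure_scores,
                     file.path(out_dir, "structure_scores.tsv"))
    annotated <- dplyr::left_join(annotated, structure_scores,
                                  by = "mutation_id")
    note("structure", nrow(structure_scores))
  }

  scored <- NULL
  if ("score" %in% stages) {
    syn2 <- annotated[annotated$consequence == "synonymous", ]
    if (is.null(structure_scores)) syn2$remurna_entropy <- NA_real_
    scored <- score_cohort(syn2)
    readr::write_tsv(
      percentile_thresholds(scored$score) |>
        dplyr::mutate(top_percent = as.character(.data$top_percent)),
      file.path(out_dir, "score_thresholds.tsv"))
    note("score", nrow(scored))
  }

  dists <- NULL
  if ("distributions" %in% stages && !is.null(scored)) {
    dists <- list(
      cds = positional_distribution(scored, by = "cds"),
      cds_by_class = positional_distribution(scored, by = "cds",
                                             stratify_by = "substitution_class"),
      internal_exon = positional_distribution(scored, by = "internal_exon"),
      score_by_cds_bin = metric_by_bin(scored, "score", by = "cds"),
      per_study = per_study_stratification(scored)
    )
    readr::write_tsv(dists$cds, file.path(out_dir, "dist_cds_deciles.tsv"))
    readr::write_tsv(dists$cds_by_class,
                     file.path(out_dir, "dist_cds_by_class.tsv"))
    readr::write_tsv(dists$internal_exon,
                     file.path(out_dir, "dist_internal_exon.tsv"))
    readr::write_tsv(dists$score_by_cds_bin,
                     file.path(out_dir, "score_by_cds_bin.tsv"))
    note("distributions", nrow(dists$cds))
  }

  final <- if (!is.null(scored)) scored else
    annotated[annotated$consequence == "synonymous", ]
  export_database_table(final, file.path(out_dir, "database_table.tsv"))
  note("export", nrow(final))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    transcriptome = transcriptome, mutations = mutations, refs = refs,
    curated = cur, annotated = annotated, motifs = motifs,
    structure = structure_scores, scored = scored, distributions = dists,
    run_log = log
  ))
}

#' Export the flat database-style table
#'
#' One row per synonymous mutation occurrence with all annotation, motif,
#' structure and score columns, written as TSV alongside a machine-readable
#' column dictionary (JSON).
#'
#' @param scored Scored (or annotated) synonymous table.
#' @param path Output TSV path; the dictionary is written next to it with
#'   suffix `.dictionary.json`.
#' @return Invisibly, the exported tibble.
#' @export
export_database_table <- function(scored, path) {
  drop <- c("alt_events")  # list-column; the flat string column remains
  flat <- scored[, setdiff(names(scored), drop)]
  readr::write_tsv(flat, path)
  base_dict <- c(
    mutation_id = "genomic variant identity chrom:pos:ref>alt (genomic strand alleles)",
    gene = "gene symbol", transcript_id = "transcript the mutation is annotated on",
    sample_id = "tumor sample carrying the mutation occurrence",
    study_id = "contributing study", chrom = "contig", pos = "1-based genomic position",
    strand = "transcript strand", cds_pos = "1-based CDS coordinate",
    ref = "coding-strand reference base", alt = "coding-strand alternate base",
    consequence = "re-derived coding consequence",
    tumor_tier = "Organ System-Site-Histology tier string",
    frequency = "number of distinct samples carrying the variant",
    recurrent = "frequency > 1",
    signature_p = "signature probability of the substitution class",
    signature_normalized_frequency = "frequency x (1 - p)",
    avg_mutation_load = "mean total mutation count of carrier samples",
    substitution_class = "one of the six strand-symmetric classes",
    cds_fraction = "cds_pos / CDS length", cds_decile = "CDS decile 1-10",
    codon_index = "1-based codon index", amino_acid = "reference amino acid",
    exon_context = "first/internal/last/monoexonic",
    internal_exon_decile = "decile within internal exon (5'->3')",
    boundary_distance = "nt to the nearest end of the containing exon",
    alt_events_str = "overlapping alternative-event labels",
    phastcons = "conservation score [0,1]", cancer_gene = "gene in cancer-gene list",
    snp_flag = "annotated as known SNP in the catalog",
    fathmm = "FATHMM-MKL score [0,1]", cadd_raw = "CADD raw score",
    remurna_entropy = "remuRNA relative entropy",
    rnasnp_dmax = "RNAsnp base-pair-probability distance",
    rnasnp_pvalue = "RNAsnp GC/length-normalized empirical p-value",
    n_gain = "ESE/ESS motif occurrences gained", n_loss = "motif occurrences lost",
    any_change = "at least one motif gained or lost",
    score = "composite prioritization score",
    score_percentile = "cohort quantile rank of the score"
  )
  dict <- lapply(names(flat), function(nm) {
    if (nm %in% names(base_dict)) base_dict[[nm]]
    else if (startsWith(nm, "loo_")) {
      paste("score recomputed without the", sub("^loo_", "", nm), "parameter")
    } else "see function documentation"
  })
  names(dict) <- names(flat)
  jsonlite::write_json(dict, paste0(path, ".dictionary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(flat)
}
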