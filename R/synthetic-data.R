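#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions for a toy transcriptome plus a COSMIC-like
#' somatic mutation catalog with known, injectable structure: a six-class
#' substitution signature, optional depletion of the first CDS decile and of
#' the outer deciles of internal exons, a log-uniform per-sample mutation-load
#' distribution, and Zipf-like per-site recurrence.
#'
#' @param n_genes,n_samples Cohort sizes (one transcript per gene).
#' @param cds_length_range CDS length bounds in nucleotides (multiples of 3).
#' @param exon_count_range Bounds on the number of exons per transcript.
#' @param signature A [signature_model()] driving the substitution mix.
#' @param depletion_first_decile Multiplicative placement weight in \[0,1\]
#'   for positions in the first 10% of the CDS (1 = no depletion).
#' @param depletion_exon_edges Placement weight in \[0,1\] for the outer
#'   deciles (1 and 10) of internal exons.
#' @param cancer_gene_fraction Fraction of genes labelled as cancer genes.
#' @param snp_fraction Fraction of mutated sites flagged as known SNPs.
#' @param load_range Per-sample total mutation count is drawn log-uniformly
#'   over this range.
#' @param recurrence_shape Exponent of the Zipf-like weight over candidate
#'   sites; larger values give heavier recurrence tails.
#' @param sites_per_mutation Candidate-site catalog size as a multiple of the
#'   total mutation count; together with `recurrence_shape` this sets the
#'   recurrent fraction (defaults give ~27% recurrent mutations).
#' @param duplicate_rate Fraction of catalog rows emitted twice verbatim, to
#'   emulate multi-mapped duplicate entries that curation must remove.
#' @param n_studies Number of study labels samples are assigned to.
#' @param utr_length_range,intron_length_range,min_exon_length Transcript
#'   architecture knobs (nucleotides).
#' @param score_load_correlation Gaussian-copula correlation in \[-1,1\]
#'   between the synthetic RNA-structure score and per-variant average
#'   mutation load (0 = independent; negative values emulate the observed
#'   higher structural impact in low-burden samples).
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return A validated config list (class `synthetic_config`).
#' @export
synthetic_config <- function(n_genes = 120,
                             n_samples = 40,
                             cds_length_range = c(300L, 2400L),
                             exon_count_range = c(1L, 10L),
                             signature = default_signature(),
                             depletion_first_decile = 1,
                             depletion_exon_edges = 1,
                             cancer_gene_fraction = 0.03,
                             snp_fraction = 0.08,
                             load_range = c(50L, 2000L),
                             recurrence_shape = 0.5,
                             sites_per_mutation = 5,
                             duplicate_rate = 0.02,
                             n_studies = 6L,
                             utr_length_range = c(20L, 200L),
                             intron_length_range = c(60L, 400L),
                             min_exon_length = 30L,
                             score_load_correlation = 0,
                             seed = 1L) {
  props <- c(depletion_first_decile, depletion_exon_edges,
             cancer_gene_fraction, snp_fraction, duplicate_rate)
  if (any(props < 0 | props > 1)) stop("proportions/weights must lie in [0, 1]")
  if (any(cds_length_range %% 3L != 0L)) stop("cds_length_range must be multiples of 3")
  if (cds_length_range[1] < 9L) stop("CDS needs at least start + one sense + stop codon")
  if (exon_count_range[1] < 1L) stop("exon_count_range must be >= 1")
  if (abs(score_load_correlation) > 1) stop("score_load_correlation must lie in [-1, 1]")
  min_tx <- utr_length_range[1] + cds_length_range[1] + utr_length_range[1]
  if (exon_count_range[1] * min_exon_length > min_tx) {
    stop("configuration error: minimum exon count cannot fit the shortest transcript")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    cds_length_range = as.integer(cds_length_range),
    exon_count_range = as.integer(exon_count_range),
    signature = signature_model(signature),
    depletion_first_decile = depletion_first_decile,
    depletion_exon_edges = depletion_exon_edges,
    cancer_gene_fraction = cancer_gene_fraction,
    snp_fraction = snp_fraction,
    load_range = as.integer(load_range),
    recurrence_shape = recurrence_shape,
    sites_per_mutation = sites_per_mutation,
    duplicate_rate = duplicate_rate,
    n_studies = as.integer(n_studies),
    utr_length_range = as.integer(utr_length_range),
    intron_length_range = as.integer(intron_length_range),
    min_exon_length = as.integer(min_exon_length),
    score_load_correlation = score_load_correlation,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

SENSE_CODONS <- local({
  gc <- Biostrings::getGeneticCode("1")
  names(gc)[gc != "*"]
})
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate a toy transcriptome
#'
#' Each gene gets one transcript on its own contig: random UTRs, a CDS of
#' random sense codons (start codon first, one stop codon last, no internal
#' stops), a random exon partition with random introns, and a random strand.
#' With a fixed seed the output is byte-identical across runs.
#'
#' @param config A [synthetic_config()].
#' @return List with `transcripts` (transcript-model tibble), `genome`
#'   (named character vector of contig sequences) and the `config` echo.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  rows <- vector("list", config$n_genes)
  genome <- character(config$n_genes)
  contigs <- sprintf("ctg%03d", seq_len(config$n_genes))
  for (i in seq_len(config$n_genes)) {
    n_codons <- sample(seq(config$cds_length_range[1] %/% 3L,
                           config$cds_length_range[2] %/% 3L), 1L)
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1L))
    utr5 <- sample(seq(config$utr_length_range[1], config$utr_length_range[2]), 1L)
    utr3 <- sample(seq(config$utr_length_range[1], config$utr_length_range[2]), 1L)
    tx_seq <- paste0(random_dna(utr5), cds, random_dna(utr3))
    tx_len <- nchar(tx_seq)
    k_max <- min(config$exon_count_range[2], tx_len %/% config$min_exon_length)
    if (k_max < config$exon_count_range[1]) {
      stop("configuration error: exon count exceeds what the transcript can hold")
    }
    k <- sample(seq(config$exon_count_range[1], k_max), 1L)
    extra <- tx_len - k * config$min_exon_length
    exon_w <- config$min_exon_length +
      as.vector(stats::rmultinom(1L, extra, rep(1 / k, k)))
    strand <- sample(c("+", "-"), 1L)
    introns <- if (k > 1L) {
      sample(seq(config$intron_length_range[1], config$intron_length_range[2]),
             k - 1L, replace = TRUE)
    } else integer(0)
    # split transcript sequence into exons in transcript order
    ends <- cumsum(exon_w)
    exon_seq <- substring(tx_seq, ends - exon_w + 1L, ends)
    flank <- 50L
    if (strand == "+") {
      genomic_exons <- exon_seq
      genomic_w <- exon_w
    } else {
      genomic_exons <- rev(as.character(revcomp(exon_seq)))
      genomic_w <- rev(exon_w)
    }
    pieces <- character(2L * k + 1L)
    pieces[1] <- random_dna(flank)
    starts0 <- integer(k)
    at <- flank
    for (j in seq_len(k)) {
      starts0[j] <- at
      pieces[2L * j] <- genomic_exons[j]
      at <- at + genomic_w[j]
      gap <- if (j < k) introns[j] else flank
      pieces[2L * j + 1L] <- random_dna(gap)
      at <- at + gap
    }
    genome[i] <- paste(pieces, collapse = "")
    rows[[i]] <- transcript_model(
      transcript_id = sprintf("TX%03d", i), gene = sprintf("GENE%03d", i),
      chrom = contigs[i], strand = strand,
      exon_starts0 = starts0, exon_ends0 = starts0 + genomic_w,
      cds_start = utr5 + 1L, cds_end = utr5 + nchar(cds),
      sequence = tx_seq, code_table = "standard"
    )
  }
  list(
    transcripts = dplyr::bind_rows(rows),
    genome = stats::setNames(genome, contigs),
    config = config
  )
}

# Per-CDS-position table for one transcriptome: placement weights implement
# the configured depletion (first CDS decile; outer deciles of internal exons).
cds_position_table <- function(transcriptome, config) {
  txs <- transcriptome$transcripts
  purrr::map_dfr(seq_len(nrow(txs)), function(i) {
    tx <- txs[i, ]
    L <- cds_length(tx)
    pos <- seq_len(L)
    tpos <- tx$cds_start + pos - 1L
    ref <- strsplit(cds_sequence(tx), "")[[1]]
    decile <- pmin(pmax(ceiling(10 * pos / L), 1L), 10L)
    ex <- exon_table(tx)
    n_ex <- nrow(ex)
    idx <- findInterval(tpos, ex$tx_start)
    in_exon_pos <- tpos - ex$tx_start[idx] + 1L
    exon_decile <- pmin(pmax(ceiling(10 * in_exon_pos / ex$width[idx]), 1L), 10L)
    internal <- idx > 1L & idx < n_ex
    w <- ifelse(decile == 1L, config$depletion_first_decile, 1) *
      ifelse(internal & exon_decile %in% c(1L, 10L), config$depletion_exon_edges, 1)
    tibble::tibble(tx_idx = i, cds_pos = pos, ref = ref, weight = w)
  })
}

# Pyrimidine-rooted change of each class, e.g. "C>T" -> c(from="C", to="T").
class_change <- function(class) {
  m <- stringr::str_split_fixed(class, ">", 2)
  list(from = m[, 1], to = m[, 2])
}

#' Generate a COSMIC-like somatic mutation catalog
#'
#' Draws a candidate-site catalog (substitution class from the signature,
#' position weighted by the depletion multipliers among ref-compatible bases),
#' Zipf-weights the sites to create recurrence, then assigns per-sample
#' mutation counts from the log-uniform load distribution. A small fraction of
#' rows is duplicated verbatim to exercise downstream deduplication.
#'
#' @param config A [synthetic_config()].
#' @param transcriptome Output of [generate_transcriptome()] for the same
#'   config family.
#' @return Tibble with the documented COSMIC-like columns: `gene`,
#'   `transcript_id`, `sample_id`, `study_id`, `chrom`, `pos` (1-based
#'   genomic), `strand`, `cds_change` (HGVS-like c. notation, coding strand),
#'   `consequence`, `organ_system`, `primary_site`, `histology`, `snp_flag`.
#' @export
generate_mutations <- function(config, transcriptome) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  txs <- transcriptome$transcripts
  pos_tbl <- cds_position_table(transcriptome, config)
  is_cg <- pos_tbl$ref %in% c("C", "G")

  samples <- sprintf("SAMP%04d", seq_len(config$n_samples))
  studies <- sprintf("ST%02d", seq_len(config$n_studies))
  sample_study <- sample(studies, config$n_samples, replace = TRUE)
  loads <- pmax(1L, round(exp(stats::runif(
    config$n_samples, log(config$load_range[1]), log(config$load_range[2])
  ))))
  n_total <- sum(loads)

  # Event classes follow the signature; each class then gets its own
  # candidate-site catalog of distinct variants. Catalog composition across
  # depletion strata (distinct placement-weight values) is allocated exactly
  # proportional to weight x stratum size, with uniform without-replacement
  # sampling inside each stratum, so the event-level positional distribution
  # matches the closed-form thinning expectation.
  event_class <- sample(SUBSTITUTION_CLASSES, n_total, replace = TRUE,
                        prob = config$signature)
  pick <- integer(0)
  site_alt <- character(0)
  event_site <- integer(0)
  event_ids <- integer(0)
  for (cl in SUBSTITUTION_CLASSES) {
    ev <- which(event_class == cl)
    n_cl <- length(ev)
    if (n_cl == 0L) next
    chg <- class_change(cl)
    pool <- which(if (chg$from == "C") is_cg else !is_cg)
    strata <- split(pool, pos_tbl$weight[pool])
    w_s <- as.numeric(names(strata))
    mass <- vapply(strata, length, integer(1)) * w_s
    # capping at the weighted capacity keeps the stratum allocation exactly
    # proportional to weight x size even when the pool saturates
    m_cl <- min(ceiling(config$sites_per_mutation * n_cl),
                floor(sum(mass) / max(w_s)))
    alloc <- floor(m_cl * mass / sum(mass))
    rem <- m_cl - sum(alloc)
    if (rem > 0) {
      frac <- m_cl * mass / sum(mass) - alloc
      bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
      alloc[bump] <- alloc[bump] + 1L
    }
    alloc <- pmin(alloc, vapply(strata, length, integer(1)))
    sites_cl <- unlist(lapply(seq_along(strata), function(s) {
      st <- strata[[s]]
      if (alloc[s] == 0L) return(integer(0))
      st[sample.int(length(st), alloc[s])]
    }), use.names = FALSE)
    sites_cl <- sites_cl[sample.int(length(sites_cl))]  # random Zipf order
    zipf_w <- seq_along(sites_cl)^(-config$recurrence_shape)
    draw <- sample.int(length(sites_cl), n_cl, replace = TRUE, prob = zipf_w)
    ref_cl <- pos_tbl$ref[sites_cl]
    alt_cl <- ifelse(ref_cl == chg$from, chg$to, complement_base(chg$to))
    off <- length(pick)
    pick <- c(pick, sites_cl)
    site_alt <- c(site_alt, alt_cl)
    event_site <- c(event_site, off + draw)
    event_ids <- c(event_ids, ev)
  }
  m_sites <- length(pick)
  site_ref <- pos_tbl$ref[pick]
  site_snp <- stats::runif(m_sites) < config$snp_fraction

  event_sample <- rep.int(seq_len(config$n_samples), loads)[event_ids]
  keep <- !duplicated(cbind(event_sample, event_site))
  event_site <- event_site[keep]
  event_sample <- event_sample[keep]

  pk <- pick[event_site]
  out <- tibble::tibble(
    tx_idx = pos_tbl$tx_idx[pk],
    cds_pos = pos_tbl$cds_pos[pk],
    ref = site_ref[event_site],
    alt = site_alt[event_site],
    snp_flag = site_snp[event_site],
    sample_id = samples[event_sample],
    study_id = sample_study[event_sample]
  )
  # map to genome and classify, per transcript
  out <- out |>
    dplyr::group_by(.data$tx_idx) |>
    dplyr::group_modify(function(d, key) {
      tx <- txs[key$tx_idx, ]
      d$pos <- transcript_to_genome(tx, tx$cds_start + d$cds_pos - 1L)
      d$consequence <- classify_codon_change(cds_sequence(tx), d$cds_pos,
                                             d$alt, tx$code_table)
      d
    }) |>
    dplyr::ungroup()
  out <- out |>
    dplyr::mutate(
      gene = txs$gene[.data$tx_idx],
      transcript_id = txs$transcript_id[.data$tx_idx],
      chrom = txs$chrom[.data$tx_idx],
      strand = txs$strand[.data$tx_idx],
      cds_change = sprintf("c.%d%s>%s", .data$cds_pos, .data$ref, .data$alt)
    )

  tumor_vocab <- tibble::tibble(
    organ_system = c("Respiratory System", "Digestive System", "Digestive System",
                     "Skin", "Urinary System", "Reproductive System",
                     "Digestive System", ""),
    primary_site = c("Lung", "Colon", "Stomach", "Skin", "Kidney", "Ovary",
                     "Liver", ""),
    histology = c("Adenocarcinoma", "Adenocarcinoma", "Adenocarcinoma",
                  "Malignant Melanoma", "Clear Cell Carcinoma",
                  "Serous Carcinoma", "Hepatocellular Carcinoma", "")
  )
  tum <- tumor_vocab[sample.int(nrow(tumor_vocab), config$n_samples,
                                replace = TRUE), ]
  tum$sample_id <- samples
  out <- dplyr::left_join(out, tum, by = "sample_id")

  dup <- out[stats::runif(nrow(out)) < config$duplicate_rate, ]
  out <- dplyr::bind_rows(out, dup)
  out <- out[sample.int(nrow(out)), ]
  dplyr::select(out, "gene", "transcript_id", "sample_id", "study_id",
                "chrom", "pos", "strand", "cds_change", "consequence",
                "organ_system", "primary_site", "histology", "snp_flag")
}

#' Generate synthetic reference tables for the annotation joins
#'
#' Conservation, FATHMM-MKL, CADD, SNP, ClinVar-like and RNA-structure score
#' tables over the variants of a synthetic catalog, plus a cancer-gene list.
#' Scores are independent uniforms/normals unless `score_load_correlation`
#' is set, in which case the structure score is correlated with per-variant
#' average mutation load through a Gaussian copula.
#'
#' @param config A [synthetic_config()].
#' @param transcriptome Matching transcriptome.
#' @param mutations Catalog from [generate_mutations()].
#' @return Named list of tibbles: `conservation` (chrom, pos, phastcons),
#'   `cancer_genes` (gene), `snps` (variant key), `fathmm`, `cadd`,
#'   `clinvar`, `structure` (remuRNA/RNAsnp-style columns).
#' @export
generate_reference_tables <- function(config, transcriptome, mutations) {
  set.seed(config$seed + 2L)
  g_ref <- ifelse(mutations$strand == "-",
                  complement_base(sub("^c\\.\\d+([ACGT])>.*$", "\\1", mutations$cds_change)),
                  sub("^c\\.\\d+([ACGT])>.*$", "\\1", mutations$cds_change))
  g_alt <- ifelse(mutations$strand == "-",
                  complement_base(sub("^c\\.\\d+[ACGT]>([ACGT])$", "\\1", mutations$cds_change)),
                  sub("^c\\.\\d+[ACGT]>([ACGT])$", "\\1", mutations$cds_change))
  var <- dplyr::distinct(tibble::tibble(
    chrom = mutations$chrom, pos = mutations$pos, ref = g_ref, alt = g_alt
  ))
  loci <- dplyr::distinct(var[, c("chrom", "pos")])
  conservation <- dplyr::mutate(loci, phastcons = stats::runif(dplyr::n()))
  genes <- unique(transcriptome$transcripts$gene)
  n_cg <- max(1L, round(config$cancer_gene_fraction * length(genes)))
  cancer_genes <- tibble::tibble(gene = sort(sample(genes, n_cg)))

  # avg load per variant (for the optional score-load correlation)
  sample_load <- dplyr::count(mutations, .data$sample_id, name = "load")
  mut_load <- mutations |>
    dplyr::left_join(sample_load, by = "sample_id") |>
    dplyr::mutate(ref = g_ref, alt = g_alt) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(avg_load = mean(.data$load), .groups = "drop")
  var <- dplyr::left_join(var, mut_load, by = c("chrom", "pos", "ref", "alt"))

  n <- nrow(var)
  rho <- config$score_load_correlation
  z_load <- as.numeric(scale(log(var$avg_load)))
  if (any(!is.finite(z_load))) z_load[!is.finite(z_load)] <- 0
  z <- rho * z_load + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  fathmm <- dplyr::mutate(var[, 1:4], fathmm = stats::runif(n))
  cadd <- dplyr::mutate(var[, 1:4], cadd_raw = stats::rnorm(n))
  structure <- dplyr::mutate(
    var[, 1:4],
    remurna_entropy = stats::qexp(stats::pnorm(z), rate = 2),
    mfe_wt = -stats::runif(n, 5, 60),
    mfe_mut = NA_real_,
    rnasnp_dmax = stats::runif(n, 0, 0.4),
    rnasnp_pvalue = stats::runif(n)
  )
  structure$mfe_mut <- structure$mfe_wt + stats::rnorm(n, 0, 1)

  phen_vocab <- c("Hereditary cancer-predisposing syndrome",
                  "Malignant tumor of breast", "Cardiomyopathy",
                  "Familial hypercholesterolemia", "not provided")
  cv_idx <- which(stats::runif(n) < 0.02)
  clinvar <- dplyr::mutate(var[cv_idx, 1:4],
                           phenotype_list = sample(phen_vocab, length(cv_idx),
                                                   replace = TRUE))
  snps <- dplyr::distinct(tibble::tibble(
    chrom = mutations$chrom, pos = mutations$pos,
    ref = g_ref, alt = g_alt
  )[mutations$snp_flag, ])
  list(conservation = conservation, cancer_genes = cancer_genes,
       snps = snps, fathmm = fathmm, cadd = cadd, clinvar = clinvar,
       structure = structure)
}

#' Write / read a COSMIC-like mutation catalog as TSV
#' @param mutations Catalog tibble.
#' @param path File path.
#' @return `read_mutation_table()` returns the tibble.
#' @export
write_mutation_table <- function(mutations, path) {
  readr::write_tsv(mutations, path)
  invisible(path)
}

#' @rdname write_mutation_table
#' @export
read_mutation_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    pos = readr::col_integer(),
                    snp_flag = readr::col_logical(),
                    .default = readr::col_character()
                  ))
}
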