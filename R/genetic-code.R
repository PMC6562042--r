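#' Genetic-code tables
#'
#' Translation tables used throughout the package. `"standard"` is NCBI
#' translation table 1, `"vertebrate_mitochondrial"` is table 2 (where TGA
#' encodes Trp and ATA encodes Met, and AGA/AGG are stops). Tables are taken
#' from Biostrings so codon-to-amino-acid lookups are never hand-maintained.
#'
#' @param code_table `"standard"` or `"vertebrate_mitochondrial"`.
#' @return Named character vector mapping the 64 codons to one-letter amino
#'   acids, with `"*"` for stop codons.
#' @export
genetic_code <- function(code_table = c("standard", "vertebrate_mitochondrial")) {
  code_table <- match.arg(code_table)
  switch(code_table,
    standard = Biostrings::getGeneticCode("1"),
    vertebrate_mitochondrial = Biostrings::getGeneticCode("2")
  )
}

#' Translate codons to amino acids
#'
#' @param codons Character vector of 3-letter DNA codons (ACGT alphabet).
#' @inheritParams genetic_code
#' @return One-letter amino-acid vector (`"*"` for stop).
#' @export
translate_codon <- function(codons, code_table = "standard") {
  gc <- genetic_code(code_table)
  bad <- !codons %in% names(gc)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codons[bad]), collapse = ", "))
  }
  unname(gc[codons])
}

DNA_BASES <- c("A", "C", "G", "T")

#' Complement / reverse-complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

#' Six strand-symmetric substitution classes
#'
#' Collapses the 12 directed single-base changes into the six classes used for
#' mutational-signature work, labelling each class by its pyrimidine-rooted
#' change so that a change and its reverse complement share one class, e.g.
#' `G>A` and `C>T` both map to `"C>T"`.
#'
#' @param ref,alt Character vectors of single bases (coding strand).
#' @return Character vector of class labels among
#'   `"C>A"`, `"C>G"`, `"C>T"`, `"T>A"`, `"T>C"`, `"T>G"`.
#' @export
substitution_class <- function(ref, alt) {
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  ok <- ref %in% DNA_BASES & alt %in% DNA_BASES
  if (!all(ok)) stop("invalid nucleotide in ref/alt")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, complement_base(ref), ref)
  a <- ifelse(flip, complement_base(alt), alt)
  paste0(r, ">", a)
}

#' @rdname substitution_class
#' @format NULL
#' @export
SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Classify the coding consequence of a single-base substitution
#'
#' Re-derives the consequence of a CDS point substitution from the transcript
#' sequence itself, under the transcript's genetic-code table. This is the
#' primitive behind curation: a change is synonymous iff reference and mutant
#' codons translate identically; nonsense iff the mutant codon is a stop and
#' the reference codon is not; loss of a reference stop is labelled `"other"`.
#'
#' @param transcript A single transcript-model row (see [transcript_model()]).
#' @param cds_pos 1-based position within the CDS.
#' @param ref,alt Single coding-strand bases; `ref` must match the CDS.
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`, `"other"`.
#' @export
classify_consequence <- function(transcript, cds_pos, ref, alt) {
  cds <- cds_sequence(transcript)
  n <- nchar(cds)
  if (any(cds_pos < 1L | cds_pos > n)) {
    stop("cds_pos out of range [1, ", n, "]")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  at <- substring(cds, cds_pos, cds_pos)
  if (any(at != ref)) {
    bad <- which(at != ref)[1]
    stop(sprintf(
      "reference mismatch at %s c.%d: expected %s, found %s",
      transcript$transcript_id[1], cds_pos[bad], at[bad], ref[bad]
    ))
  }
  classify_codon_change(cds, cds_pos, alt, transcript$code_table[1])
}

# Vectorized core: consequence of substituting `alt` at cds_pos of `cds`.
classify_codon_change <- function(cds, cds_pos, alt, code_table) {
  codon_idx <- (cds_pos - 1L) %/% 3L
  codon_start <- codon_idx * 3L + 1L
  wt_codon <- substring(cds, codon_start, codon_start + 2L)
  offset <- cds_pos - codon_start  # 0, 1, 2
  mut_codon <- wt_codon
  substring(mut_codon, offset + 1L, offset + 1L) <- alt
  aa_wt <- translate_codon(wt_codon, code_table)
  aa_mut <- translate_codon(mut_codon, code_table)
  dplyr::case_when(
    aa_wt == aa_mut ~ "synonymous",
    aa_mut == "*" ~ "nonsense",
    aa_wt == "*" ~ "other",
    TRUE ~ "missense"
  )
}
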