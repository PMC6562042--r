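#' Mutational signature over the six substitution classes
#'
#' A signature model is a probability distribution over the six
#' strand-symmetric substitution classes (see [substitution_class()]). It is
#' used to normalize recurrence for mutational bias and to drive the
#' substitution mix of the synthetic generator.
#'
#' @param probs Named numeric vector with one probability per class in
#'   `SUBSTITUTION_CLASSES`; must sum to 1.
#' @return Validated named numeric vector (ordered as `SUBSTITUTION_CLASSES`).
#' @export
signature_model <- function(probs) {
  if (!all(SUBSTITUTION_CLASSES %in% names(probs))) {
    stop("signature must name all six classes: ",
         paste(SUBSTITUTION_CLASSES, collapse = ", "))
  }
  p <- probs[SUBSTITUTION_CLASSES]
  if (any(p < 0 | p > 1)) stop("signature probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-8) stop("signature probabilities must sum to 1")
  p
}

#' Default aging-type signature
#'
#' Six-class collapse of the ubiquitous C>T-dominated aging signature
#' (signature 1), the only signature present across all tumor entities; the
#' C>T/G>A class carries about two thirds of the mass, matching the share of
#' C>T/G>A changes observed among somatic synonymous mutations.
#'
#' @return A [signature_model()].
#' @export
default_signature <- function() {
  signature_model(c(
    "C>A" = 0.04, "C>G" = 0.03, "C>T" = 0.67,
    "T>A" = 0.06, "T>C" = 0.15, "T>G" = 0.05
  ))
}

#' Collapse a 96-channel signature to six classes
#'
#' Accepts the conventional trinucleotide channel notation (`"A[C>T]G"`) and
#' sums context channels within each strand-symmetric class.
#'
#' @param channels Tibble/data.frame with columns `channel` (e.g. `"A[C>T]G"`)
#'   and `proportion`.
#' @return A [signature_model()].
#' @export
collapse_signature <- function(channels) {
  cls <- stringr::str_match(channels$channel, "\\[([ACGT]>[ACGT])\\]")[, 2]
  if (anyNA(cls)) stop("unparseable channel notation")
  p <- tapply(channels$proportion, cls, sum)
  p <- p / sum(p)
  signature_model(stats::setNames(as.numeric(p), names(p)))
}

#' Signature probability of a specific base change
#'
#' @param signature A [signature_model()].
#' @param ref,alt Coding-strand bases of the change.
#' @return Class probability p for each change.
#' @export
class_probability <- function(signature, ref, alt) {
  unname(signature[substitution_class(ref, alt)])
}
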