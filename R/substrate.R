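#' EFQO oligonucleotide substrate
#'
#' Describes a single-stranded DNA substrate carrying a 5' fluorophore and a
#' 3' quencher, as used in end-labeled fluorescence-quenched oligonucleotide
#' (EFQO) 5'-exonuclease assays. While the substrate is intact the quencher
#' suppresses fluorophore emission; exonucleolytic release of the terminal
#' 5' nucleotide (with its fluorophore) produces fluorescence.
#'
#' Phosphorothioate (PTO) linkages are recorded as an explicit set of 0-based
#' internucleotide linkage indices (linkage \code{i} joins nucleotides
#' \code{i} and \code{i+1}); no placement is ever inferred from the sequence.
#' \code{pto_rate_factor} is the multiplicative effect of 5'-terminal PTO
#' modification on the hydrolysis rate (1 = unmodified kinetics);
#' \code{five_prime_base_factor} is the rate multiplier associated with the
#' identity of the terminal 5' base.
#'
#' @param sequence character(1), 5'->3' over \code{A,C,G,T}; length >= 2.
#' @param five_prime_label \code{"FAM"} or \code{"none"}.
#' @param three_prime_quencher logical(1): quencher coupled to the terminal
#'   3' nucleotide.
#' @param pto_linkages integer vector of 0-based linkage indices, each
#'   \code{< nchar(sequence) - 1}. Default: the three 3'-terminal linkages of
#'   the standard 30-nt assay substrate.
#' @param pto_rate_factor numeric(1) in (0, 1].
#' @param five_prime_base_factor numeric(1) > 0.
#' @return An object of class \code{oligo_substrate}.
#' @examples
#' oligo_substrate()                       # standard 30-mer, 3'-PTO protected
#' oligo_substrate(pto_linkages = 0:2, pto_rate_factor = 1/500)  # 5'-PTO
#' @export
oligo_substrate <- function(sequence = "ACCATGACGTTCCTGATGCTAAGTATGCAC",
                            five_prime_label = c("FAM", "none"),
                            three_prime_quencher = TRUE,
                            pto_linkages = c(26L, 27L, 28L),
                            pto_rate_factor = 1,
                            five_prime_base_factor = 1) {
  five_prime_label <- match.arg(five_prime_label)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 2L)
    stop("substrate sequence must contain at least 2 nucleotides")
  if (grepl("[^ACGT]", sequence))
    stop("substrate sequence must be over the alphabet {A,C,G,T}")
  pto_linkages <- sort(unique(as.integer(pto_linkages)))
  if (length(pto_linkages) &&
      (any(pto_linkages < 0L) || any(pto_linkages >= nchar(sequence) - 1L)))
    stop("pto_linkages must be 0-based indices < sequence length - 1")
  if (!is.numeric(pto_rate_factor) || pto_rate_factor <= 0 || pto_rate_factor > 1)
    stop("pto_rate_factor must lie in (0, 1]")
  if (!is.numeric(five_prime_base_factor) || five_prime_base_factor <= 0)
    stop("five_prime_base_factor must be > 0")
  structure(
    list(sequence = sequence,
         five_prime_label = five_prime_label,
         three_prime_quencher = isTRUE(three_prime_quencher),
         pto_linkages = pto_linkages,
         pto_rate_factor = as.numeric(pto_rate_factor),
         five_prime_base_factor = as.numeric(five_prime_base_factor)),
    class = "oligo_substrate")
}

#' @export
print.oligo_substrate <- function(x, ...) {
  cat(sprintf("<oligo_substrate> %d nt, 5'-%s, 3' quencher: %s\n",
              nchar(x$sequence), x$five_prime_label,
              if (x$three_prime_quencher) "yes" else "no"))
  cat("  5'-", x$sequence, "-3'\n", sep = "")
  if (length(x$pto_linkages))
    cat("  PTO linkages (0-based):", paste(x$pto_linkages, collapse = ", "), "\n")
  cat(sprintf("  rate factors: PTO %.4g, 5' base %.4g\n",
              x$pto_rate_factor, x$five_prime_base_factor))
  invisible(x)
}

#' Default 5'-terminal base rate factors
#'
#' Relative hydrolysis-rate multipliers by identity of the terminal 5'
#' nucleotide, ordered T > A > G > C. The ordering reflects the observed
#' base preference of the lysosomal 5' exonuclease; the numeric values are
#' generator conventions (no quantitative preference values are established).
#'
#' @return Named numeric vector over \code{c("T","A","G","C")}.
#' @export
five_prime_base_factors <- function() {
  c(T = 1.0, A = 0.8, G = 0.55, C = 0.35)
}
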