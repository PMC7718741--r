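# Internal lookup tables for the universal genetic code.
#
# Everything downstream (rate matrices, likelihoods, simulation) indexes
# codons 1..61 over the sense codons in lexicographic T/C/A/G-free order:
# we use alphabetical ACGT order of the 64 triplets with the three stop
# codons (TAA, TAG, TGA) removed.

.NUC <- c("A", "C", "G", "T")

.all_codons <- function() {
  g <- expand.grid(p3 = .NUC, p2 = .NUC, p1 = .NUC, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.SENSE_CODONS <- setdiff(.all_codons(), .STOP_CODONS)

# amino acid for each sense codon (universal code)
.SENSE_AA <- {
  gc <- Biostrings::GENETIC_CODE
  # GENETIC_CODE is keyed with T already
  unname(gc[.SENSE_CODONS])
}

# 61 x 3 matrix of nucleotide characters
.SENSE_NUC <- do.call(rbind, strsplit(.SENSE_CODONS, ""))

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Pairwise structure of the 61-codon neighbor graph:
#   NEIGHBOR: differ at exactly one position
#   TS:       that difference is a transition
#   NONSYN:   amino acids differ
.codon_pair_tables <- function() {
  n <- length(.SENSE_CODONS)
  ndiff <- matrix(0L, n, n)
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    same <- outer(.SENSE_NUC[, p], .SENSE_NUC[, p], "==")
    ndiff <- ndiff + !same
    ts <- ts | (outer(.SENSE_NUC[, p], .SENSE_NUC[, p], .is_transition) & !same)
  }
  nb <- ndiff == 1L
  list(
    NEIGHBOR = nb,
    TS = ts & nb,
    NONSYN = outer(.SENSE_AA, .SENSE_AA, "!=")
  )
}

.CODON_TABLES <- .codon_pair_tables()

#' Sense codons of the universal genetic code
#'
#' The 61 sense codons (stop codons TAA, TAG, TGA excluded), in the fixed
#' order used by all rate matrices, likelihood vectors and frequency vectors
#' in this package.
#'
#' @return Character vector of length 61.
#' @export
#' @examples
#' head(senseCodons())
senseCodons <- function() .SENSE_CODONS

# Map codon strings (uppercase) to 1..61 indices; NA for anything containing
# a gap or ambiguity, error for stop codons handled by callers.
.codon_index <- function(codons) {
  match(codons, .SENSE_CODONS)
}
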