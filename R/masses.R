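## Monoisotopic mass constants.  Residue masses are the standard values for
## the 20 proteinogenic amino acids; the extra decimals matter because the
## carbamidomethyl-adjusted Cys offsets only reproduce their printed
## 4-decimal values when the arithmetic is carried out at >= 5 decimals.

#' Monoisotopic residue masses
#'
#' Named numeric vector of monoisotopic residue (i.e. water-free) masses in
#' daltons for the 20 standard amino acids.
#'
#' @format Named numeric vector, one entry per single-letter residue code.
#' @keywords internal
AA_MASSES <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

MASS_WATER <- 18.0105646
MASS_PROTON <- 1.00727646688
MASS_O <- 15.994915
MASS_CARBAMIDOMETHYL <- 57.021464
MASS_ACETYL <- 42.010565

#' Validate a peptide sequence
#'
#' Checks that all characters of `sequence` are standard amino-acid letters
#' and stops naming the first offending character otherwise.
#'
#' @param sequence Character scalar, uppercase peptide sequence.
#' @return Invisibly, the character vector of residues.
#' @keywords internal
checkResidues <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(AA_MASSES))
  if (length(bad) > 0L) {
    stop("unknown amino-acid letter '", chars[bad[1L]], "' at position ",
         bad[1L], " of sequence '", sequence, "'", call. = FALSE)
  }
  invisible(chars)
}
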