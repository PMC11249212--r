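## The ten Kidera factors: orthogonal physico-chemical property scores per
## standard amino acid, derived by Kidera and colleagues from a
## dimensionality reduction of 188 physical properties. KF1..KF10 cover,
## among others, helix/bend preference (KF1), side-chain size (KF2),
## extended-structure preference (KF3), hydrophobicity (KF4), double-bend
## preference (KF5), flat extended preference (KF7), alpha-helix-region
## occurrence (KF8) and partial specific volume / pK-related charge terms
## (KF9, KF10). Row = amino acid (one-letter code), column = factor.
.KIDERA <- matrix(c(
  # KF1    KF2    KF3    KF4    KF5    KF6    KF7    KF8    KF9    KF10
  -1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08,  0.21, -0.48, # A
   0.22,  1.27,  1.37,  1.87, -1.70,  0.46,  0.92, -0.39,  0.23,  0.93, # R
   1.14, -0.07, -0.12,  0.81,  0.18,  0.37, -0.09,  1.23,  1.10, -1.73, # N
   0.58, -0.22, -1.58,  0.81, -0.92,  0.15, -1.52,  0.47,  0.76,  0.70, # D
   0.12, -0.89,  0.45, -1.05, -0.71,  2.41,  1.52, -0.69,  1.13,  1.10, # C
  -0.47,  0.24,  0.07,  1.10,  1.10,  0.59,  0.84, -0.71, -0.03, -2.33, # Q
  -1.45,  0.19, -1.61,  1.17, -1.31,  0.40,  0.04,  0.38, -0.35, -0.12, # E
   1.46, -1.96, -0.23, -0.16,  0.10, -0.11,  1.32,  2.36, -1.66,  0.46, # G
  -0.41,  0.52, -0.28,  0.28,  1.61,  1.01, -1.85,  0.47,  1.13,  1.63, # H
  -0.73, -0.16,  1.79, -0.77, -0.54,  0.03, -0.83,  0.51,  0.66, -1.78, # I
  -1.04,  0.00, -0.24, -1.10, -0.55, -2.05,  0.96, -0.76,  0.45,  0.93, # L
  -0.34,  0.82, -0.23,  1.70,  1.54, -1.62,  1.15, -0.08, -0.48,  0.60, # K
  -1.40,  0.18, -0.42, -0.73,  2.00,  1.52,  0.26,  0.11, -1.27,  0.27, # M
  -0.21,  0.98, -0.36, -1.43,  0.22, -0.81,  0.67,  1.10,  1.71, -0.44, # F
   2.06, -0.33, -1.15, -0.75,  0.88, -0.45,  0.30, -2.30,  0.74, -0.28, # P
   0.81, -1.08,  0.16,  0.42, -0.21, -0.43, -1.89, -1.15, -0.97, -0.23, # S
   0.26, -0.70,  1.21,  0.63, -0.10,  0.21,  0.24, -1.15, -0.56,  0.19, # T
   0.30,  2.10, -0.72, -1.57, -1.16,  0.57, -0.48, -0.40, -2.30, -0.60, # W
   1.38,  1.48,  0.80, -0.56,  0.00, -0.68, -0.31,  1.03, -0.05,  0.53, # Y
  -0.74, -0.71,  2.04, -0.40,  0.50, -0.81, -1.07,  0.06, -0.46,  0.65  # V
), nrow = 20L, byrow = TRUE,
  dimnames = list(
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    paste0("KF", 1:10)))

#' Kidera-factor table for the 20 standard amino acids
#'
#' Returns the bundled 20 x 10 matrix of per-residue Kidera factor values
#' (rows: one-letter amino-acid codes, columns: `KF1`..`KF10`).
#'
#' @return numeric matrix, 20 rows x 10 columns.
#' @examples
#' kideraTable()["A", ]
#' @export
kideraTable <- function() .KIDERA

#' Kidera-factor descriptor of a CDR3 amino-acid sequence
#'
#' Summarises the physico-chemical character of a peptide as the arithmetic
#' mean, across its residues, of the ten per-residue Kidera factor values.
#' This is the standard peptide-level aggregation of the Kidera scales and
#' is the CDR3 descriptor used in the feature vectors.
#'
#' @param cdr3Aa single non-empty string over the 20 standard one-letter
#'   amino-acid codes.
#' @return named numeric vector of length 10 (`KF1`..`KF10`).
#' @examples
#' kideraDescriptor("CARDYW")
#' stopifnot(all(kideraDescriptor("AA") == kideraDescriptor("A")))
#' @export
kideraDescriptor <- function(cdr3Aa) {
  if (!is.character(cdr3Aa) || length(cdr3Aa) != 1L || is.na(cdr3Aa) ||
      !nzchar(cdr3Aa))
    .stopf("'cdr3Aa' must be a single non-empty amino-acid string")
  residues <- strsplit(cdr3Aa, "", fixed = TRUE)[[1L]]
  bad <- which(!(residues %in% rownames(.KIDERA)))
  if (length(bad))
    .stopf("non-standard residue '%s' at position %d of '%s'",
           residues[bad[1L]], bad[1L], cdr3Aa)
  colMeans(.KIDERA[residues, , drop = FALSE])
}
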