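# Average residue masses (Da), derived from standard residue elemental
# compositions and IUPAC atomic weights C 12.011, H 1.008, N 14.007,
# O 15.999, S 32.06. Residue = amino acid minus one water.
AVG_RESIDUE_MASS <- c(
  G = 57.052,  A = 71.079,  S = 87.078,  P = 97.117,  V = 99.133,
  T = 101.105, C = 103.139, L = 113.160, I = 113.160, N = 114.104,
  D = 115.088, Q = 128.131, K = 128.175, E = 129.115, M = 131.193,
  H = 137.142, F = 147.177, R = 156.189, Y = 163.176, W = 186.214
)

# Monoisotopic residue masses (Da), for reflector-mode work.
MONO_RESIDUE_MASS <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER      <- 18.015
MASS_WATER_MONO <- 18.010565
MASS_H          <- 1.008
MASS_PROTON     <- 1.007

#' Average (or monoisotopic) mass of a peptide
#'
#' Computes the neutral molecular mass of a linear peptide as the sum of
#' residue masses plus one water, minus `2 * 1.008` Da per disulfide bond
#' (each S-S bond removes two hydrogens). Average masses are the appropriate
#' scale for linear-mode MALDI of ~6 kDa peptides; monoisotopic masses are
#' available via `monoisotopic = TRUE`.
#'
#' @param aa_seq peptide sequence, one-letter codes (no `X`: an unknown
#'   residue has no defined mass).
#' @param n_disulfides number of disulfide bonds formed (0 to
#'   `floor(n_cys / 2)`).
#' @param monoisotopic use monoisotopic residue masses instead of average.
#' @return neutral mass in Da.
#' @examples
#' average_mass("G")                  # 75.07
#' average_mass("ACDEFGHIK", n_disulfides = 0)
#' @export
average_mass <- function(aa_seq, n_disulfides = 0L, monoisotopic = FALSE) {
  check_aa(aa_seq, allow_x = FALSE, what = "peptide")
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1L]]
  tab <- if (monoisotopic) MONO_RESIDUE_MASS else AVG_RESIDUE_MASS
  n_cys <- sum(res == "C")
  n_disulfides <- as.integer(n_disulfides)
  if (n_disulfides < 0L || n_disulfides > n_cys %/% 2L) {
    stop("n_disulfides must be between 0 and floor(n_cys/2) = ",
         n_cys %/% 2L, call. = FALSE)
  }
  water <- if (monoisotopic) MASS_WATER_MONO else MASS_WATER
  sum(tab[res]) + water - 2 * MASS_H * n_disulfides
}
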