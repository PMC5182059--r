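#' Physical constants used throughout the package
#'
#' Monoisotopic residue masses (Da), the mass of water, the proton mass used
#' for charge-state deconvolution and the deuterium-for-hydrogen mass
#' increment.
#'
#' @keywords internal
#' @name hdx-constants
NULL

# monoisotopic amino-acid residue masses, Da
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_WATER <- 18.010565
.MASS_PROTON <- 1.00728
# mass increment per amide hydrogen replaced by deuterium, Da
.MASS_D_INCREMENT <- 1.00628

#' Monoisotopic neutral mass of a peptide
#'
#' @param sequence one-letter amino-acid string.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("GAS")
#' @export
peptide_mass <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(.AA_MONO))
  if (length(bad) > 0) {
    stop("unknown amino-acid code(s): ", paste(unique(bad), collapse = ", "))
  }
  sum(.AA_MONO[aa]) + .MASS_WATER
}
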