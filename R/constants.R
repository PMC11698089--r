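#' Monoisotopic mass constants
#'
#' Standard monoisotopic residue masses (Da) for the 20 amino acids, plus the
#' proton and water masses used throughout the package. Residue masses are the
#' neutral residue (amino acid minus water); a neutral peptide is the residue
#' sum plus one water. Values follow the standard IUPAC/Unimod monoisotopic
#' tables at 1e-5 Da precision.
#'
#' @format `aa_monoisotopic_masses` is a named numeric vector keyed by
#'   one-letter residue code.
#' @name mass_constants
NULL

#' @rdname mass_constants
#' @export
aa_monoisotopic_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname mass_constants
#' @export
proton_mass <- 1.007276

#' @rdname mass_constants
#' @export
water_mass <- 18.010565
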