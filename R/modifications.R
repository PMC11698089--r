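#' Modification specification
#'
#' Describes a fixed or variable mass modification, or the photo-adduct, by
#' name, monoisotopic delta mass, residue targets and multiplicity. Exactly
#' one spec of kind `"adduct"` may be present in an analysis.
#'
#' @param name modification name.
#' @param delta_mass monoisotopic mass shift in Da (finite).
#' @param targets character vector of one-letter residue codes, or `"any"`.
#' @param max_per_peptide maximum occurrences per peptide (>= 0).
#' @param kind `"fixed"`, `"variable"` or `"adduct"`.
#' @return object of class `modification_spec`.
#' @export
modification_spec <- function(name, delta_mass, targets = "any",
                              max_per_peptide = 2L, kind = "variable") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(delta_mass)) stop("delta_mass must be finite")
  kind <- match.arg(kind, c("fixed", "variable", "adduct"))
  max_per_peptide <- as.integer(max_per_peptide)
  if (max_per_peptide < 0L) stop("max_per_peptide must be >= 0")
  structure(list(name = name, delta_mass = delta_mass, targets = targets,
                 max_per_peptide = max_per_peptide, kind = kind),
            class = "modification_spec")
}

#' Default modification table
#'
#' Ships the modifications used by the PAL middle-down workflow:
#' * `AziPm` — the diazirine photo-adduct, nominal +216.08 Da on any residue
#'   (the printed two-decimal value; supply `adduct_delta` to override with a
#'   full-precision mass derived from an elemental composition);
#' * `NEM` — N-ethylmaleimide cysteine alkylation, +125.04768 Da
#'   (C6H7NO2);
#' * `DTT` — dithiothreitol cysteine adduct, +151.99657 Da (C4H8O2S2,
#'   DTT minus H2 via disulfide exchange);
#' * `Oxidation` — methionine oxidation, +15.99491 Da (O).
#'
#' @param adduct_delta photo-adduct delta mass in Da.
#' @return named list of [modification_spec].
#' @export
default_modifications <- function(adduct_delta = 216.08) {
  list(
    AziPm = modification_spec("AziPm", adduct_delta, targets = "any",
                              max_per_peptide = 2L, kind = "adduct"),
    NEM = modification_spec("NEM", 125.04768, targets = "C", kind = "variable"),
    DTT = modification_spec("DTT", 151.99657, targets = "C", kind = "variable"),
    Oxidation = modification_spec("Oxidation", 15.99491, targets = "M",
                                  kind = "variable")
  )
}

#' Retrieve the single adduct spec from a modification table
#' @param mods named list of [modification_spec].
#' @return the [modification_spec] with kind `"adduct"`.
#' @export
adduct_spec <- function(mods) {
  kinds <- vapply(mods, `[[`, character(1), "kind")
  i <- which(kinds == "adduct")
  if (length(i) != 1L) stop("exactly one modification of kind 'adduct' is required")
  mods[[i]]
}
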