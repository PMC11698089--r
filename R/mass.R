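#' Neutral monoisotopic peptide mass
#'
#' Residue masses plus one water, plus any fixed modifications recorded on
#' the peptide, plus `adduct_count` times the adduct delta mass. Deterministic
#' to 1e-6 Da.
#'
#' @param pep a [peptide].
#' @param mods named list of [modification_spec]; must contain every
#'   modification the peptide references and exactly one adduct spec when the
#'   peptide carries adducts.
#' @return neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(pep, mods = default_modifications()) {
  stopifnot(inherits(pep, "peptide"))
  m <- sum(aa_monoisotopic_masses[strsplit(pep$sequence, "")[[1]]]) + water_mass
  if (!is.null(pep$fixed_mods) && nrow(pep$fixed_mods)) {
    for (nm in pep$fixed_mods$name) {
      if (is.null(mods[[nm]]))
        stop(sprintf("unknown modification '%s'", nm))
      m <- m + mods[[nm]]$delta_mass
    }
  }
  if (length(pep$adduct_positions))
    m <- m + length(pep$adduct_positions) * adduct_spec(mods)$delta_mass
  unname(m)
}

#' Mass-to-charge ratio of a protonated species
#'
#' @param neutral_mass neutral monoisotopic mass (Da); vectorized.
#' @param charge positive integer charge state.
#' @return (neutral_mass + charge * proton) / charge.
#' @export
mz <- function(neutral_mass, charge) {
  charge <- as.integer(charge)
  if (any(charge < 1L)) stop("charge must be >= 1")
  (neutral_mass + charge * proton_mass) / charge
}

#' Theoretical b/y fragment ions of a (possibly adduct-bearing) peptide
#'
#' Generates the full b and y series (indices 1..L-1) at the requested charge
#' states. Fragment neutral masses follow the dominant convention: b = residue
#' sum, y = residue sum + water; the singly charged ion adds one proton. Each
#' ion's `adduct_count` is the number of adduct positions falling inside its
#' residue span, and its m/z is shifted by that many adduct delta masses, so a
#' labeled y_n / unlabeled y_{n-1} pair brackets the adducted residue.
#' Fixed modifications recorded on the peptide are applied to the fragments
#' whose spans contain them.
#'
#' @param pep a [peptide].
#' @param adduct_positions protein residue numbers carrying the adduct;
#'   defaults to the peptide's own `adduct_positions`.
#' @param charges integer vector of fragment charge states.
#' @param mods modification table (see [default_modifications()]).
#' @return data.frame with columns `series`, `index`, `charge`,
#'   `adduct_count`, `mz`, `span_start`, `span_end`.
#' @export
fragment_ions <- function(pep, adduct_positions = pep$adduct_positions,
                          charges = 1L, mods = default_modifications()) {
  stopifnot(inherits(pep, "peptide"))
  adduct_positions <- as.integer(adduct_positions)
  if (length(adduct_positions) &&
      any(adduct_positions < pep$start_residue | adduct_positions > pep$end_residue))
    stop("adduct_positions must lie within the peptide span")
  L <- nchar(pep$sequence)
  if (L < 2L) return(data.frame(series = character(0), index = integer(0),
                                charge = integer(0), adduct_count = integer(0),
                                mz = numeric(0), span_start = integer(0),
                                span_end = integer(0)))
  res <- aa_monoisotopic_masses[strsplit(pep$sequence, "")[[1]]]
  # per-position fixed-mod deltas
  fixed <- numeric(L)
  if (!is.null(pep$fixed_mods) && nrow(pep$fixed_mods)) {
    for (r in seq_len(nrow(pep$fixed_mods))) {
      nm <- pep$fixed_mods$name[r]
      if (is.null(mods[[nm]])) stop(sprintf("unknown modification '%s'", nm))
      i <- pep$fixed_mods$position[r] - pep$start_residue + 1L
      fixed[i] <- fixed[i] + mods[[nm]]$delta_mass
    }
  }
  delta <- if (length(adduct_positions)) adduct_spec(mods)$delta_mass else 0
  csum <- cumsum(res + fixed)
  total <- csum[L]
  idx <- seq_len(L - 1L)
  b_neutral <- csum[idx]                       # residue sum, N-terminal
  y_neutral <- total - csum[L - idx] + water_mass
  b_start <- rep(pep$start_residue, L - 1L)
  b_end <- pep$start_residue + idx - 1L
  y_start <- pep$end_residue - idx + 1L
  y_end <- rep(pep$end_residue, L - 1L)
  count_in <- function(a, b) vapply(seq_along(a), function(i)
    sum(adduct_positions >= a[i] & adduct_positions <= b[i]), integer(1))
  b_cnt <- count_in(b_start, b_end)
  y_cnt <- count_in(y_start, y_end)
  out <- do.call(rbind, lapply(as.integer(charges), function(z) {
    data.frame(
      series = rep(c("b", "y"), each = L - 1L),
      index = c(idx, idx),
      charge = z,
      adduct_count = c(b_cnt, y_cnt),
      mz = c(mz(b_neutral + b_cnt * delta, z), mz(y_neutral + y_cnt * delta, z)),
      span_start = c(b_start, y_start),
      span_end = c(b_end, y_end))
  }))
  rownames(out) <- NULL
  out
}

#' Smallest y-ion index whose span contains a residue
#'
#' The first adduct-shifted y ion for a label at `residue_number`: the y_n
#' series covers the C-terminal n residues, so the minimal index containing
#' the residue is `end_residue - residue_number + 1`. Together with the
#' unshifted y_{n-1} this pair is the classic site-defining evidence.
#'
#' @param pep a [peptide].
#' @param residue_number protein residue number within the peptide span.
#' @return integer y-ion index.
#' @export
min_containing_y_index <- function(pep, residue_number) {
  stopifnot(inherits(pep, "peptide"))
  residue_number <- as.integer(residue_number)
  if (residue_number < pep$start_residue || residue_number > pep$end_residue)
    stop("residue outside the peptide span")
  pep$end_residue - residue_number + 1L
}
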