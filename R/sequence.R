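#' Protein sequence with explicit residue numbering
#'
#' Container for a one-letter amino-acid string together with the protein
#' residue number of its first character, so that digest products and
#' fragment ions can be reported in the numbering used by structural and
#' mutagenesis work (e.g. a transmembrane segment excised from a full-length
#' channel keeps its native numbering).
#'
#' @param identifier character scalar naming the sequence.
#' @param residues one-letter amino-acid string (standard 20 letters only).
#' @param numbering_offset residue number of the first character (1-based,
#'   >= 1).
#' @return An object of class `protein_sequence` with fields `identifier`,
#'   `residues`, `numbering_offset`.
#' @export
protein_sequence <- function(identifier, residues, numbering_offset = 1L) {
  stopifnot(is.character(identifier), length(identifier) == 1L,
            is.character(residues), length(residues) == 1L, nchar(residues) >= 1L)
  numbering_offset <- as.integer(numbering_offset)
  if (is.na(numbering_offset) || numbering_offset < 1L)
    stop("numbering_offset must be an integer >= 1")
  letters_vec <- strsplit(residues, "")[[1]]
  bad <- which(!letters_vec %in% names(aa_monoisotopic_masses))
  if (length(bad))
    stop(sprintf("non-standard residue letter '%s' at position %d of '%s'",
                 letters_vec[bad[1]], bad[1], identifier))
  structure(list(identifier = identifier, residues = residues,
                 numbering_offset = numbering_offset),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  last <- x$numbering_offset + nchar(x$residues) - 1L
  cat(sprintf("<protein_sequence> %s  residues %d-%d (%d aa)\n",
              x$identifier, x$numbering_offset, last, nchar(x$residues)))
  invisible(x)
}

#' Digest peptide
#'
#' A proteolytic digest product carrying its protein residue span, missed
#' cleavage count, fixed modifications and photo-adduct positions. Adduct
#' positions are protein residue numbers; at most two adducts are allowed,
#' matching the singly and doubly labeled species reported by PAL-MS.
#'
#' @param sequence one-letter peptide string.
#' @param start_residue,end_residue inclusive protein residue numbers.
#' @param missed_cleavages internal uncleaved sites (>= 0).
#' @param adduct_positions integer vector of labeled residue numbers
#'   (length 0, 1 or 2), each within `[start_residue, end_residue]`.
#' @param fixed_mods optional data.frame with columns `position` (protein
#'   residue number) and `name` (modification name, see
#'   [default_modifications()]).
#' @return An object of class `peptide`.
#' @export
peptide <- function(sequence, start_residue, end_residue = start_residue + nchar(sequence) - 1L,
                    missed_cleavages = 0L, adduct_positions = integer(0),
                    fixed_mods = NULL) {
  start_residue <- as.integer(start_residue); end_residue <- as.integer(end_residue)
  if (end_residue - start_residue + 1L != nchar(sequence))
    stop("residue span does not match sequence length")
  letters_vec <- strsplit(sequence, "")[[1]]
  bad <- which(!letters_vec %in% names(aa_monoisotopic_masses))
  if (length(bad))
    stop(sprintf("non-standard residue letter '%s' at position %d", letters_vec[bad[1]], bad[1]))
  adduct_positions <- sort(as.integer(adduct_positions))
  if (length(adduct_positions) > 2L)
    stop("at most two photo-adducts per peptide are supported")
  if (any(adduct_positions < start_residue | adduct_positions > end_residue))
    stop("adduct_positions must lie within the peptide span")
  if (anyDuplicated(adduct_positions)) stop("duplicated adduct position")
  if (!is.null(fixed_mods)) {
    stopifnot(is.data.frame(fixed_mods), all(c("position", "name") %in% names(fixed_mods)))
    if (any(fixed_mods$position < start_residue | fixed_mods$position > end_residue))
      stop("fixed modification outside the peptide span")
  }
  structure(list(sequence = sequence, start_residue = start_residue,
                 end_residue = end_residue,
                 missed_cleavages = as.integer(missed_cleavages),
                 adduct_positions = adduct_positions, fixed_mods = fixed_mods),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  lab <- if (length(x$adduct_positions))
    paste0("  adducts@", paste(x$adduct_positions, collapse = ",")) else ""
  cat(sprintf("<peptide> %d-%d %s  (%d mc)%s\n", x$start_residue, x$end_residue,
              x$sequence, x$missed_cleavages, lab))
  invisible(x)
}

#' Residue letter at a protein residue number
#' @param pep a [peptide] or [protein_sequence].
#' @param residue_number protein residue number.
#' @return single character.
#' @export
residue_at <- function(pep, residue_number) {
  off <- if (inherits(pep, "peptide")) pep$start_residue else pep$numbering_offset
  seqstr <- if (inherits(pep, "peptide")) pep$sequence else pep$residues
  i <- residue_number - off + 1L
  if (i < 1L || i > nchar(seqstr)) stop("residue number outside span")
  substr(seqstr, i, i)
}

#' In-silico tryptic digestion
#'
#' Fully tryptic digestion: cleavage after K or R except when the following
#' residue is P, allowing up to `max_missed` internal missed cleavages.
#' Products carry protein residue numbering from the input sequence.
#'
#' @param protein a [protein_sequence].
#' @param max_missed maximum internal missed cleavage sites (>= 0); the
#'   default mirrors the permissive middle-down search setting of five.
#' @return list of [peptide] objects sorted by (start_residue, end_residue),
#'   without duplicates.
#' @export
digest <- function(protein, max_missed = 5L) {
  stopifnot(inherits(protein, "protein_sequence"))
  max_missed <- as.integer(max_missed)
  if (is.na(max_missed) || max_missed < 0L) stop("max_missed must be >= 0")
  s <- strsplit(protein$residues, "")[[1]]
  n <- length(s)
  # cut sites: index i means a cut after position i
  cuts <- which(s %in% c("K", "R"))
  cuts <- cuts[cuts == n | s[pmin(cuts + 1L, n)] != "P"]
  # fragment boundaries: 0, cuts..., n
  bounds <- unique(c(0L, cuts, n))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  k <- length(starts)
  out <- list()
  for (i in seq_len(k)) {
    for (j in i:min(k, i + max_missed)) {
      a <- starts[i]; b <- ends[j]
      out[[length(out) + 1L]] <- peptide(
        sequence = paste(s[a:b], collapse = ""),
        start_residue = protein$numbering_offset + a - 1L,
        end_residue = protein$numbering_offset + b - 1L,
        missed_cleavages = j - i)
    }
  }
  ord <- order(vapply(out, `[[`, integer(1), "start_residue"),
               vapply(out, `[[`, integer(1), "end_residue"))
  out[ord]
}

#' Digest products as a data frame
#'
#' Tabulates a digest with neutral monoisotopic mass and m/z at a set of
#' charge states.
#'
#' @param peptides list of [peptide] (e.g. from [digest()]).
#' @param mods modification table, see [default_modifications()].
#' @param charges integer charge states for the m/z columns.
#' @return data.frame with one row per peptide.
#' @export
digest_table <- function(peptides, mods = default_modifications(), charges = 1:5) {
  mass <- vapply(peptides, peptide_mass, numeric(1), mods = mods)
  df <- data.frame(
    sequence = vapply(peptides, `[[`, character(1), "sequence"),
    start_residue = vapply(peptides, `[[`, integer(1), "start_residue"),
    end_residue = vapply(peptides, `[[`, integer(1), "end_residue"),
    missed_cleavages = vapply(peptides, `[[`, integer(1), "missed_cleavages"),
    neutral_mass = mass, stringsAsFactors = FALSE)
  for (z in charges) df[[sprintf("mz_z%d", z)]] <- mz(mass, z)
  df
}
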