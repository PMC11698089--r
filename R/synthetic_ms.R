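#' Bundled fixture protein segments
#'
#' The four tryptic regions of the human HCN1 channel on which the PAL-MS
#' analysis centers — S3 (residues 220-249), S6 (352-404), the CNBD A-helix
#' (469-490) and the CNBD C-helix (582-593) — each as a [protein_sequence]
#' with native hHCN1 residue numbering. Digesting these segments yields the
#' reference peptides (220-241, 220-249, 352-404, 469-490, 582-590, 582-593,
#' 591-593) without requiring any external sequence download.
#'
#' @return named list of [protein_sequence] objects.
#' @export
hcn1_segments <- function() {
  list(
    S3 = protein_sequence("hHCN1_S3", "SWFVVDFISSIPVDYIFLIVEKGMDSEVYK", 220L),
    S6 = protein_sequence("hHCN1_S6",
      "AMSHMLCIGYGAQAPVSMSDLWITMLSMIVGATCYAMFVGHATALIQSLDSSR", 352L),
    Ahelix = protein_sequence("hHCN1_CNBD_A", "LVATMPLFANADPNFVTAMLSK", 469L),
    Chelix = protein_sequence("hHCN1_CNBD_C", "AFETVAIDRLDR", 582L)
  )
}

#' Ground truth for a synthetic LC-MS/MS run
#'
#' Defines exactly what a simulated run contains, so downstream stages can be
#' scored against it: the peptides present, the per-site labeling fractions,
#' per-condition multipliers on those fractions (competition), a retention
#' model in which every adduct delays elution, per-peptide abundances, and
#' the noise model (ppm jitter, intensity CV, decoy peak rate). All
#' randomness is driven by `seed`.
#'
#' @param peptides list of [peptide] objects (unlabeled templates).
#' @param species list (parallel to `peptides`) of lists of labeled species,
#'   each `list(sites = <residue numbers>, fraction = <[0,1]>)`; per peptide
#'   the fractions must sum to <= 1, the remainder being the unlabeled
#'   species.
#' @param condition_scalers named numeric multipliers applied to every
#'   labeling fraction (e.g. `c(control = 1, propofol = 0.05, cAMP = 1)`).
#' @param rt_base numeric retention-time apex (s) per peptide.
#' @param rt_adduct_delay positive delay (s) added per adduct, modelling the
#'   later elution of the hydrophobic labeled species.
#' @param rt_sd Gaussian elution peak width (s).
#' @param abundance per-peptide total abundance (area units).
#' @param charges precursor charge states emitted.
#' @param scan_interval MS1 scan spacing (s).
#' @param ppm_sd mass jitter standard deviation (ppm).
#' @param intensity_cv multiplicative intensity coefficient of variation.
#' @param decoy_rate expected decoy peaks per scan/spectrum (Poisson).
#' @param seed integer RNG seed.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(peptides, species,
                         condition_scalers = c(control = 1),
                         rt_base = 300 + 60 * (seq_along(peptides) - 1),
                         rt_adduct_delay = 30, rt_sd = 6,
                         abundance = rep(1e6, length(peptides)),
                         charges = c(2L, 3L), scan_interval = 2,
                         ppm_sd = 0, intensity_cv = 0, decoy_rate = 0,
                         seed = 1L) {
  stopifnot(is.list(peptides), length(peptides) >= 1L,
            all(vapply(peptides, inherits, logical(1), "peptide")),
            length(species) == length(peptides))
  if (rt_adduct_delay <= 0) stop("rt_adduct_delay must be positive")
  for (i in seq_along(species)) {
    fr <- vapply(species[[i]], `[[`, numeric(1), "fraction")
    if (length(fr) && (any(fr < 0 | fr > 1) || sum(fr) > 1))
      stop("labeling fractions must lie in [0,1] and sum to <= 1 per peptide")
    for (sp in species[[i]]) {
      if (any(sp$sites < peptides[[i]]$start_residue |
              sp$sites > peptides[[i]]$end_residue))
        stop("labeled site outside its peptide span")
    }
  }
  if (is.null(names(condition_scalers))) stop("condition_scalers must be named")
  if (any(condition_scalers < 0)) stop("condition scalers must be >= 0")
  structure(list(peptides = peptides, species = species,
                 condition_scalers = condition_scalers,
                 rt_base = rt_base, rt_adduct_delay = rt_adduct_delay,
                 rt_sd = rt_sd, abundance = abundance,
                 charges = as.integer(charges), scan_interval = scan_interval,
                 ppm_sd = ppm_sd, intensity_cv = intensity_cv,
                 decoy_rate = decoy_rate, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Enumerate the species a ground truth emits under one condition
#'
#' @param truth a [ground_truth].
#' @param condition name in `truth$condition_scalers`.
#' @return data.frame with one row per (peptide, species): sequence, span,
#'   adduct count, sites, fraction, abundance, retention-time center.
#' @export
truth_species_table <- function(truth, condition = "control") {
  if (!condition %in% names(truth$condition_scalers))
    stop(sprintf("unknown condition '%s'", condition))
  scaler <- truth$condition_scalers[[condition]]
  rows <- list()
  for (i in seq_along(truth$peptides)) {
    pep <- truth$peptides[[i]]
    lab <- truth$species[[i]]
    fr <- vapply(lab, `[[`, numeric(1), "fraction") * scaler
    if (any(fr > 1) || sum(fr) > 1)
      stop("condition scaler pushes labeling fractions outside [0,1]")
    f0 <- 1 - sum(fr)
    add <- function(sites, fraction) {
      n <- length(sites)
      rows[[length(rows) + 1L]] <<- data.frame(
        peptide_index = i, sequence = pep$sequence,
        start_residue = pep$start_residue, end_residue = pep$end_residue,
        n_adducts = n,
        sites = paste(sites, collapse = ";"),
        fraction = fraction,
        abundance = truth$abundance[i] * fraction,
        rt_center = truth$rt_base[i] + n * truth$rt_adduct_delay,
        condition = condition, stringsAsFactors = FALSE)
    }
    add(integer(0), f0)
    for (j in seq_along(lab)) add(lab[[j]]$sites, fr[j])
  }
  do.call(rbind, rows)
}

#' Generate a synthetic centroided LC-MS/MS run
#'
#' Emits, for each species in the ground truth, Gaussian elution profiles of
#' centroided MS1 sticks at the adduct-shifted m/z for every configured
#' charge state, and one MS2 spectrum per species containing its full
#' singly charged b/y series (each ion shifted by the adducts its span
#' contains), plus Poisson decoy peaks. Peak areas are analytically equal to
#' species abundances, so efficiency recovery is exactly checkable. The same
#' seed and truth always produce the identical run.
#'
#' @param truth a [ground_truth].
#' @param condition condition name (default `"control"`).
#' @param seed RNG seed; defaults to the truth's own seed.
#' @param mods modification table supplying the adduct mass.
#' @return list with elements `run` (class `annotated_run`: `ms1_scans`,
#'   `ms2_spectra`, `metadata`) and `truth_record` (the species table with
#'   theoretical m/z columns).
#' @export
generate_run <- function(truth, condition = "control", seed = truth$seed,
                         mods = default_modifications()) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(as.integer(seed))
  spt <- truth_species_table(truth, condition)
  delta <- adduct_spec(mods)$delta_mass
  nz <- length(truth$charges)
  # neutral mass per species
  spt$neutral_mass <- NA_real_
  species_sites <- strsplit(spt$sites, ";")
  for (r in seq_len(nrow(spt))) {
    pep <- truth$peptides[[spt$peptide_index[r]]]
    base <- peptide_mass(peptide(pep$sequence, pep$start_residue,
                                 fixed_mods = pep$fixed_mods), mods)
    spt$neutral_mass[r] <- base + spt$n_adducts[r] * delta
  }
  lo <- min(spt$rt_center) - 5 * truth$rt_sd
  hi <- max(spt$rt_center) + 5 * truth$rt_sd
  scan_rts <- seq(lo, hi, by = truth$scan_interval)
  slog <- if (truth$intensity_cv > 0) sqrt(log(1 + truth$intensity_cv^2)) else 0
  theo_mz <- lapply(seq_len(nrow(spt)), function(r)
    mz(spt$neutral_mass[r], truth$charges))
  mz_lo <- min(unlist(theo_mz)) * 0.9
  mz_hi <- max(unlist(theo_mz)) * 1.1
  floor_int <- min(truth$abundance) * 1e-9

  ms1 <- lapply(scan_rts, function(rt) {
    mzv <- numeric(0); inv <- numeric(0)
    for (r in seq_len(nrow(spt))) {
      if (spt$abundance[r] <= 0) next
      dens <- stats::dnorm(rt, spt$rt_center[r], truth$rt_sd)
      base_int <- spt$abundance[r] * dens / nz
      if (base_int < floor_int) next
      for (k in seq_len(nz)) {
        m <- theo_mz[[r]][k]
        if (truth$ppm_sd > 0)
          m <- m * (1 + stats::rnorm(1, 0, truth$ppm_sd) * 1e-6)
        it <- base_int
        if (slog > 0) it <- it * exp(stats::rnorm(1, -slog^2 / 2, slog))
        mzv <- c(mzv, m); inv <- c(inv, it)
      }
    }
    if (truth$decoy_rate > 0) {
      nd <- stats::rpois(1, truth$decoy_rate)
      if (nd > 0) {
        mzv <- c(mzv, stats::runif(nd, mz_lo, mz_hi))
        inv <- c(inv, stats::runif(nd, 0, max(c(inv, 1)) * 0.5))
      }
    }
    o <- order(mzv)
    list(rt = rt, mz = mzv[o], intensity = inv[o])
  })

  ms2 <- list()
  for (r in seq_len(nrow(spt))) {
    if (spt$abundance[r] <= 0) next
    pep <- truth$peptides[[spt$peptide_index[r]]]
    sites <- if (nzchar(spt$sites[r])) as.integer(species_sites[[r]]) else integer(0)
    frag <- fragment_ions(peptide(pep$sequence, pep$start_residue,
                                  fixed_mods = pep$fixed_mods),
                          adduct_positions = sites, charges = 1L, mods = mods)
    fmz <- frag$mz
    if (truth$ppm_sd > 0)
      fmz <- fmz * (1 + stats::rnorm(length(fmz), 0, truth$ppm_sd) * 1e-6)
    fint <- rep(100, length(fmz))
    if (slog > 0) fint <- fint * exp(stats::rnorm(length(fint), -slog^2 / 2, slog))
    if (truth$decoy_rate > 0) {
      nd <- stats::rpois(1, truth$decoy_rate)
      if (nd > 0) {
        fmz <- c(fmz, stats::runif(nd, min(fmz) * 0.9, max(fmz) * 1.1))
        fint <- c(fint, stats::runif(nd, 0, 50))
      }
    }
    o <- order(fmz)
    ms2[[length(ms2) + 1L]] <- list(
      precursor_mz = theo_mz[[r]][1], precursor_charge = truth$charges[1],
      rt = spt$rt_center[r], mz = fmz[o], intensity = fint[o])
  }
  ord <- order(vapply(ms2, `[[`, numeric(1), "rt"))
  ms2 <- ms2[ord]

  for (k in seq_len(nz))
    spt[[sprintf("mz_z%d", truth$charges[k])]] <-
      vapply(theo_mz, `[`, numeric(1), k)

  run <- structure(list(ms1_scans = ms1, ms2_spectra = ms2,
                        metadata = list(schema = "palmap-run/1",
                                        seed = as.integer(seed),
                                        condition = condition,
                                        scan_interval = truth$scan_interval,
                                        charges = truth$charges)),
                   class = "annotated_run")
  list(run = run, truth_record = spt)
}

#' @export
print.annotated_run <- function(x, ...) {
  cat(sprintf("<annotated_run> %d MS1 scans, %d MS2 spectra (condition %s, seed %s)\n",
              length(x$ms1_scans), length(x$ms2_spectra),
              x$metadata$condition, x$metadata$seed))
  invisible(x)
}
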