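#' Extract MS1 features from a centroided run
#'
#' Groups MS1 sticks whose m/z agree within `ppm_group_tol` across adjacent
#' scans into chromatographic features. A feature must span at least
#' `min_scans` scans with no gap larger than `max_scan_gap`; its m/z is the
#' intensity-weighted mean of its sticks, its apex the scan of maximum
#' intensity.
#'
#' @param run an `annotated_run`.
#' @param ppm_group_tol m/z agreement tolerance in ppm.
#' @param min_scans minimum number of scans per feature.
#' @param max_scan_gap largest allowed gap (in scans) within a feature.
#' @return data.frame of features (`mz`, `rt_apex`, `rt_start`, `rt_end`,
#'   `n_scans`, `total_intensity`) with the per-scan trace in the
#'   list-column `trace`.
#' @export
extract_features <- function(run, ppm_group_tol = 10, min_scans = 3L,
                             max_scan_gap = 1L) {
  stopifnot(inherits(run, "annotated_run"))
  empty <- data.frame(mz = numeric(0), rt_apex = numeric(0),
                      rt_start = numeric(0), rt_end = numeric(0),
                      n_scans = integer(0), total_intensity = numeric(0))
  if (!length(run$ms1_scans)) { empty$trace <- list(); return(empty) }
  scan_idx <- rep(seq_along(run$ms1_scans),
                  vapply(run$ms1_scans, function(s) length(s$mz), integer(1)))
  rts <- vapply(run$ms1_scans, `[[`, numeric(1), "rt")
  mzv <- unlist(lapply(run$ms1_scans, `[[`, "mz"))
  inv <- unlist(lapply(run$ms1_scans, `[[`, "intensity"))
  if (!length(mzv)) { empty$trace <- list(); return(empty) }
  o <- order(mzv)
  mzv <- mzv[o]; inv <- inv[o]; scan_idx <- scan_idx[o]
  # greedy m/z clustering: break where the relative gap exceeds the tolerance
  gap_ppm <- c(Inf, diff(mzv) / mzv[-length(mzv)] * 1e6)
  cluster <- cumsum(gap_ppm > ppm_group_tol)
  feats <- list()
  for (cl in split(seq_along(mzv), cluster)) {
    so <- cl[order(scan_idx[cl])]
    sidx <- scan_idx[so]
    runs <- cumsum(c(1L, diff(sidx) > max_scan_gap))
    for (rr in split(so, runs)) {
      if (length(unique(scan_idx[rr])) < min_scans) next
      w <- inv[rr]
      tr <- data.frame(rt = rts[scan_idx[rr]], intensity = w)
      tr <- stats::aggregate(intensity ~ rt, tr, sum)
      feats[[length(feats) + 1L]] <- list(
        mz = sum(mzv[rr] * w) / sum(w),
        rt_apex = tr$rt[which.max(tr$intensity)],
        rt_start = min(tr$rt), rt_end = max(tr$rt),
        n_scans = nrow(tr), total_intensity = sum(w), trace = tr)
    }
  }
  if (!length(feats)) { empty$trace <- list(); return(empty) }
  out <- data.frame(
    mz = vapply(feats, `[[`, numeric(1), "mz"),
    rt_apex = vapply(feats, `[[`, numeric(1), "rt_apex"),
    rt_start = vapply(feats, `[[`, numeric(1), "rt_start"),
    rt_end = vapply(feats, `[[`, numeric(1), "rt_end"),
    n_scans = vapply(feats, `[[`, integer(1), "n_scans"),
    total_intensity = vapply(feats, `[[`, numeric(1), "total_intensity"))
  out$trace <- lapply(feats, `[[`, "trace")
  out[order(out$mz), , drop = FALSE]
}

#' Match peptides (with 0..max adducts) against MS1 features
#'
#' For each peptide and adduct multiplicity n, computes the theoretical m/z
#' at every requested charge and collects features within `tol_ppm`
#' (criterion ii: mass accuracy below 20 ppm of the theoretical m/z).
#' Candidates with n >= 1 are returned, each carrying its matched unlabeled
#' (n = 0) partner when one was found — needed for the retention-delay
#' criterion and for efficiency quantification.
#'
#' @param features data.frame from [extract_features()].
#' @param peptides list of [peptide].
#' @param mods modification table (supplies the adduct delta mass).
#' @param max_adducts maximum adduct multiplicity considered.
#' @param tol_ppm precursor match tolerance (ppm).
#' @param charges charge states searched.
#' @return list of candidate objects (class `labeled_candidate`), each with
#'   `peptide`, `adduct_count`, `matches` (data.frame: charge, mz_theoretical,
#'   mz_observed, ppm_error, rt_apex, total_intensity, feature row index),
#'   `ppm_error` (of the most intense match) and `unlabeled` (same shape, or
#'   NULL).
#' @export
match_peptides <- function(features, peptides, mods = default_modifications(),
                           max_adducts = 2L, tol_ppm = 20, charges = c(2L, 3L)) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  delta <- adduct_spec(mods)$delta_mass
  match_mass <- function(neutral) {
    rows <- list()
    for (z in charges) {
      theo <- mz(neutral, z)
      ppm <- (features$mz - theo) / theo * 1e6
      hit <- which(abs(ppm) <= tol_ppm)
      for (h in hit)
        rows[[length(rows) + 1L]] <- data.frame(
          charge = z, mz_theoretical = theo, mz_observed = features$mz[h],
          ppm_error = ppm[h], rt_apex = features$rt_apex[h],
          total_intensity = features$total_intensity[h], feature = h)
    }
    if (!length(rows)) NULL else do.call(rbind, rows)
  }
  out <- list()
  for (pep in peptides) {
    base <- peptide_mass(pep, mods)
    m0 <- match_mass(base)
    for (n in seq_len(max_adducts)) {
      mn <- match_mass(base + n * delta)
      if (is.null(mn)) next
      best <- which.max(mn$total_intensity)
      out[[length(out) + 1L]] <- structure(
        list(peptide = pep, adduct_count = n, matches = mn,
             ppm_error = mn$ppm_error[best], unlabeled = m0),
        class = "labeled_candidate")
    }
  }
  out
}

#' Apply the predetermined photolabeled-peptide acceptance criteria
#'
#' Sets the four flags a labeled candidate must pass: (i) clearly defined
#' charge states — matched in at least `min_charge_states` charge states;
#' (ii) precursor mass within the ppm tolerance (established at matching
#' time); (iii) retention time delayed relative to the unlabeled partner
#' (the hydrophobic adduct elutes later); (iv) site-defining fragment ions
#' found — merged in from a [localize()] result when supplied. A candidate
#' is accepted only when all four hold; with no unlabeled partner the delay
#' is undetermined and the candidate is not accepted.
#'
#' @param candidate a `labeled_candidate` from [match_peptides()].
#' @param min_rt_delay minimum apex delay in seconds (strictly exceeded).
#' @param min_charge_states minimum number of distinct matched charges.
#' @param localization optional [localize()] result for this candidate.
#' @return the candidate with `criteria` (named logical, NA allowed for an
#'   undetermined delay), `rt_delay` and `accepted` fields set.
#' @export
apply_criteria <- function(candidate, min_rt_delay = 0, min_charge_states = 1L,
                           localization = NULL) {
  stopifnot(inherits(candidate, "labeled_candidate"))
  m <- candidate$matches
  charge_state_defined <- length(unique(m$charge)) >= min_charge_states
  mass_within_tol <- all(is.finite(m$ppm_error))
  if (is.null(candidate$unlabeled)) {
    rt_delay <- NA_real_
    rt_delayed <- NA
  } else {
    lab_apex <- m$rt_apex[which.max(m$total_intensity)]
    un <- candidate$unlabeled
    un_apex <- un$rt_apex[which.max(un$total_intensity)]
    rt_delay <- lab_apex - un_apex
    rt_delayed <- rt_delay > min_rt_delay
  }
  site_ions_found <- if (is.null(localization)) NA else
    isTRUE(nrow(localization$evidence) > 0 &&
             any(localization$evidence$site_determining))
  crit <- c(charge_state_defined = charge_state_defined,
            mass_within_tol = mass_within_tol,
            rt_delayed = rt_delayed,
            site_ions_found = site_ions_found)
  candidate$criteria <- crit
  candidate$rt_delay <- rt_delay
  candidate$accepted <- isTRUE(all(crit))
  candidate
}

#' @export
print.labeled_candidate <- function(x, ...) {
  cat(sprintf("<labeled_candidate> %d-%d +%d adduct(s), %d feature match(es), ppm %.2f\n",
              x$peptide$start_residue, x$peptide$end_residue, x$adduct_count,
              nrow(x$matches), x$ppm_error))
  if (!is.null(x$criteria)) {
    cat("  criteria:", paste(names(x$criteria), unname(x$criteria),
                             sep = "=", collapse = " "),
        sprintf(" accepted=%s\n", x$accepted))
  }
  invisible(x)
}
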