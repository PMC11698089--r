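#' Extracted-ion chromatogram
#'
#' Per MS1 scan within the retention window, sums the intensities of peaks
#' whose m/z lies within `tol_ppm` of the target.
#'
#' @param run an `annotated_run`.
#' @param target_mz target m/z.
#' @param tol_ppm tolerance in ppm (> 0).
#' @param rt_window length-2 numeric window, or NULL for the full run.
#' @return data.frame with columns `rt`, `intensity` (one row per scan in
#'   the window).
#' @export
xic <- function(run, target_mz, tol_ppm = 20, rt_window = NULL) {
  stopifnot(inherits(run, "annotated_run"))
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  tol <- target_mz * tol_ppm * 1e-6
  rows <- lapply(run$ms1_scans, function(s) {
    if (!is.null(rt_window) && (s$rt < rt_window[1] || s$rt > rt_window[2]))
      return(NULL)
    sel <- abs(s$mz - target_mz) <= tol
    data.frame(rt = s$rt, intensity = sum(s$intensity[sel]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame(rt = numeric(0), intensity = numeric(0)))
  do.call(rbind, rows)
}

#' Area under an intensity trace
#'
#' Trapezoidal integral over retention time; traces with fewer than two
#' points have zero area.
#'
#' @param trace data.frame with `rt` (strictly increasing) and `intensity`.
#' @return numeric area.
#' @export
auc <- function(trace) {
  if (nrow(trace) < 2L) return(0)
  if (is.unsorted(trace$rt, strictly = TRUE)) stop("trace must be sorted by rt")
  sum(diff(trace$rt) * (utils::head(trace$intensity, -1) +
                          utils::tail(trace$intensity, -1)) / 2)
}

#' Photolabeling efficiency from XIC areas
#'
#' The labeled-species area divided by the total area of all species of the
#' peptide, times 100; singly and doubly labeled species share the common
#' denominator (unlabeled + singly + doubly), so the two percentages sum to
#' at most 100. Areas should already be summed over the configured charge
#' states, identically for all species.
#'
#' @param auc_unlabeled,auc_singly,auc_doubly non-negative areas.
#' @return named numeric: `singly_percent`, `doubly_percent`.
#' @export
labeling_efficiency <- function(auc_unlabeled, auc_singly, auc_doubly = 0) {
  if (any(c(auc_unlabeled, auc_singly, auc_doubly) < 0))
    stop("areas must be non-negative")
  total <- auc_unlabeled + auc_singly + auc_doubly
  if (total <= 0) stop("total area is zero; efficiency undefined")
  c(singly_percent = 100 * auc_singly / total,
    doubly_percent = 100 * auc_doubly / total)
}

#' Quantify labeling efficiency of a peptide in a run
#'
#' Sums XICs of the unlabeled, singly and doubly labeled species across the
#' configured charge states, integrates each, and applies the shared
#' denominator efficiency formula.
#'
#' @param run an `annotated_run`.
#' @param pep a [peptide] (unlabeled template).
#' @param mods modification table.
#' @param charges charge states summed.
#' @param tol_ppm XIC tolerance in ppm.
#' @return one-row data.frame with areas and `singly_percent`,
#'   `doubly_percent`.
#' @export
quantify_peptide <- function(run, pep, mods = default_modifications(),
                             charges = c(2L, 3L), tol_ppm = 20) {
  base <- peptide_mass(pep, mods)
  delta <- adduct_spec(mods)$delta_mass
  area_of <- function(n) {
    sum(vapply(charges, function(z)
      auc(xic(run, mz(base + n * delta, z), tol_ppm)), numeric(1)))
  }
  a0 <- area_of(0); a1 <- area_of(1); a2 <- area_of(2)
  eff <- labeling_efficiency(a0, a1, a2)
  data.frame(sequence = pep$sequence, start_residue = pep$start_residue,
             end_residue = pep$end_residue,
             auc_unlabeled = a0, auc_singly = a1, auc_doubly = a2,
             singly_percent = eff[["singly_percent"]],
             doubly_percent = eff[["doubly_percent"]])
}

#' Competition (prevention-of-labeling) test across conditions
#'
#' One-way ANOVA of replicate labeling efficiencies across conditions,
#' followed by Dunnett many-to-one comparisons against the control. A
#' condition is flagged as preventing labeling when its Dunnett-adjusted
#' p-value falls below `alpha` and its mean efficiency is below the
#' control's.
#'
#' @param groups named list, one numeric vector of replicate efficiencies
#'   per condition (each with >= 2 replicates).
#' @param control_label name of the control condition in `groups`.
#' @param alpha significance level.
#' @return object of class `competition_result` with `anova_F`, `anova_p`,
#'   `dunnett` (data.frame: condition, estimate, adjusted p, prevented) and
#'   `group_means`.
#' @export
competition_test <- function(groups, control_label = "control", alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least two conditions")
  if (!control_label %in% names(groups))
    stop(sprintf("control condition '%s' not found", control_label))
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L))
    stop("each condition needs >= 2 replicate efficiencies")
  lev <- c(control_label, setdiff(names(groups), control_label))
  df <- data.frame(
    efficiency = unlist(groups, use.names = FALSE),
    condition = factor(rep(names(groups), sizes), levels = lev))
  fit <- stats::aov(efficiency ~ condition, data = df)
  an <- summary(fit)[[1]]
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
  sm <- summary(glht_fit)
  means <- tapply(df$efficiency, df$condition, mean)
  cond <- sub(paste0(" - ", control_label, "$"), "", names(sm$test$coefficients))
  dn <- data.frame(condition = cond,
                   estimate = as.numeric(sm$test$coefficients),
                   p_adjusted = as.numeric(sm$test$pvalues))
  dn$prevented <- dn$p_adjusted < alpha &
    means[dn$condition] < means[[control_label]]
  structure(list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 dunnett = dn, group_means = means, alpha = alpha,
                 control = control_label),
            class = "competition_result")
}

#' @export
print.competition_result <- function(x, ...) {
  cat(sprintf("<competition_result> one-way ANOVA F = %.2f (p = %.3g); Dunnett vs %s:\n",
              x$anova_F, x$anova_p, x$control))
  for (i in seq_len(nrow(x$dunnett)))
    cat(sprintf("  %s: diff %+.2f, adj p = %.3g%s\n", x$dunnett$condition[i],
                x$dunnett$estimate[i], x$dunnett$p_adjusted[i],
                if (x$dunnett$prevented[i]) "  [prevented]" else ""))
  invisible(x)
}
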