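#' Reference labeling fractions by reagent concentration
#'
#' The printed photolabeling efficiencies (percent) of the four reference
#' peptides at 3, 10, 30 and 100 uM reagent, used as generator inputs so a
#' synthetic design reproduces the concentration dependence of labeling:
#' efficiency rises with reagent concentration for every site. `NA` marks
#' species not detected at that concentration.
#'
#' @return data.frame: `peptide` (S3, S6, Ahelix, Chelix), `concentration`
#'   (uM), `singly_percent`, `doubly_percent`.
#' @export
reference_fractions <- function() {
  data.frame(
    peptide = rep(c("S3", "S6", "Ahelix", "Chelix"), each = 4),
    concentration = rep(c(3, 10, 30, 100), times = 4),
    singly_percent = c(3.0, 15.9, 18.0, 18.6,
                       NA, 28.2, NA, NA,
                       1.0, 4.2, 6.9, 18.6,
                       NA, 0.2, 0.6, 0.7),
    doubly_percent = c(NA, 1.1, 2.3, 1.4,
                       NA, NA, NA, NA,
                       NA, NA, NA, NA,
                       NA, NA, NA, NA))
}

#' Ground truth emulating the reference photolabeling design
#'
#' Builds a [ground_truth] over the four reference peptides (S3 220-241
#' labeled at Y234, doubly at I227+Y234; S6 352-404 at C385; CNBD A-helix
#' 469-490 at M487; CNBD C-helix 582-593 at L591) with labeling fractions
#' taken from [reference_fractions()] at the requested reagent
#' concentration. Peptides whose species were not detected at that
#' concentration are included unlabeled.
#'
#' @param concentration reagent concentration in uM (3, 10, 30 or 100).
#' @param condition_scalers named multipliers on the labeling fractions
#'   (competition design); default control plus a propofol condition that
#'   almost abolishes labeling and a cAMP condition that leaves it intact.
#' @param ppm_sd,intensity_cv,decoy_rate noise model, see [ground_truth()].
#' @param rt_adduct_delay labeled-species retention delay (s).
#' @param seed RNG seed.
#' @return a [ground_truth].
#' @export
reference_truth <- function(concentration = 10,
                            condition_scalers = c(control = 1,
                                                  propofol = 0.05,
                                                  cAMP = 1.0),
                            ppm_sd = 5, intensity_cv = 0.02,
                            decoy_rate = 1, rt_adduct_delay = 30,
                            seed = 1L) {
  fr <- reference_fractions()
  fr <- fr[fr$concentration == concentration, ]
  if (!nrow(fr)) stop("concentration must be one of 3, 10, 30, 100")
  segs <- hcn1_segments()
  peps <- list(
    S3 = peptide("SWFVVDFISSIPVDYIFLIVEK", 220L),
    S6 = peptide(segs$S6$residues, 352L),
    Ahelix = peptide(segs$Ahelix$residues, 469L),
    Chelix = peptide(segs$Chelix$residues, 582L))
  sites <- list(S3 = 234L, S6 = 385L, Ahelix = 487L, Chelix = 591L)
  species <- lapply(names(peps), function(nm) {
    row <- fr[fr$peptide == nm, ]
    out <- list()
    if (is.finite(row$singly_percent))
      out[[length(out) + 1L]] <- list(sites = sites[[nm]],
                                      fraction = row$singly_percent / 100)
    if (is.finite(row$doubly_percent))
      out[[length(out) + 1L]] <- list(sites = c(227L, 234L),
                                      fraction = row$doubly_percent / 100)
    out
  })
  ground_truth(peptides = unname(peps), species = species,
               condition_scalers = condition_scalers,
               rt_adduct_delay = rt_adduct_delay,
               ppm_sd = ppm_sd, intensity_cv = intensity_cv,
               decoy_rate = decoy_rate, seed = seed)
}

#' Pipeline configuration
#'
#' Collects the tolerances, charge states, criteria thresholds and design
#' parameters shared by the pipeline stages.
#'
#' @param truth a [ground_truth] describing the synthetic design (or NULL
#'   when running on externally supplied runs).
#' @param mods modification table.
#' @param max_missed tryptic missed cleavages for the digest stage.
#' @param precursor_tol_ppm precursor match tolerance (ppm).
#' @param frag_tol,frag_tol_unit fragment match tolerance.
#' @param charges precursor charge states searched and quantified.
#' @param min_rt_delay,min_charge_states criteria thresholds, see
#'   [apply_criteria()].
#' @param replicates replicate runs per condition.
#' @param alpha significance level for the competition test.
#' @param seed base RNG seed; replicate r of condition c uses
#'   `seed + 1000 * condition_index + r`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(truth = reference_truth(), mods = default_modifications(),
                            max_missed = 5L, precursor_tol_ppm = 20,
                            frag_tol = 20, frag_tol_unit = "ppm",
                            charges = c(2L, 3L), min_rt_delay = 0,
                            min_charge_states = 1L, replicates = 3L,
                            alpha = 0.05, seed = 1L) {
  if (precursor_tol_ppm <= 0 || frag_tol <= 0) stop("tolerances must be positive")
  structure(list(truth = truth, mods = mods, max_missed = as.integer(max_missed),
                 precursor_tol_ppm = precursor_tol_ppm, frag_tol = frag_tol,
                 frag_tol_unit = frag_tol_unit, charges = as.integer(charges),
                 min_rt_delay = min_rt_delay,
                 min_charge_states = as.integer(min_charge_states),
                 replicates = as.integer(replicates), alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML file of scalar settings (and an optional reference-design
#' block with `concentration`, `condition_scalers`, noise fields) onto
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  truth_args <- y$design
  truth <- if (is.null(truth_args)) reference_truth() else
    do.call(reference_truth, c(
      truth_args[setdiff(names(truth_args), "condition_scalers")],
      if (!is.null(truth_args$condition_scalers))
        list(condition_scalers = unlist(truth_args$condition_scalers))))
  keep <- intersect(names(y), names(formals(pipeline_config)))
  do.call(pipeline_config, c(list(truth = truth), y[setdiff(keep, c("truth"))]))
}

# plain 31-bit polynomial checksum of a string; provenance fingerprint only
config_checksum <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Search one run for labeled peptides and localize adduct sites
#'
#' The per-run core: feature extraction, adduct-shifted m/z matching,
#' MS2-based site localization, and the four acceptance criteria.
#'
#' @param run an `annotated_run`.
#' @param peptides digest peptides to search.
#' @param config a `pipeline_config`.
#' @return list: `candidates` (list of criteria-annotated
#'   `labeled_candidate`s with a `localization` field), `features`.
#' @export
search_run <- function(run, peptides, config = pipeline_config()) {
  features <- extract_features(run, ppm_group_tol = config$precursor_tol_ppm / 2)
  candidates <- match_peptides(features, peptides, mods = config$mods,
                               tol_ppm = config$precursor_tol_ppm,
                               charges = config$charges)
  ms2_mz <- vapply(run$ms2_spectra, `[[`, numeric(1), "precursor_mz")
  ms2_rt <- vapply(run$ms2_spectra, `[[`, numeric(1), "rt")
  delta <- adduct_spec(config$mods)$delta_mass
  out <- lapply(candidates, function(cand) {
    loc <- NULL
    theo <- mz(peptide_mass(cand$peptide, config$mods) +
                 cand$adduct_count * delta, config$charges[1])
    hit <- which(abs(ms2_mz - theo) / theo * 1e6 <= config$precursor_tol_ppm)
    if (length(hit)) {
      apex <- cand$matches$rt_apex[which.max(cand$matches$total_intensity)]
      sp <- run$ms2_spectra[[hit[which.min(abs(ms2_rt[hit] - apex))]]]
      loc <- localize(sp, cand$peptide, n_adducts = cand$adduct_count,
                      frag_tol = config$frag_tol,
                      tol_unit = config$frag_tol_unit, mods = config$mods)
    }
    cand <- apply_criteria(cand, min_rt_delay = config$min_rt_delay,
                           min_charge_states = config$min_charge_states,
                           localization = loc)
    cand$localization <- loc
    cand
  })
  list(candidates = out, features = features)
}

#' Run the full synthetic PAL-MS pipeline
#'
#' Executes simulate -> digest -> search -> localize -> quantify -> compete
#' on the configured synthetic design: for every condition and replicate a
#' run is generated (seeded deterministically from the base seed), searched
#' against the digest of the fixture segments, adduct sites are localized,
#' labeling efficiencies quantified, and a Dunnett competition test run per
#' peptide across conditions. Identical configuration and seed reproduce the
#' result bundle exactly.
#'
#' @param config a `pipeline_config` with a non-NULL `truth`.
#' @param outdir optional directory; when given, tabular results and a
#'   provenance block (seed, config JSON, checksum) are written as CSV/JSON.
#' @return list of class `pipeline_result`: `candidates` (data.frame),
#'   `localizations` (data.frame), `efficiencies` (data.frame),
#'   `competition` (list of [competition_test()] results per peptide),
#'   `report` (peptide x condition mean efficiencies), `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- config$truth
  if (is.null(truth)) stop("run_pipeline needs a configured synthetic design")
  peptides <- truth$peptides
  conditions <- names(truth$condition_scalers)
  cand_rows <- list(); loc_rows <- list(); eff_rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    for (r in seq_len(config$replicates)) {
      run_seed <- config$seed + 1000L * ci + r
      gen <- generate_run(truth, condition = cond, seed = run_seed,
                          mods = config$mods)
      sr <- search_run(gen$run, peptides, config)
      for (cand in sr$candidates) {
        sites <- if (!is.null(cand$localization))
          paste(vapply(cand$localization$best_sites, paste, character(1),
                       collapse = "+"), collapse = "|") else ""
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          condition = cond, replicate = r,
          start_residue = cand$peptide$start_residue,
          end_residue = cand$peptide$end_residue,
          n_adducts = cand$adduct_count,
          n_charges = length(unique(cand$matches$charge)),
          ppm_error = cand$ppm_error, rt_delay = cand$rt_delay,
          charge_state_defined = cand$criteria[["charge_state_defined"]],
          mass_within_tol = cand$criteria[["mass_within_tol"]],
          rt_delayed = cand$criteria[["rt_delayed"]],
          site_ions_found = cand$criteria[["site_ions_found"]],
          accepted = cand$accepted, best_sites = sites)
        if (!is.null(cand$localization)) {
          loc <- cand$localization
          loc_rows[[length(loc_rows) + 1L]] <- data.frame(
            condition = cond, replicate = r,
            start_residue = cand$peptide$start_residue,
            end_residue = cand$peptide$end_residue,
            n_adducts = cand$adduct_count, best_sites = sites,
            ambiguity_set = paste(loc$ambiguity_set, collapse = ";"),
            score = loc$score, n_evidence = nrow(loc$evidence))
        }
      }
      for (pep in peptides) {
        q <- quantify_peptide(gen$run, pep, mods = config$mods,
                              charges = config$charges,
                              tol_ppm = config$precursor_tol_ppm)
        q$condition <- cond; q$replicate <- r
        eff_rows[[length(eff_rows) + 1L]] <- q
      }
    }
  }
  candidates <- do.call(rbind, cand_rows)
  localizations <- if (length(loc_rows)) do.call(rbind, loc_rows) else NULL
  efficiencies <- do.call(rbind, eff_rows)
  competition <- list()
  if (config$replicates >= 2L && length(conditions) >= 2L) {
    for (pep in peptides) {
      sub <- efficiencies[efficiencies$start_residue == pep$start_residue &
                            efficiencies$end_residue == pep$end_residue, ]
      groups <- split(sub$singly_percent, sub$condition)[conditions]
      key <- sprintf("%d-%d", pep$start_residue, pep$end_residue)
      competition[[key]] <- tryCatch(
        competition_test(groups, control_label = conditions[1],
                         alpha = config$alpha),
        error = function(e) e)
    }
  }
  agg <- stats::aggregate(cbind(singly_percent, doubly_percent) ~
                            start_residue + end_residue + condition,
                          efficiencies, mean)
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), c("truth", "mods"))],
                               auto_unbox = TRUE, digits = NA, force = TRUE)
  provenance <- list(seed = config$seed, config = as.character(cfg_json),
                     config_checksum = config_checksum(as.character(cfg_json)),
                     conditions = conditions, replicates = config$replicates)
  res <- structure(list(candidates = candidates, localizations = localizations,
                        efficiencies = efficiencies, competition = competition,
                        report = agg[order(agg$start_residue, agg$condition), ],
                        provenance = provenance),
                   class = "pipeline_result")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(candidates, file.path(outdir, "candidates.csv"),
                     row.names = FALSE)
    if (!is.null(localizations))
      utils::write.csv(localizations, file.path(outdir, "localizations.csv"),
                       row.names = FALSE)
    utils::write.csv(efficiencies, file.path(outdir, "efficiencies.csv"),
                     row.names = FALSE)
    utils::write.csv(res$report, file.path(outdir, "report.csv"),
                     row.names = FALSE)
    if (length(competition)) {
      comp_rows <- list()
      for (key in names(competition)) {
        cr <- competition[[key]]
        if (inherits(cr, "error")) next
        d <- cr$dunnett; d$peptide <- key; d$anova_F <- cr$anova_F
        comp_rows[[length(comp_rows) + 1L]] <- d
      }
      if (length(comp_rows))
        utils::write.csv(do.call(rbind, comp_rows),
                         file.path(outdir, "competition.csv"), row.names = FALSE)
    }
    jsonlite::write_json(provenance, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d candidate rows, %d efficiency rows, %d competition tests (seed %d)\n",
              nrow(x$candidates), nrow(x$efficiencies), length(x$competition),
              x$provenance$seed))
  invisible(x)
}
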