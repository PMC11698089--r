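#!/usr/bin/env Rscript
# Quantify labeling efficiency across the reagent-concentration series and
# test prevention of labeling (competition) at 10 uM with a 3-replicate
# control / propofol / cAMP design.

suppressPackageStartupMessages(library(palmap))
seed <- 20240801L

message("-- concentration series: mean efficiency per peptide (control) --")
series <- list()
for (conc in c(3, 10, 30, 100)) {
  truth <- reference_truth(concentration = conc,
                           condition_scalers = c(control = 1), seed = seed)
  cfg <- pipeline_config(truth = truth, replicates = 1L, seed = seed + conc)
  res <- run_pipeline(cfg)
  rep_tab <- res$report
  rep_tab$concentration_uM <- conc
  series[[length(series) + 1L]] <- rep_tab
}
series <- do.call(rbind, series)
series <- series[order(series$start_residue, series$concentration_uM),
                 c("start_residue", "end_residue", "concentration_uM",
                   "singly_percent", "doubly_percent")]
write.csv(series, "results/efficiency_series.csv", row.names = FALSE)
for (i in seq_len(nrow(series)))
  message(sprintf("  %d-%d @ %3g uM: singly %5.2f%%  doubly %4.2f%%",
                  series$start_residue[i], series$end_residue[i],
                  series$concentration_uM[i], series$singly_percent[i],
                  series$doubly_percent[i]))

message("-- competition design at 10 uM (control / +propofol / +cAMP) --")
truth <- reference_truth(concentration = 10, seed = seed)
cfg <- pipeline_config(truth = truth, replicates = 3L, seed = seed)
res <- run_pipeline(cfg, outdir = "results/competition_10uM")
for (key in names(res$competition)) {
  cr <- res$competition[[key]]
  if (inherits(cr, "error")) next
  dn <- cr$dunnett
  message(sprintf("  peptide %s: one-way ANOVA F = %.2f", key, cr$anova_F))
  for (j in seq_len(nrow(dn)))
    message(sprintf("    vs %-9s adj p = %.4g %s", dn$condition[j],
                    dn$p_adjusted[j],
                    if (dn$prevented[j]) "[prevented]" else ""))
}
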