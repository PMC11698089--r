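#!/usr/bin/env Rscript
# Simulate the study's three kinds of raw data with known ground truth:
# an LC-MS/MS run of the reference photolabeling design (10 uM reagent),
# tail-current G-V tables with a drug-shifted Boltzmann, and a dwell-model
# ligand trajectory. Everything downstream (02-05) consumes these files.

suppressPackageStartupMessages(library(palmap))
dir.create("results", showWarnings = FALSE)
seed <- 20240801L

message("-- synthetic LC-MS/MS run (10 uM design, control condition) --")
truth <- reference_truth(concentration = 10, seed = seed)
gen <- generate_run(truth, condition = "control")
write_run_jsonl(gen$run, "results/run_control_10uM.jsonl")
write.csv(gen$truth_record, "results/run_control_10uM_truth.csv",
          row.names = FALSE)
message(sprintf("  %d MS1 scans, %d MS2 spectra, %d species (seed %d)",
                length(gen$run$ms1_scans), length(gen$run$ms2_spectra),
                nrow(gen$truth_record), seed))

message("-- synthetic G-V dataset (20 mV hyperpolarizing shift at 10 uM) --")
gv <- generate_gv_dataset(v_half = -90, k = 8,
                          shifts = c(propofol_10uM = -20, propofol_100uM = -40),
                          noise_sd = 0.02, voltages = seq(-20, -140, by = -10),
                          n_replicates = 5, seed = seed)
write.csv(gv, "results/gv_dataset.csv", row.names = FALSE)
message(sprintf("  %d recordings across %d conditions", nrow(gv),
                length(unique(gv$condition))))

message("-- synthetic ligand-residue trajectory (dwell model) --")
traj <- generate_trajectory(dwell_bound = 47L, dwell_unbound = 53L,
                            n_frames = 1000L, seed = seed)
write_xyz_frames(traj$trajectory, "results/trajectory.xyz")
message(sprintf("  1000 frames; analytic dual-cutoff occupancy %.3f",
                traj$analytic_occupancy))
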