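#!/usr/bin/env Rscript
# Dual-cutoff contact occupancy and time-averaged ligand density on the
# simulated trajectory.

suppressPackageStartupMessages(library(palmap))

traj <- read_xyz_frames("results/trajectory.xyz")
d <- min_distance_series(traj, "LIG", "RES")
occ <- dual_cutoff_occupancy(d, lower = 2.5, upper = 3.5)
message(sprintf("-- dual-cutoff occupancy (2.5 / 3.5 A): %.3f over %d frames --",
                occ$occupancy, length(d)))
message(sprintf("  %d bound intervals; first interval frames [%d, %d)",
                nrow(occ$intervals), occ$intervals$start[1],
                occ$intervals$end[1]))
write.csv(data.frame(frame = seq_along(d), min_distance = d,
                     bound = occ$bound),
          "results/occupancy_frames.csv", row.names = FALSE)

grid <- density_grid(traj, "LIG", voxel = 1.0)
write_dx(grid, "results/ligand_density.dx")
message(sprintf("  density grid %s voxels, total mass %.3f atoms/frame -> results/ligand_density.dx",
                paste(dim(grid$counts), collapse = "x"), sum(grid$counts)))
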