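#!/usr/bin/env Rscript
# Stage 4: score steric accessibility of nucleophilic attack in the two
# simulated trajectories — per-frame distance/theta/phi, reactive-frame
# extraction (d <= 4 A, theta in [150, 180]), phi histogram, and the
# optimal-phi fraction (phi in [100, 180]).
# Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(rssmet))
data_dir <- "results/data"
out <- "results"

summaries <- list()
for (nm in c("unhindered", "hindered")) {
  tr <- read_xyz(file.path(data_dir, paste0("traj_", nm, ".xyz")))
  geom <- trajectory_geometry(tr, atom_map(1, 2, 3, 4, ligand_kind = nm))
  s <- steric_summary(geom)
  cat(sprintf("%-10s: %d/%d frames reaction-competent; optimal-phi fraction %.1f%%\n",
              nm, s$n_extracted, s$n_frames_total, s$optimal_fraction))
  utils::write.csv(s$phi_histogram,
                   file.path(out, paste0("phi_histogram_", nm, ".csv")),
                   row.names = FALSE)
  summaries[[nm]] <- list(n_frames_total = s$n_frames_total,
                          n_extracted = s$n_extracted,
                          n_optimal = s$n_optimal,
                          optimal_fraction = s$optimal_fraction)
}

cat("Contrast: the unhindered (persulfide-like) geometry should exceed 75%\n")
cat("and the hindered (methylselenide-like) geometry fall below 25%.\n")

write_result_json(result_envelope(
  "geometry",
  parameters = list(d_max = 4, theta_range = c(150, 180),
                    phi_range = c(100, 180)),
  payload = summaries,
  input_paths = file.path(data_dir, paste0("traj_",
                                           c("unhindered", "hindered"), ".xyz"))),
  file.path(out, "geometry.json"))
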