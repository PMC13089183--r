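#!/usr/bin/env Rscript
# Stage 1: generate the three synthetic input families with known ground
# truth — kinetic initial-rate tables, a planted-cluster PIE matrix, and
# attack-geometry trajectories — and write them under results/data/.

suppressPackageStartupMessages(library(rssmet))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260927L

# Kinetics: the assay design (0, 20, 200, 2000 uM; 3 replicates) with the
# published disulfide parameters and 5%-of-Vmax additive noise.
design <- kinetic_design(c(0, 20, 200, 2000), n_rep = 3,
                         noise_sd = 0.05 * 260, seed = seed)
kin <- gen_mm_rates(mm_truth(331, 260), design, condition = "Na2S2")
write_kinetic_csv(kin, file.path(out, "kinetics_na2s2.csv"))

# Dual-substrate data: persulfide branch (209, 392), H2S branch (1978, 5.37),
# planted breakpoint C1 = 50 uM, on a dense design for the breakpoint fit.
dual_design <- kinetic_design(seq(0, 2000, by = 20), n_rep = 1,
                              noise_sd = 0.05 * 5.37, seed = seed + 1L)
dual <- gen_dual_mm_rates(mm_truth(209, 392), mm_truth(1978, 5.37), 50,
                          dual_design, condition = "Na2S+GSH")
write_kinetic_csv(dual, file.path(out, "kinetics_dual.csv"))

# PIE matrix: 4 planted strong clusters (equal total, distinct shapes) and
# 2 weaker ones, 20 conformations each, 12 fragments.
profiles <- lapply(1:6, function(i) {
  total <- if (i <= 4) -260 else -120
  w <- ((1:12 + 3L * i) %% 12L) + 1L
  total * w / sum(w)
})
spec <- pie_cluster_spec(profiles, rep(20L, 6), within_sd = 2, seed = seed + 2L)
pie <- gen_pie_matrix(spec)
write_pie_tsv(pie$matrix, file.path(out, "pie.tsv"))
writeLines(as.character(pie$true_labels), file.path(out, "pie_true_labels.txt"))

# Trajectories: unhindered (phi ~ N(135, 15)) and hindered (phi ~ N(75, 15))
# attack geometry, matched distance/alignment distributions.
phi_centers <- c(unhindered = 135, hindered = 75)
for (nm in names(phi_centers)) {
  tr <- gen_trajectory(geom_spec(2000L,
    d_dist = list(dist = "normal", mean = 3.6, sd = 0.3),
    theta_dist = list(dist = "normal", mean = 165, sd = 10),
    phi_dist = list(dist = "normal", mean = phi_centers[[nm]], sd = 15),
    seed = seed + 3L + match(nm, names(phi_centers))))
  write_xyz(tr, file.path(out, paste0("traj_", nm, ".xyz")))
}

cat("Wrote synthetic inputs to", out, "\n")
cat(" - kinetics_na2s2.csv:", nrow(kin), "rows; truth Km 331, Vmax 260\n")
cat(" - kinetics_dual.csv:", nrow(dual), "rows; planted C1 = 50 uM\n")
cat(" - pie.tsv:", nrow(pie$matrix), "conformations x 12 fragments; 4 strong + 2 weak clusters\n")
cat(" - traj_{unhindered,hindered}.xyz: 2000 frames each\n")
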