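#!/usr/bin/env Rscript
# Generate the synthetic study datasets used by the downstream analyses:
# a repression (occlusion) allelic series, two class I activation series
# with different cooperativities, an acceleration series with saturated
# points, and a seven-concentration effector titration. Each table is
# written as CSV with a ground-truth JSON sidecar so that every later
# estimate can be compared with what generated the data.

suppressPackageStartupMessages(library(allelic))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

write_truth <- function(truth, path) {
  truth$P_by_promoter <- as.list(truth$P_by_promoter)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = I(12),
                       pretty = TRUE)
}

# occlusion architecture: 41 promoters, 2 of them outliers, as a
# realistic desk-scale replica of a repression measurement campaign
rep_sim <- simulate_allelic_series(41, "repression", noise_cv = 0.1,
                                   outlier_fraction = 0.05, seed = 101,
                                   architecture = "occlusion+0.5")
write_measurements(rep_sim$data, file.path(out_dir, "repression.csv"))
write_truth(rep_sim$truth, file.path(out_dir, "repression_truth.json"))

# two class I architectures sharing tsat but differing in cooperativity
for (cfg in list(list(alpha = 712, name = "classI-61.5"),
                 list(alpha = 30, name = "classI-60.5"))) {
  sim <- simulate_allelic_series(30, "stabilization", alpha = cfg$alpha,
                                 noise_cv = 0.1, P_range = c(1e-4, 10),
                                 seed = 200 + cfg$alpha,
                                 architecture = cfg$name)
  write_measurements(sim$data,
                     file.path(out_dir, paste0(cfg$name, ".csv")))
  write_truth(sim$truth,
              file.path(out_dir, paste0(cfg$name, "_truth.json")))
}

# acceleration series with doubly-saturated coverage (P up to 100)
acc_sim <- simulate_allelic_series(24, "acceleration", alpha = 712,
                                   beta = 3, noise_cv = 0.1,
                                   P_range = c(1e-4, 100), seed = 301,
                                   architecture = "classII-41.5-like")
write_measurements(acc_sim$data, file.path(out_dir, "acceleration.csv"))
write_truth(acc_sim$truth, file.path(out_dir, "acceleration_truth.json"))

# cAMP-style titration: F ~ c^1.41 over 2.5-250 uM
tit <- simulate_titration(n_promoters = 20, exponent = 1.41,
                          noise_cv = 0.1, seed = 401)
for (nm in names(tit$datasets)) {
  write_measurements(tit$datasets[[nm]],
                     file.path(out_dir, paste0("titration_", nm, ".csv")))
}
tit$truth$F_by_conc <- as.list(tit$truth$F_by_conc)
jsonlite::write_json(tit$truth, file.path(out_dir, "titration_truth.json"),
                     auto_unbox = TRUE, digits = I(12), pretty = TRUE)

cat("simulated datasets written under", out_dir, "\n")
cat(sprintf("  repression: %d promoters (%d injected outliers)\n",
            nrow(rep_sim$data), length(rep_sim$truth$outlier_ids)))
cat(sprintf("  titration: %d concentrations x %d promoters\n",
            length(tit$datasets), 20))
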