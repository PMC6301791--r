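#!/usr/bin/env Rscript
# Effector titration: infer the TF binding factor F at each concentration
# (tsat and tbg held at previously determined values) and summarize the
# power-law dependence of F on concentration by log-log regression over
# the four largest concentrations.

suppressPackageStartupMessages(library(allelic))

truth <- jsonlite::fromJSON("results/data/titration_truth.json")
files <- sort(list.files("results/data", pattern = "^titration_.*\\.csv$",
                         full.names = TRUE))
datasets <- lapply(files, read_measurements)
names(datasets) <- vapply(datasets, function(d) unique(d$condition), "")

tf <- titration_fit(datasets, tsat = truth$tsat, tbg = truth$tbg,
                    n_boot = 50, seed = 3)
print(tf)

utils::write.csv(tf$table, "results/titration_F.csv", row.names = FALSE)
jsonlite::write_json(
  list(exponent = tf$exponent, exponent_ci95 = tf$exponent_ci95,
       truth_exponent = truth$exponent),
  "results/titration_exponent.json", auto_unbox = TRUE, digits = I(12))

cat(sprintf("\nF ~ [cAMP]^%.2f  (95%% CI %.2f-%.2f; truth %.2f)\n",
            tf$exponent, tf$exponent_ci95[1], tf$exponent_ci95[2],
            truth$exponent))
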