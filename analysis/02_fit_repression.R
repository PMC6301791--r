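#!/usr/bin/env Rscript
# Fit the occlusion (repression) allelic manifold: flag outliers against a
# robust preliminary fit, refit on the survivors, and quantify uncertainty
# in the TF-DNA binding factor F (and dG_F) by bootstrap resampling of
# promoters.

suppressPackageStartupMessages(library(allelic))

data <- read_measurements("results/data/repression.csv")
truth <- jsonlite::fromJSON("results/data/repression_truth.json")

flagged <- detect_outliers(data, "repression", seed = 1)
cat(sprintf("flagged %d of %d promoters as outliers: %s\n",
            sum(flagged$is_outlier), nrow(flagged),
            paste(flagged$promoter_id[flagged$is_outlier],
                  collapse = ", ")))
cat("injected outliers were:",
    paste(truth$outlier_ids, collapse = ", "), "\n")

bs <- bootstrap_manifold(flagged, "repression", n_boot = 100, seed = 1)
print(bs)

dir.create("results", showWarnings = FALSE)
write_fit_json(bs$point, "results/fit_repression.json", boot = bs)
utils::write.csv(bs$draws, "results/fit_repression_bootstrap.csv",
                 row.names = FALSE)

cat(sprintf("\ndG_F = %.2f kcal/mol  [68%% CI %.2f, %.2f]  (truth %.2f)\n",
            bs$point$dg$dg_F, bs$ci68$dg_F[1], bs$ci68$dg_F[2],
            dg_from_factor(truth$F)))
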