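#!/usr/bin/env Rscript

# Step 4 — validate the whole pipeline on synthetic ground truth.
#
# Generates a noise-free dose-response experiment from the mechanistic
# surface (calibrated to the study's per-chemical response ranges), fits
# the network, optimizes on the *fitted* model, and scores the recommended
# protocol on the *true* surface. The pipeline should find a protocol that
# disinfects nearly as well as maximal dosing at a fraction of the damage.

suppressPackageStartupMessages(library(disinfopt))
dir.create("results", showWarnings = FALSE)

spz <- surface_params(noise_sd = 0)
tab <- generate_table(200, spz, design = "random", seed = 21)
scal <- fit_scaler(tab)
fit <- train_mlp(tab, split_table(tab, seed = 21), scal,
                 train_config(seed = 21, max_epochs = 500))
cat(sprintf("surrogate fit: %d epochs, validation MSE %.2e (normalized)\n",
            fit$epochs_run, fit$mse_val))

front <- optimize_protocol(fit$params, scal,
                           ga_config(seed = 21, max_generations = 150,
                                     n_explore = 5000))
rec <- select_recommendation(front, "target_de")
truth <- true_surface(as.numeric(rec[1, 1:4]), spz)
corner <- true_surface(default_bounds()[, 2], spz)

out <- data.frame(
  protocol = c("recommended", "maximal dosing"),
  naocl_pct = c(rec$naocl, default_bounds()["naocl", 2]),
  h2o2_pct = c(rec$h2o2, default_bounds()["h2o2", 2]),
  hgcl2_pct = c(rec$hgcl2, default_bounds()["hgcl2", 2]),
  time_min = c(rec$time, default_bounds()["time", 2]),
  de_true = c(truth$de_true, corner$de_true),
  nde_true = c(truth$nde_true, corner$nde_true))
print(out, digits = 3)

cat(sprintf("\nthe recommended protocol reaches %.1f%% true disinfection at %.1f%%\n",
            truth$de_true, truth$nde_true))
cat(sprintf("true damage, versus %.1f%% disinfection at %.1f%% damage for maximal\n",
            corner$de_true, corner$nde_true))
cat("dosing: the optimizer recovers a genuinely better protocol than the\n")
cat("brute-force extreme, using only the fitted surrogate.\n")

write.csv(out, "results/synthetic_recovery.csv", row.names = FALSE)
cat("\nwrote results/synthetic_recovery.csv\n")
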