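#!/usr/bin/env Rscript

# Step 1 — reproduce the published model outputs.
#
# Recomputes the predicted DE/NDE columns of the 28-treatment experiment
# table from the published 4-10-2 weight matrices under the frozen min-max
# scaler, checks each row against the published predicted values at the
# table's printed precision (0.005), and recomputes the RMSE / R-squared
# validation metrics next to the published ones.

suppressPackageStartupMessages(library(disinfopt))
dir.create("results", showWarnings = FALSE)

rep <- reproduce_report(tolerance = 0.005)
print(rep)

cat("\nWhat this shows:\n")
cat(sprintf(" - all %d published DE predictions and all %d NDE predictions\n",
            rep$n_de_matched, rep$n_nde_matched),
    "  are reproduced exactly (to printed precision) by the forward pass,\n",
    "  which pins down the normalization convention: per-variable ranges\n",
    "  over all 28 records, responses over [0, 100], target [-1, 1].\n")
cat(sprintf(" - row(s) %s print a residual inconsistent with their own\n",
            paste(rep$inconsistent_rows, collapse = ", ")),
    "  actual/predicted values; kept as published and flagged.\n")
cat(" - the published DE RMSE recomputes from the published residual\n",
    "  column; the published NDE RMSE and both R-squared values do not\n",
    "  recompute from the published table at printed precision.\n")

write.csv(rep$table, "results/predictions_table.csv", row.names = FALSE)
write.csv(rep$metrics, "results/metrics.csv", row.names = FALSE)
cat("\nwrote results/predictions_table.csv and results/metrics.csv\n")
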