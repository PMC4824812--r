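#!/usr/bin/env Rscript
# Relate the urine markers to the plasma-derived indices: Spearman
# correlation table (urinary glucose and C-peptide, raw and
# creatinine-adjusted, against incremental AUCs, S_I, Phi and DI indices)
# and family-adjusted ROC c-indices for the three tolerance contrasts.
#
# Usage: Rscript analysis/04_urine_markers_report.R [seed]

suppressPackageStartupMessages(library(ommurine))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20151102L %% 100000L

idx <- readr::read_csv("results/indices.csv", show_col_types = FALSE)
cfg <- run_config(seed = seed)

spear <- spearman_table(idx)
readr::write_csv(spear, "results/spearman.csv", progress = FALSE)
cat("Spearman urine-plasma correlations (|r| > 0.3 shown):\n")
print(as.data.frame(spear[!is.na(spear$r) & abs(spear$r) > 0.3, ]), digits = 2)

cidx <- cindex_table(idx, cfg)
readr::write_csv(cidx, "results/cindex.csv", progress = FALSE)
cat("\nfamily-adjusted c-indices (cluster bootstrap CI,",
    cfg$n_boot, "draws):\n")
print(as.data.frame(cidx), digits = 3)

comp <- idx[!is.na(idx$urine_cpeptide) & !is.na(idx$k01_flux_auc), ]
r <- suppressWarnings(cor(comp$urine_cpeptide, comp$k01_flux_auc,
                          method = "spearman"))
cat(sprintf("\nurinary C-peptide vs model k01-flux AUC: Spearman r = %.2f (n = %d)\n",
            r, nrow(comp)))
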