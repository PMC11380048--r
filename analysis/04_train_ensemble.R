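#!/usr/bin/env Rscript
# Stage 4 — train the fold-wise deep ensemble.
#
# The TCGA-like training split is divided into five class-stratified
# folds; each fold's fit split is searched over a hyperparameter grid
# (fully connected nets, Adam, binary cross-entropy), and the entry
# performing best (ROC AUC) on the SNUH-like training split is kept. The
# ensemble averages the five winners' outputs. The 12-entry desk-scale
# grid is used here; swap in default_grid() (2160 combinations) for a
# cluster-scale search.

suppressPackageStartupMessages(library(resistseq))

seed <- 20240907
cohorts <- c("TCGA", "Patch", "SNUH")
load_part <- function(nm, part)
  load_expression(sprintf("results/split/%s_%s.tsv", nm, part),
                  "results/data/sample_annotation.tsv")
train <- setNames(lapply(cohorts, load_part, part = "train"), cohorts)

panel_json <- jsonlite::read_json("results/panel.json", simplifyVector = TRUE)
panel <- combine_panel(panel_json$tier1, as.list(panel_json$tier2))

t0 <- Sys.time()
ens <- train_ensemble(train[["TCGA"]], train[["SNUH"]], panel,
                      grid = small_grid(), k = 5, seed = seed + 3)
message(sprintf("grid search over %d entries x 5 folds in %s",
                nrow(small_grid()), format(Sys.time() - t0, digits = 3)))
print(ens)

save_ensemble(ens, "results/model")
message("model bundle written to results/model/")
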