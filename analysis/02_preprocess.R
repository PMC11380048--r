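#!/usr/bin/env Rscript
# Stage 2 — merge cohorts on shared gene IDs, drop lowly expressed genes
# (TPM >= 1 in >= 20% of pooled samples), and split each cohort 2:1 into
# training and testing with class stratification.

suppressPackageStartupMessages(library(resistseq))

seed <- 20240907
mats <- lapply(c("TCGA", "Patch", "SNUH"), function(nm)
  load_expression(file.path("results/data", paste0(nm, "_tpm.tsv")),
                  "results/data/sample_annotation.tsv"))
names(mats) <- c("TCGA", "Patch", "SNUH")

ds <- merge_cohorts(mats)
n0 <- nrow(ds[[1]]$tpm)
ds <- filter_low_expression(ds, min_tpm = 1, min_fraction = 0.2)
message(sprintf("low-expression filter: %d of %d genes retained",
                nrow(ds[[1]]$tpm), n0))

split <- stratified_split(ds, test_fraction = 1 / 3, seed = seed + 1)
print(split)

dir.create("results/split", showWarnings = FALSE, recursive = TRUE)
for (part in c("train", "test")) {
  for (nm in names(split[[part]])) {
    write_expression(split[[part]][[nm]],
                     file.path("results/split", sprintf("%s_%s.tsv", nm, part)))
  }
}
assign_tab <- do.call(rbind, lapply(c("train", "test"), function(part)
  do.call(rbind, lapply(unclass(split[[part]]), function(m)
    data.frame(sample_id = colnames(m$tpm), cohort = m$cohort,
               response = m$response, partition = part)))))
write.table(assign_tab, "results/split/assignment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote per-cohort train/test matrices to results/split/")
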