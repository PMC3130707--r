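#!/usr/bin/env Rscript
# Filter the simulated predictions at the miTG >= 20 reliability cutoff,
# convert gene ids through the ID map (unannotated ids dropped), and record
# the per-miRNA attrition from prediction rows to usable target genes.

suppressMessages(library(mirnet))

data_dir <- "scratch/analysis/data"
predictions <- read_predictions(file.path(data_dir, "targets.tsv"))
idmap <- read_idmap(file.path(data_dir, "idmap.tsv"))

sets <- build_target_sets(predictions, idmap, cutoff = 20)

att <- do.call(rbind, lapply(sets, function(ts) {
  data.frame(mirna = ts$mirna, n_predictions = ts$n_input,
             n_filtered = ts$n_filtered, n_mapped = ts$n_mapped)
}))
dir.create("results", showWarnings = FALSE)
write.table(att, "results/target_attrition.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(length(sets), "of", length(unique(predictions$mirna)),
    "miRNAs kept a non-empty target set\n")
cat("median attrition:", median(att$n_predictions), "predictions ->",
    median(att$n_filtered), "reliable ->", median(att$n_mapped),
    "mapped genes\n")
cat("table written to results/target_attrition.tsv\n")
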