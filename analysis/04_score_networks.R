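#!/usr/bin/env Rscript
# Score every extracted network against every canonical network with the
# upper-tail hypergeometric overlap statistic: pathways on molecules plus
# relations (T = molecules + relations of the knowledgebase), diseases and
# pathological events on molecules alone (T = molecules). Scores are
# -log2(p) floored at the smallest normalised double. Keeps the full result
# table alongside a compact per-miRNA top-3 table.

suppressMessages(library(mirnet))

data_dir <- "scratch/analysis/data"
graph <- read_knowledgebase(file.path(data_dir, "nodes.tsv"),
                            file.path(data_dir, "edges.tsv"))
library_ <- read_canonical_library(file.path(data_dir, "library.json"), graph)
predictions <- read_predictions(file.path(data_dir, "targets.tsv"))
idmap <- read_idmap(file.path(data_dir, "idmap.tsv"))

sets <- build_target_sets(predictions, idmap)
nets <- extract_cohort(sets, graph)
results <- enrich_cohort(nets, library_, graph)
results$score_int <- round_half_up(results$score)

write.table(results, "scratch/analysis/enrichment_full.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
top3 <- results[results$rank <= 3, ]
top3 <- top3[order(top3$mirna, top3$category, top3$rank), ]
dir.create("results", showWarnings = FALSE)
write.table(top3, "results/enrichment_top3.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

ledger <- jsonlite::fromJSON(file.path(data_dir, "ledger.json"),
                             simplifyVector = TRUE)
hit <- top3[top3$category == "pathway" & top3$rank == 1, ]
cat(nrow(results), "comparisons scored for", length(nets), "miRNAs\n")
cat("planted network", ledger$planted_network, "is the top pathway for",
    sum(hit$canonical_name == ledger$planted_network), "of", nrow(hit),
    "miRNAs\n")
cat("top-3 table written to results/enrichment_top3.tsv\n")
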