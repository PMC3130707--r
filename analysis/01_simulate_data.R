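#!/usr/bin/env Rscript
# Simulate the study's data universe at one-tenth scale: a scale-free
# molecular-interaction knowledgebase (~1,570 molecules, ~12,300 typed
# relations), a canonical library (43 pathways / 88 diseases / 21
# pathological events), and per-miRNA target predictions with a planted
# enriched pathway (rho = 0.5), plus the Ensembl->Entrez-style ID map.
# Outputs are written where the downstream scripts (and nothing else)
# consume them; they regenerate byte-identically from the seed.

suppressMessages(library(mirnet))

data_dir <- "scratch/analysis/data"
cfg <- generator_config(n_mirnas = 20, rho = 0.5,
                        planted_network = "pathway_001", seed = 20260924)
d <- generate_dataset(cfg, dir = data_dir)

cat("knowledgebase:", d$graph$n_molecules, "molecules,",
    d$graph$n_relations, "relations\n")
cat("canonical library:",
    paste(names(library_categories(d$library)),
          library_categories(d$library), sep = "=", collapse = ", "), "\n")
cat("predictions:", nrow(d$predictions), "rows over",
    length(unique(d$predictions$mirna)), "miRNAs; planted network:",
    d$ledger$planted_network, "(rho =", cfg$rho, ")\n")
cat("ID map covers", nrow(d$idmap), "of",
    length(unique(d$predictions$gene)), "used gene ids\n")
cat("written to", data_dir, "\n")
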