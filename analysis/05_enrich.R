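#!/usr/bin/env Rscript
# Stage 5 — over-representation analysis of the brain-age gene list.
#
# Hypergeometric test of the FWE-significant genes against the GMT
# collection, BH-adjusted; the universe is the expression panel.

source("analysis/common.R")

sets <- read_gmt(file.path(DATA_DIR, "gene_sets.gmt"))
genes <- readLines(file.path(RESULTS, "significant_genes.txt"))
dataset <- read_expression(file.path(DATA_DIR, "expression.tsv"),
                           file.path(DATA_DIR, "samples.tsv"))

ora <- run_ora(genes, sets, universe = dataset$gene_ids)
write.table(ora, file.path(RESULTS, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- ora[ora$significant, ]
cat(sprintf("%d/%d terms enriched at q < 0.05; top term: %s (k/K = %d/%d, q = %.2g)\n",
            nrow(sig), nrow(ora), ora$term[1], ora$overlap[1],
            ora$term_size[1], ora$q[1]))
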