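#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs with known ground truth.
#
# Produces: an atlas (68 ROIs / 17 networks) as NIfTI, a 250-subject cohort
# whose age-related atrophy is concentrated in network 5, a 6-donor spatial
# expression dataset whose 20 signal genes are shifted in network-5 samples,
# and a 40-term gene-set collection with one planted term.

source("analysis/common.R")

atlas <- build_atlas()
write_atlas_nifti(atlas, file.path(DATA_DIR, "atlas_labels.nii.gz"),
                  file.path(DATA_DIR, "brain_mask.nii.gz"))
write.table(data.frame(roi = atlas$roi_ids,
                       network = as.integer(atlas$network_of_roi)),
            file.path(DATA_DIR, "roi_networks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cohort <- generate_cohort(atlas, n_subjects = 250L,
                          truth = planted_network_truth(17L, PLANTED_NETWORK,
                                                        seed = SEED + 1L))
write_gmv_table(cohort$gmv, file.path(DATA_DIR, "gmv.tsv"))
write.table(cohort$phenotypes, file.path(DATA_DIR, "phenotypes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

signal_genes <- sprintf("G%04d", 1:20)
dataset <- generate_expression(atlas, n_donors = 6L,
                               samples_per_donor_range = c(40L, 80L),
                               n_genes = 200L,
                               truth = expression_truth(signal_genes,
                                                        PLANTED_NETWORK,
                                                        delta = 0.5,
                                                        seed = SEED + 2L))
write_expression(dataset, file.path(DATA_DIR, "expression.tsv"),
                 file.path(DATA_DIR, "samples.tsv"))
writeLines(signal_genes, file.path(DATA_DIR, "signal_genes.txt"))

sets <- generate_gene_sets(dataset$gene_ids, n_terms = 40L,
                           term_size_range = c(10L, 60L),
                           planted_genes = signal_genes, seed = SEED + 3L)
write_gmt(sets, file.path(DATA_DIR, "gene_sets.gmt"))

cat(sprintf(
  "simulated: %d subjects x %d ROIs (signal in network %d), %d genes x %d samples, %d gene sets\n",
  nrow(cohort$gmv), ncol(cohort$gmv), PLANTED_NETWORK,
  nrow(dataset$expr), ncol(dataset$expr), length(sets)))
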