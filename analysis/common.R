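# Shared settings for the analysis drivers. Every script sources this file,
# rebuilds the (deterministic) atlas from the seed, and reads/writes under
# results/. Desk-scale sizes: 68 ROIs in 17 networks, 250 subjects, 5 CV
# repeats, 999 permutations.

library(netbrainage)

SEED <- 20260901L
PLANTED_NETWORK <- 5L
RESULTS <- "results"
DATA_DIR <- file.path(RESULTS, "data")

dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

build_atlas <- function() {
  generate_atlas(n_rois = 68L, n_networks = 17L,
                 grid_shape = c(24L, 28L, 24L), voxel_size_mm = 4,
                 seed = SEED)
}
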