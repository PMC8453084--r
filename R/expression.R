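#' Ground truth for a synthetic spatial expression dataset
#'
#' @param signal_gene_ids gene ids carrying a planted expression shift.
#' @param target_network network id whose samples receive the shift.
#' @param delta mean shift on the log-expression scale added to signal genes
#'   in samples mapped to the target network; 0 plants no effect.
#' @param seed integer seed used by [generate_expression()].
#' @return object of class `expression_truth`.
#' @export
expression_truth <- function(signal_gene_ids, target_network, delta = 0.5,
                             seed = 1L) {
  structure(list(signal_gene_ids = as.character(signal_gene_ids),
                 target_network = as.integer(target_network),
                 delta = delta, seed = as.integer(seed)),
            class = "expression_truth")
}

#' Generate a multi-donor spatial gene-expression dataset
#'
#' Emulates a postmortem expression atlas: several donors each contribute
#' spatially localized tissue samples (world-mm coordinates inside the brain
#' mask) with a genes x samples expression matrix. Baseline expression is
#' log-normal — log-expression is Gaussian with mean 1 and sd 0.25 per gene —
#' giving strictly positive values with multiplicative noise. Signal genes
#' receive an additive shift of `delta` on the log scale in every sample
#' whose 6-mm sphere maps to the target network under the same
#' sphere-overlap rule used by the annotation stage
#' ([map_samples_to_clusters()]).
#'
#' @param atlas a `brain_atlas` supplying mask, network labels and affine.
#' @param n_donors number of donors; default 6.
#' @param samples_per_donor_range integer `(lo, hi)`; each donor's sample
#'   count is drawn uniformly from this range (363-946 at full scale).
#' @param n_genes number of genes.
#' @param truth an [expression_truth()]; its signal genes must be a subset of
#'   the generated gene ids `G0001..G<n_genes>` (ids outside that range are
#'   rejected).
#' @param radius_mm,overlap_threshold sphere-mapping parameters used to decide
#'   which samples receive the planted shift.
#' @return object of class `expression_dataset`: list with `expr`
#'   (genes x samples matrix), `gene_ids`, `samples` (data.frame: sample_id,
#'   donor, x, y, z), `truth`, and `target_samples` (logical, which samples
#'   received the shift).
#' @export
generate_expression <- function(atlas, n_donors = 6L,
                                samples_per_donor_range = c(363L, 946L),
                                n_genes = 500L,
                                truth = expression_truth(character(0), 1L),
                                radius_mm = 6, overlap_threshold = 0.5) {
  stopifnot(inherits(atlas, "brain_atlas"),
            inherits(truth, "expression_truth"),
            n_donors >= 1, length(samples_per_donor_range) == 2,
            samples_per_donor_range[1] >= 1,
            samples_per_donor_range[1] <= samples_per_donor_range[2])
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (!all(truth$signal_gene_ids %in% gene_ids))
    stop("signal_gene_ids must be a subset of the generated gene ids")
  net_grid <- network_label_grid(atlas)
  if (!any(net_grid == truth$target_network))
    stop(sprintf("target network %d has no voxels", truth$target_network))

  mask_idx <- which(atlas$mask)
  dims <- dim(atlas$mask)

  withr::with_seed(truth$seed, {
    per_donor <- sample(seq(samples_per_donor_range[1],
                            samples_per_donor_range[2]),
                        n_donors, replace = TRUE)
    n_samp <- sum(per_donor)
    donor <- rep(sprintf("D%02d", seq_len(n_donors)), per_donor)
    # uniform within the mask: pick a mask voxel, jitter within its cube
    vox <- arrayInd(sample(mask_idx, n_samp, replace = TRUE), dims)
    jit <- matrix(stats::runif(3 * n_samp, -0.5, 0.5), n_samp, 3)
    world <- voxel_to_world(vox + jit, atlas$affine)
    logx <- matrix(stats::rnorm(n_genes * n_samp, mean = 1, sd = 0.25),
                   n_genes, n_samp)
  })

  # tie-break warnings are analysis-facing; irrelevant while generating truth
  assign <- suppressWarnings(
    map_samples_to_clusters(world, atlas$mask, net_grid,
                            atlas$affine, radius_mm = radius_mm,
                            overlap_threshold = overlap_threshold))
  target <- !is.na(assign$cluster) & assign$cluster == truth$target_network
  if (truth$delta != 0 && length(truth$signal_gene_ids) > 0 && any(target)) {
    sig <- match(truth$signal_gene_ids, gene_ids)
    logx[sig, target] <- logx[sig, target] + truth$delta
  }
  expr <- exp(logx)

  sample_ids <- sprintf("SA%05d", seq_len(nrow(world)))
  dimnames(expr) <- list(gene_ids, sample_ids)
  samples <- data.frame(sample_id = sample_ids, donor = donor,
                        x = world[, 1], y = world[, 2], z = world[, 3],
                        stringsAsFactors = FALSE)
  structure(list(expr = expr, gene_ids = gene_ids, samples = samples,
                 truth = truth, target_samples = target),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples, %d donors\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$samples$donor))))
  invisible(x)
}

#' Generate a gene-set collection with one planted term
#'
#' The first term ("PLANTED") is the planted signal genes topped up with
#' random background genes to its drawn size; the remaining terms are uniform
#' random draws from the universe. The collection is writable as GMT.
#'
#' @param gene_ids gene universe.
#' @param n_terms number of terms.
#' @param term_size_range integer `(lo, hi)` of term sizes (capped at the
#'   universe size).
#' @param planted_genes character vector of signal genes seeding the planted
#'   term; empty for none.
#' @param seed integer seed.
#' @return named list of character vectors (class `gene_sets`), with a
#'   `description` attribute parallel to the terms.
#' @export
generate_gene_sets <- function(gene_ids, n_terms = 50L,
                               term_size_range = c(10L, 200L),
                               planted_genes = character(0), seed = 1L) {
  stopifnot(length(term_size_range) == 2,
            term_size_range[1] >= 1,
            term_size_range[1] <= term_size_range[2])
  if (term_size_range[2] > length(gene_ids))
    stop("term sizes exceed the universe size")
  if (!all(planted_genes %in% gene_ids))
    stop("planted_genes must lie in the universe")
  withr::with_seed(seed, {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    sets <- vector("list", n_terms)
    for (t in seq_len(n_terms)) {
      if (t == 1L && length(planted_genes) > 0) {
        sz <- max(sizes[t], length(planted_genes))
        extra <- sample(setdiff(gene_ids, planted_genes),
                        sz - length(planted_genes))
        sets[[t]] <- c(planted_genes, extra)
      } else {
        sets[[t]] <- sample(gene_ids, sizes[t])
      }
    }
  })
  names(sets) <- c(if (length(planted_genes) > 0) "PLANTED" else NULL,
                   sprintf("RAND%03d",
                           seq_len(n_terms - (length(planted_genes) > 0))))
  attr(sets, "description") <- rep("synthetic gene set", n_terms)
  class(sets) <- "gene_sets"
  sets
}
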