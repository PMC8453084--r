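#' Per-donor median normalization of expression
#'
#' For each donor and gene, subtracts the median of the gene's expression
#' across that donor's samples and divides by the same median:
#' `x' = (x - median_d) / median_d`. This removes donor-specific expression
#' scale so samples can be pooled across donors.
#'
#' @param dataset an `expression_dataset`, or a list with `expr`
#'   (genes x samples) and `samples` (data.frame with `donor`).
#' @return matrix of normalized expression, same shape as `expr`.
#' @export
normalize_expression <- function(dataset) {
  expr <- dataset$expr
  donor <- dataset$samples$donor
  stopifnot(length(donor) == ncol(expr), !anyNA(expr))
  out <- expr
  for (d in unique(donor)) {
    idx <- which(donor == d)
    med <- apply(expr[, idx, drop = FALSE], 1, stats::median)
    if (any(med == 0)) {
      g <- rownames(expr)[which(med == 0)[1]]
      stop(sprintf("zero median for gene %s in donor %s",
                   if (is.null(g)) which(med == 0)[1] else g, d))
    }
    out[, idx] <- (expr[, idx, drop = FALSE] - med) / med
  }
  out
}

#' Permutation test for cluster-associated genes with FWE control
#'
#' For each gene the observed statistic is the mean normalized expression
#' over the samples assigned to the cluster. The null distribution draws the
#' same number of samples uniformly without replacement from all admitted
#' samples and recomputes the mean, `n_perm` times, reusing the same
#' permutations for every gene. One-sided p-values use the add-one estimator
#' `p_hi = (1 + #\{T_b >= T_obs\}) / (n_perm + 1)` (and the analogous lower
#' tail); the two-sided p is `min(1, 2 min(p_hi, p_lo))`. Family-wise error
#' control is single-step max-statistic by default: each gene's
#' `|T_obs - mean(T_null)|` is compared with the permutation distribution of
#' the maximum of that centred absolute statistic across genes
#' (`fwe = "bonferroni"` multiplies the raw p instead). Adjusted p-values are
#' floored at the unadjusted ones.
#'
#' @param norm_expr normalized genes x samples matrix over *admitted* samples
#'   (see [map_samples_to_clusters()]).
#' @param in_cluster logical vector over the columns of `norm_expr`, `TRUE`
#'   for samples assigned to the cluster under test.
#' @param n_perm number of permutations (>= 100), default 999.
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param fwe `"maxstat"` (default) or `"bonferroni"`.
#' @return data.frame with one row per gene: `gene`, `t_obs`, `p`
#'   (uncorrected, per `alternative`), `p_fwe`, `significant` (at 0.05).
#' @export
permutation_gene_association <- function(norm_expr, in_cluster,
                                         n_perm = 999L, seed = 1L,
                                         alternative = c("two.sided",
                                                         "greater", "less"),
                                         fwe = c("maxstat", "bonferroni")) {
  alternative <- match.arg(alternative)
  fwe <- match.arg(fwe)
  norm_expr <- as.matrix(norm_expr)
  in_cluster <- as.logical(in_cluster)
  stopifnot(length(in_cluster) == ncol(norm_expr))
  m <- sum(in_cluster)
  s <- ncol(norm_expr)
  if (m < 2 || s - m < 2)
    stop("need at least 2 samples inside and outside the cluster")
  if (n_perm < 100) stop("n_perm must be at least 100")

  t_obs <- rowMeans(norm_expr[, in_cluster, drop = FALSE])

  ind <- withr::with_seed(seed, {
    M <- matrix(0, s, n_perm)
    for (b in seq_len(n_perm)) M[sample.int(s, m), b] <- 1 / m
    M
  })
  t_null <- norm_expr %*% ind            # genes x n_perm

  p_hi <- (1 + rowSums(t_null >= t_obs)) / (n_perm + 1)
  p_lo <- (1 + rowSums(t_null <= t_obs)) / (n_perm + 1)
  p <- switch(alternative,
              two.sided = pmin(1, 2 * pmin(p_hi, p_lo)),
              greater = p_hi,
              less = p_lo)

  if (fwe == "maxstat") {
    ctr <- rowMeans(t_null)
    d_obs <- abs(t_obs - ctr)
    max_null <- apply(abs(t_null - ctr), 2, max)
    p_fwe <- vapply(d_obs, function(d) (1 + sum(max_null >= d)) / (n_perm + 1),
                    numeric(1))
  } else {
    p_fwe <- pmin(1, p * nrow(norm_expr))
  }
  p_fwe <- pmax(p_fwe, p)

  genes <- rownames(norm_expr)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(norm_expr)))
  data.frame(gene = genes, t_obs = t_obs, p = p, p_fwe = p_fwe,
             significant = p_fwe < 0.05, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select cluster-associated genes at an FWE threshold
#'
#' @param associations output of [permutation_gene_association()].
#' @param alpha FWE threshold, default 0.05. The comparison is strict
#'   (`p_fwe < alpha`); `alpha = 1` returns every gene.
#' @return character vector of gene ids sorted by adjusted then raw p.
#' @export
select_genes <- function(associations, alpha = 0.05) {
  hit <- associations[associations$p_fwe < alpha | alpha >= 1, ]
  hit <- hit[order(hit$p_fwe, hit$p), ]
  hit$gene
}

#' Collapse probe-level expression to gene level
#'
#' Keeps, for each gene, the probe with the highest mean expression across
#' samples. Utility for probe-level inputs; the main analysis path assumes
#' gene-level expression.
#'
#' @param probe_expr probes x samples matrix.
#' @param gene_of_probe character vector mapping each probe row to a gene.
#' @return genes x samples matrix, one row per unique gene.
#' @export
collapse_probes <- function(probe_expr, gene_of_probe) {
  probe_expr <- as.matrix(probe_expr)
  stopifnot(length(gene_of_probe) == nrow(probe_expr))
  avg <- rowMeans(probe_expr)
  keep <- vapply(split(seq_along(gene_of_probe), gene_of_probe),
                 function(rows) rows[which.max(avg[rows])], integer(1))
  out <- probe_expr[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out
}

#' Annotate a cluster with associated genes
#'
#' End-to-end gene annotation of one cluster: map samples into the cluster
#' label volume with sphere ROIs, normalize expression per donor, run the
#' permutation association test over the admitted samples, and select the
#' FWE-significant genes.
#'
#' @param dataset an `expression_dataset`.
#' @param background_mask logical 3-D array (brain mask).
#' @param cluster_labels integer 3-D array of cluster ids.
#' @param affine 4x4 voxel-to-world matrix.
#' @param cluster_id the cluster to annotate.
#' @param radius_mm,overlap_threshold sphere-mapping parameters
#'   (defaults 6 mm, 0.5).
#' @param n_perm,seed,alternative,fwe passed to
#'   [permutation_gene_association()].
#' @param alpha FWE threshold for [select_genes()].
#' @return list with `assignment` (all samples), `associations` (per gene),
#'   `genes` (selected ids), and the settings used.
#' @export
annotate_cluster <- function(dataset, background_mask, cluster_labels,
                             affine, cluster_id, radius_mm = 6,
                             overlap_threshold = 0.5, n_perm = 999L,
                             seed = 1L, alternative = "two.sided",
                             fwe = "maxstat", alpha = 0.05) {
  coords <- as.matrix(dataset$samples[, c("x", "y", "z")])
  assignment <- map_samples_to_clusters(coords, background_mask,
                                        cluster_labels, affine,
                                        radius_mm = radius_mm,
                                        overlap_threshold = overlap_threshold)
  admitted <- !is.na(assignment$cluster)
  if (!any(admitted))
    stop("no admitted samples; cannot annotate")
  norm <- normalize_expression(dataset)[, admitted, drop = FALSE]
  in_cluster <- assignment$cluster[admitted] == cluster_id
  assoc <- permutation_gene_association(norm, in_cluster, n_perm = n_perm,
                                        seed = seed,
                                        alternative = alternative, fwe = fwe)
  list(assignment = assignment, associations = assoc,
       genes = select_genes(assoc, alpha = alpha),
       cluster_id = cluster_id, radius_mm = radius_mm,
       overlap_threshold = overlap_threshold, n_perm = n_perm,
       alternative = alternative, fwe = fwe, alpha = alpha, seed = seed)
}
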