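test_that("sphere voxelization matches an exhaustive scan", {
  affine <- tiny_atlas$affine
  dims <- dim(tiny_atlas$mask)
  # a radius smaller than half a voxel centred on a voxel centre -> 1 voxel
  ctr <- voxel_to_world(matrix(c(8, 8, 8), 1), affine)
  vox <- voxelize_sphere(ctr, 1, dims, affine)     # 1 mm < 2.5 mm half-voxel
  expect_equal(vox, matrix(c(8L, 8L, 8L), 1))

  # 6-mm sphere: exhaustive scan over every voxel centre
  for (center in list(ctr, ctr + c(2.2, -1.7, 0.4))) {
    vox <- voxelize_sphere(center, 6, dims, affine)
    all_vox <- as.matrix(expand.grid(i = 1:dims[1], j = 1:dims[2],
                                     k = 1:dims[3]))
    w <- voxel_to_world(all_vox, affine)
    inside <- sqrt(colSums((t(w) - as.vector(center))^2)) <= 6
    brute <- all_vox[inside, , drop = FALSE]
    expect_equal(vox[order(vox[, 1], vox[, 2], vox[, 3]), ],
                 unname(brute[order(brute[, 1], brute[, 2], brute[, 3]), ]))
  }

  # translation by one full voxel shifts the voxel set congruently
  v0 <- voxelize_sphere(ctr, 6, dims, affine)
  v1 <- voxelize_sphere(ctr + c(tiny_atlas$voxel_size_mm, 0, 0), 6, dims,
                        affine)
  expect_equal(v1, v0 + rep(c(1L, 0L, 0L), each = nrow(v0)))

  expect_warning(out <- voxelize_sphere(c(1e4, 1e4, 1e4), 6, dims, affine),
                 "outside")
  expect_equal(nrow(out), 0)
})

test_that("sample admission requires strictly more than half in-mask", {
  dims <- c(16L, 16L, 16L)
  affine <- diag(c(2, 2, 2, 1))                    # 2 mm voxels
  # centre offset by half a voxel along x so the voxel count is even
  ctr <- voxel_to_world(matrix(c(8, 8, 8), 1), affine) + c(1, 0, 0)
  sphere <- voxelize_sphere(ctr, 6, dims, affine)
  expect_true(nrow(sphere) %% 2 == 0)              # split exactly in half
  idx <- sphere[, 1] + dims[1] * (sphere[, 2] - 1L) +
    dims[1] * dims[2] * (sphere[, 3] - 1L)
  mask <- array(FALSE, dims)
  mask[idx[seq_len(nrow(sphere) / 2)]] <- TRUE     # overlap exactly 0.5
  labels <- array(0L, dims)
  labels[mask] <- 1L
  res <- map_samples_to_clusters(ctr, mask, labels, affine, radius_mm = 6)
  expect_equal(res$overlap, 0.5)
  expect_true(is.na(res$cluster))                  # not strictly greater

  mask[idx] <- TRUE                                # now fully inside
  labels[mask] <- 1L
  res2 <- map_samples_to_clusters(ctr, mask, labels, affine, radius_mm = 6)
  expect_equal(res2$overlap, 1)
  expect_equal(res2$cluster, 1L)

  far <- map_samples_to_clusters(c(500, 500, 500), mask, labels, affine)
  expect_true(is.na(far$cluster))
})

test_that("sample mapping is invariant to sample order", {
  net_grid <- network_label_grid(tiny_atlas)
  set.seed(13)
  vox <- arrayInd(sample(which(tiny_atlas$mask), 20), dim(tiny_atlas$mask))
  coords <- voxel_to_world(vox, tiny_atlas$affine)
  res <- suppressWarnings(
    map_samples_to_clusters(coords, tiny_atlas$mask, net_grid,
                            tiny_atlas$affine))
  perm <- sample(20)
  res_p <- suppressWarnings(
    map_samples_to_clusters(coords[perm, ], tiny_atlas$mask, net_grid,
                            tiny_atlas$affine))
  expect_equal(res_p$cluster, res$cluster[perm])
  expect_equal(res_p$overlap, res$overlap[perm])
})

test_that("per-donor median normalization follows its formula", {
  expr <- rbind(g1 = c(1, 2, 3, 10, 20, 30),
                g2 = c(4, 4, 4, 8, 8, 8))
  ds <- list(expr = expr,
             samples = data.frame(donor = rep(c("a", "b"), each = 3)))
  norm <- normalize_expression(ds)
  expect_equal(norm["g1", ], c(-0.5, 0, 0.5, -0.5, 0, 0.5),
               ignore_attr = TRUE)
  expect_equal(norm["g2", ], rep(0, 6), ignore_attr = TRUE)
  # hand computation for two donors with different medians
  expect_equal(norm["g1", 4], (10 - 20) / 20, ignore_attr = TRUE)
  # sign structure: above donor median positive, below negative
  set.seed(14)
  expr2 <- matrix(rlnorm(50 * 12), 50, 12)
  ds2 <- list(expr = expr2,
              samples = data.frame(donor = rep(c("a", "b"), each = 6)))
  n2 <- normalize_expression(ds2)
  med_a <- apply(expr2[, 1:6], 1, median)
  expect_true(all((n2[, 1:6] > 0) == (expr2[, 1:6] > med_a)))

  ds$expr["g2", 1:3] <- c(-1, 0, 1)
  expect_error(normalize_expression(ds), "zero median")
})

test_that("permutation p-values follow the add-one estimator and reproduce", {
  set.seed(15)
  expr <- matrix(rnorm(20 * 40), 20, 40,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  expr[1, 1:8] <- expr[1, 1:8] + 100     # beyond every permuted mean
  in_cl <- c(rep(TRUE, 8), rep(FALSE, 32))
  res <- permutation_gene_association(expr, in_cl, n_perm = 999, seed = 5,
                                      alternative = "greater")
  expect_equal(res$p[1], 1 / 1000)
  res2 <- permutation_gene_association(expr, in_cl, n_perm = 999, seed = 5,
                                       alternative = "greater")
  expect_identical(res, res2)            # bit-for-bit under the same seed
  res3 <- permutation_gene_association(expr, in_cl, n_perm = 999, seed = 6,
                                       alternative = "greater")
  expect_false(identical(res$p, res3$p))
  expect_true(all(res$p_fwe >= res$p))

  expect_error(permutation_gene_association(expr, rep(TRUE, 40)),
               "outside")
  expect_error(permutation_gene_association(expr, in_cl, n_perm = 10),
               "at least 100")
})

test_that("permutation p-values are valid under a null cluster", {
  set.seed(16)
  expr <- matrix(rnorm(40 * 60), 40, 60)
  in_cl <- c(rep(TRUE, 12), rep(FALSE, 48))
  rates <- replicate(30, {
    e <- matrix(rnorm(40 * 60), 40, 60)
    p <- permutation_gene_association(e, in_cl, n_perm = 199,
                                      seed = sample.int(1e6, 1))$p
    mean(p <= 0.05)
  })
  expect_lte(mean(rates), 0.05 + 1 / 200 +
               2.576 * sqrt(0.05 * 0.95 / (30 * 40)))
})

test_that("gene selection orders and thresholds by adjusted p", {
  assoc <- data.frame(gene = c("a", "b", "c"), t_obs = 1:3,
                      p = c(0.2, 0.001, 0.01), p_fwe = c(1, 0.002, 0.04))
  expect_equal(select_genes(assoc), c("b", "c"))
  expect_equal(select_genes(assoc, alpha = 1), c("b", "c", "a"))
  assoc$p_fwe <- 1
  expect_length(select_genes(assoc), 0)
})

test_that("probe collapsing keeps the highest-expressed probe per gene", {
  pe <- rbind(p1 = c(1, 1), p2 = c(5, 5), p3 = c(2, 4))
  out <- collapse_probes(pe, c("gA", "gA", "gB"))
  expect_equal(rownames(out), c("gA", "gB"))
  expect_equal(out["gA", ], c(5, 5), ignore_attr = TRUE)
})

test_that("cluster annotation recovers planted signal genes end to end", {
  sig <- sprintf("G%04d", 1:15)
  ds <- generate_expression(tiny_atlas, n_donors = 6L,
                            samples_per_donor_range = c(40L, 60L),
                            n_genes = 120L,
                            truth = expression_truth(sig, 2L, delta = 0.5,
                                                     seed = 23L))
  ann <- suppressWarnings(
    annotate_cluster(ds, tiny_atlas$mask, network_label_grid(tiny_atlas),
                     tiny_atlas$affine, cluster_id = 2L,
                     n_perm = 499, seed = 3L))
  expect_true(all(sig %in% ann$genes))
  false_pos <- setdiff(ann$genes, sig)
  expect_lte(length(false_pos), 2)
})
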