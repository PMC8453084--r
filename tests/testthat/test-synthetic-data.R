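test_that("atlas generation yields the requested parcellation", {
  atlas <- generate_atlas(n_rois = 246L, n_networks = 17L, seed = 1L)
  labs <- atlas$label_grid[atlas$label_grid > 0]
  expect_setequal(unique(labs), 1:246)           # every ROI non-empty
  expect_length(atlas$roi_ids, 246)
  expect_true(all(atlas$network_of_roi %in% 1:17))
  # balanced assignment up to remainder
  expect_lte(diff(range(table(atlas$network_of_roi))), 1)
  # background outside the mask only
  expect_true(all((atlas$label_grid > 0) == atlas$mask))
})

test_that("degenerate and deterministic atlas cases behave", {
  one <- generate_atlas(n_rois = 1L, n_networks = 1L,
                        grid_shape = c(10L, 10L, 10L), seed = 0L)
  expect_true(all(one$label_grid[one$mask] == 1L))

  a1 <- generate_atlas(8L, 4L, grid_shape = c(20L, 20L, 20L), seed = 7L)
  a2 <- generate_atlas(8L, 4L, grid_shape = c(20L, 20L, 20L), seed = 7L)
  expect_identical(a1$label_grid, a2$label_grid)

  expect_error(generate_atlas(50L, 2L, grid_shape = c(3L, 3L, 3L)),
               "too small")
  expect_error(generate_atlas(4L, 8L), "n_networks")
})

test_that("cohorts decline with age and reproduce bitwise under a seed", {
  coh <- generate_cohort(tiny_atlas, n_subjects = 200L,
                         truth = cohort_truth(4L, seed = 3L))
  net <- as.integer(tiny_atlas$network_of_roi)
  for (nw in 1:4) {
    m <- rowMeans(coh$gmv[, net == nw, drop = FALSE])
    expect_lt(cor(coh$phenotypes$age, m), 0)
  }
  coh2 <- generate_cohort(tiny_atlas, n_subjects = 200L,
                          truth = cohort_truth(4L, seed = 3L))
  expect_identical(coh$gmv, coh2$gmv)
  expect_identical(coh$phenotypes, coh2$phenotypes)
  expect_error(generate_cohort(tiny_atlas, n_subjects = 5L), ">= 10")
})

test_that("noiseless cohorts are exact affine functions of age", {
  coh <- generate_cohort(tiny_atlas, n_subjects = 50L,
                         truth = noiseless_truth(4L))
  for (j in c(1L, 7L, 20L)) {
    fit <- lm(coh$gmv[, j] ~ coh$phenotypes$age)
    expect_lt(max(abs(resid(fit))), 1e-8)
  }
})

test_that("expression generator plants a shift in target-network samples", {
  sig <- sprintf("G%04d", 1:25)
  ds <- generate_expression(tiny_atlas, n_donors = 6L,
                            samples_per_donor_range = c(30L, 60L),
                            n_genes = 500L,
                            truth = expression_truth(sig, 2L, delta = 0.5,
                                                     seed = 3L))
  expect_gt(sum(ds$target_samples), 2)
  in_t <- ds$target_samples
  shift <- rowMeans(log(ds$expr[sig, in_t, drop = FALSE])) -
    rowMeans(log(ds$expr[sig, !in_t, drop = FALSE]))
  expect_true(all(shift > 0.2))            # planted delta = 0.5 on log scale
  bg <- setdiff(ds$gene_ids, sig)[1:25]
  shift_bg <- rowMeans(log(ds$expr[bg, in_t, drop = FALSE])) -
    rowMeans(log(ds$expr[bg, !in_t, drop = FALSE]))
  expect_true(all(abs(shift_bg) < 0.2))    # background untouched

  # delta = 0: signal genes indistinguishable from background
  ds0 <- generate_expression(tiny_atlas, n_donors = 6L,
                             samples_per_donor_range = c(30L, 60L),
                             n_genes = 100L,
                             truth = expression_truth(sprintf("G%04d", 1:10),
                                                      2L, delta = 0,
                                                      seed = 4L))
  s0 <- rowMeans(log(ds0$expr[1:10, ds0$target_samples, drop = FALSE])) -
    rowMeans(log(ds0$expr[1:10, !ds0$target_samples, drop = FALSE]))
  expect_true(all(abs(s0) < 0.2))
})

test_that("full-scale donor sample counts respect the documented range", {
  ds <- generate_expression(tiny_atlas, n_donors = 6L,
                            samples_per_donor_range = c(363L, 946L),
                            n_genes = 2L,
                            truth = expression_truth(character(0), 1L,
                                                     seed = 9L))
  counts <- table(ds$samples$donor)
  expect_length(counts, 6)
  expect_true(all(counts >= 363 & counts <= 946))
  expect_gte(ncol(ds$expr), 6 * 363)
  expect_lte(ncol(ds$expr), 6 * 946)
})

test_that("gene-set generation plants one enriched term and is valid GMT", {
  genes <- sprintf("G%04d", 1:500)
  sig <- genes[1:25]
  sets <- generate_gene_sets(genes, n_terms = 50L,
                             term_size_range = c(10L, 200L),
                             planted_genes = sig, seed = 2L)
  expect_length(sets, 50)
  expect_true(all(sig %in% sets[["PLANTED"]]))
  expect_true(all(vapply(sets, function(s) all(s %in% genes), logical(1))))
  expect_true(all(lengths(sets) >= 10 & lengths(sets) <= 200))
  sets2 <- generate_gene_sets(genes, n_terms = 50L,
                              term_size_range = c(10L, 200L),
                              planted_genes = sig, seed = 2L)
  expect_identical(unclass(sets), unclass(sets2))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_atlas(4L, 2L, grid_shape = c(10L, 10L, 10L), seed = 1L))
  invisible(generate_cohort(tiny_atlas, 20L,
                            truth = cohort_truth(4L, seed = 1L)))
  expect_identical(.Random.seed, before)
})
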