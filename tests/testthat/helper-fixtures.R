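# Shared small fixtures, built once per test run.

# tiny atlas: 20 ROIs in 4 networks on a 16^3 grid, 5 mm voxels
tiny_atlas <- generate_atlas(n_rois = 20L, n_networks = 4L,
                             grid_shape = c(16L, 16L, 16L),
                             voxel_size_mm = 5, seed = 11L)

# desk-scale atlas used by the heavier integration checks
desk_atlas <- generate_atlas(n_rois = 68L, n_networks = 17L,
                             grid_shape = c(24L, 28L, 24L),
                             voxel_size_mm = 4, seed = 1L)

# a noiseless truth: GMV an exact affine function of age
noiseless_truth <- function(n_networks, seed = 5L) {
  cohort_truth(n_networks = n_networks, network_noise_sd = 0,
               subject_sd = 0, roi_slope_sd = 0.02, seed = seed)
}

# independent transcription of the dependent-correlation Z statistic
# (Steiger 1980, two correlations sharing one variable, mean-r substitution),
# kept deliberately separate from the package implementation
steiger_reference <- function(r1, r2, r12, n) {
  rm2 <- ((r1 + r2) / 2)^2
  psi <- r12 * (1 - 2 * rm2) - (rm2 / 2) * (1 - 2 * rm2 - r12^2)
  (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 - 2 * psi / (1 - rm2)^2))
}

# dense-linear-algebra oracle for the GPR predictive mean at fixed
# hyperparameters (explicit solve, no Cholesky reuse)
gpr_mean_oracle <- function(model, X, y, Xnew) {
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, `/`)
  Xns <- sweep(sweep(Xnew, 2, model$x_center), 2, model$x_scale, `/`)
  hp <- model$hyperparams
  K <- kernel_matrix(Xs, Xs, hp) + diag(hp$sigma_n^2, nrow(Xs))
  ks <- kernel_matrix(Xns, Xs, hp)
  as.vector(ks %*% solve(K, y - mean(y))) + mean(y)
}
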