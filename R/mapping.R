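#' Convert between voxel indices and world coordinates
#'
#' The affine follows the NIfTI convention (it maps 0-based voxel indices to
#' world mm); these helpers take and return R's 1-based indices.
#'
#' @param vox matrix (n x 3) of 1-based voxel coordinates (may be fractional).
#' @param affine 4x4 voxel-to-world matrix.
#' @return `voxel_to_world()`: n x 3 matrix of world mm; `world_to_voxel()`:
#'   n x 3 matrix of (fractional) 1-based voxel coordinates.
#' @export
voxel_to_world <- function(vox, affine) {
  vox <- matrix(vox, ncol = 3)
  t(affine[1:3, 1:3] %*% t(vox - 1) + affine[1:3, 4])
}

#' @rdname voxel_to_world
#' @param world matrix (n x 3) of world coordinates in mm.
#' @export
world_to_voxel <- function(world, affine) {
  world <- matrix(world, ncol = 3)
  inv <- solve(affine[1:3, 1:3])
  t(inv %*% (t(world) - affine[1:3, 4])) + 1
}

#' Voxelize a sphere on a grid
#'
#' Returns the voxels whose *centre* lies within `radius_mm` (Euclidean, in
#' world coordinates) of `center_mm`. Voxels outside the grid bounds are
#' dropped; a sphere entirely outside the grid yields an empty set with a
#' warning.
#'
#' @param center_mm numeric length-3 world coordinate of the sphere centre.
#' @param radius_mm sphere radius in mm (> 0).
#' @param grid_dim integer length-3 grid dimensions.
#' @param affine 4x4 voxel-to-world matrix.
#' @return integer matrix (n x 3) of 1-based voxel coordinates.
#' @export
voxelize_sphere <- function(center_mm, radius_mm, grid_dim, affine) {
  stopifnot(radius_mm > 0, length(grid_dim) == 3, all(grid_dim >= 1))
  cv <- as.vector(world_to_voxel(matrix(center_mm, 1), affine))
  # conservative bounding box in voxel units
  step <- min(sqrt(colSums(affine[1:3, 1:3]^2)))
  halo <- ceiling(radius_mm / step) + 1L
  rng <- function(d) {
    seq(max(1L, floor(cv[d] - halo)), min(grid_dim[d], ceiling(cv[d] + halo)))
  }
  if (any(vapply(1:3, function(d) cv[d] + halo < 1 || cv[d] - halo > grid_dim[d],
                 logical(1)))) {
    warning("sphere entirely outside the grid")
    return(matrix(integer(0), 0, 3))
  }
  cand <- as.matrix(expand.grid(i = rng(1), j = rng(2), k = rng(3)))
  w <- voxel_to_world(cand, affine)
  d2 <- (w[, 1] - center_mm[1])^2 + (w[, 2] - center_mm[2])^2 +
    (w[, 3] - center_mm[3])^2
  keep <- d2 <= radius_mm^2
  if (!any(keep)) {
    warning("sphere contains no voxel centres inside the grid")
    return(matrix(integer(0), 0, 3))
  }
  out <- cand[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Map expression samples to clusters via sphere ROIs
#'
#' Each sample is represented by a sphere of `radius_mm` around its world
#' coordinate. A sample is *admitted* when the fraction of its sphere voxels
#' lying inside the background mask is strictly greater than
#' `overlap_threshold`; an admitted sample is assigned to the cluster label
#' holding the largest share of its sphere voxels (ties broken toward the
#' lowest cluster id, with a warning).
#'
#' @param sample_coords n x 3 matrix of world mm coordinates.
#' @param background_mask logical (or 0/1) 3-D array.
#' @param cluster_labels integer 3-D array of cluster ids (0 = none).
#' @param affine 4x4 voxel-to-world matrix.
#' @param radius_mm sphere radius, default 6 mm.
#' @param overlap_threshold admission threshold on the in-mask fraction,
#'   default 0.5 (strictly greater than).
#' @return data.frame with one row per sample: `sample` (row index),
#'   `n_sphere_voxels`, `overlap` (in-mask fraction), `cluster` (assigned id
#'   or `NA` if unadmitted or no labeled voxel in the sphere).
#' @export
map_samples_to_clusters <- function(sample_coords, background_mask,
                                    cluster_labels, affine, radius_mm = 6,
                                    overlap_threshold = 0.5) {
  sample_coords <- matrix(sample_coords, ncol = 3)
  if (!identical(dim(background_mask), dim(cluster_labels)))
    stop("mask and cluster labels must share one grid")
  dims <- dim(background_mask)
  n <- nrow(sample_coords)
  out <- data.frame(sample = seq_len(n), n_sphere_voxels = 0L,
                    overlap = NA_real_, cluster = NA_integer_)
  for (s in seq_len(n)) {
    vox <- suppressWarnings(
      voxelize_sphere(sample_coords[s, ], radius_mm, dims, affine))
    if (nrow(vox) == 0L) next
    idx <- vox[, 1] + dims[1] * (vox[, 2] - 1L) +
      dims[1] * dims[2] * (vox[, 3] - 1L)
    out$n_sphere_voxels[s] <- nrow(vox)
    out$overlap[s] <- mean(background_mask[idx] != 0)
    if (out$overlap[s] > overlap_threshold) {
      labs <- cluster_labels[idx]
      labs <- labs[labs > 0L]
      if (length(labs) > 0L) {
        tab <- table(labs)
        win <- which(tab == max(tab))
        if (length(win) > 1L)
          warning(sprintf("sample %d: cluster tie, taking lowest id", s))
        out$cluster[s] <- as.integer(names(tab)[win[1]])
      }
    }
  }
  out
}
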