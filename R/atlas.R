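#' Synthetic brain atlas fixture
#'
#' Generates a deterministic parcellation of a brain-like ellipsoid mask into
#' `n_rois` compact parcels, each assigned to one of `n_networks` networks.
#' Parcels are Voronoi cells grown from seed voxels sampled uniformly inside
#' the mask, so every parcel is non-empty and spatially compact. The network
#' assignment cycles through network ids in ROI order, which balances network
#' sizes up to a remainder.
#'
#' The voxel-to-world transform is a scaled identity (`voxel_size_mm` on the
#' diagonal) with a translation that places the world origin at the grid
#' centre, following the NIfTI convention that voxel indices are 0-based.
#'
#' @param n_rois number of regions of interest (parcels); default 246.
#' @param n_networks number of networks the ROIs are grouped into; default 17.
#' @param grid_shape integer vector of length 3, the label-grid dimensions.
#' @param voxel_size_mm isotropic voxel edge length in millimetres.
#' @param seed integer seed; the atlas is a pure function of its arguments.
#' @return An object of class `brain_atlas`: a list with `label_grid` (3-D
#'   integer array, 0 = background), `mask` (logical array), `voxel_size_mm`,
#'   `roi_ids`, `network_of_roi` (named integer vector, ROI id -> network id)
#'   and `affine` (4x4 voxel-to-world matrix, 0-based voxel indices).
#' @export
generate_atlas <- function(n_rois = 246L, n_networks = 17L,
                           grid_shape = c(40L, 48L, 40L),
                           voxel_size_mm = 3, seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            voxel_size_mm > 0, n_rois >= 1, n_networks >= 1)
  if (n_networks > n_rois)
    stop("n_networks must not exceed n_rois")

  mask <- ellipsoid_mask(grid_shape)
  mask_idx <- which(mask)
  if (length(mask_idx) < n_rois)
    stop(sprintf("grid too small: mask has %d voxels for %d ROIs",
                 length(mask_idx), n_rois))

  coords <- arrayInd(mask_idx, grid_shape)  # 1-based voxel coordinates
  seeds <- withr::with_seed(seed, sample(length(mask_idx), n_rois))
  seed_xyz <- coords[seeds, , drop = FALSE]

  # Voronoi assignment: nearest seed in voxel space, running minimum over
  # seeds to avoid an n_mask x n_rois distance matrix.
  best_d2 <- rep(Inf, length(mask_idx))
  label <- integer(length(mask_idx))
  for (j in seq_len(n_rois)) {
    d2 <- (coords[, 1] - seed_xyz[j, 1])^2 +
          (coords[, 2] - seed_xyz[j, 2])^2 +
          (coords[, 3] - seed_xyz[j, 3])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    label[upd] <- j
  }

  label_grid <- array(0L, dim = grid_shape)
  label_grid[mask_idx] <- label

  roi_ids <- seq_len(n_rois)
  network_of_roi <- rep_len(seq_len(n_networks), n_rois)
  names(network_of_roi) <- roi_ids

  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2

  structure(list(label_grid = label_grid, mask = mask,
                 voxel_size_mm = voxel_size_mm, roi_ids = roi_ids,
                 network_of_roi = network_of_roi, affine = affine,
                 n_networks = as.integer(n_networks), seed = seed),
            class = "brain_atlas")
}

# Ellipsoid inscribed in the grid with semi-axes 0.45 * dim (voxel units).
ellipsoid_mask <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  ax <- 0.45 * grid_shape
  i <- (seq_len(grid_shape[1]) - ctr[1]) / ax[1]
  j <- (seq_len(grid_shape[2]) - ctr[2]) / ax[2]
  k <- (seq_len(grid_shape[3]) - ctr[3]) / ax[3]
  outer(outer(i^2, j^2, `+`), k^2, `+`) <= 1
}

#' Per-network voxel label grid
#'
#' Relabels an atlas so each voxel carries its network id instead of its ROI
#' id. Used as the cluster-label volume for expression-sample mapping.
#'
#' @param atlas a `brain_atlas`.
#' @return 3-D integer array of network labels (0 = background).
#' @export
network_label_grid <- function(atlas) {
  stopifnot(inherits(atlas, "brain_atlas"))
  lut <- c(0L, as.integer(atlas$network_of_roi))
  array(lut[atlas$label_grid + 1L], dim = dim(atlas$label_grid))
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("brain_atlas: %d ROIs in %d networks, grid %s, %.1f mm voxels\n",
              length(x$roi_ids), x$n_networks,
              paste(dim(x$label_grid), collapse = "x"), x$voxel_size_mm))
  invisible(x)
}

#' Write an atlas (labels + mask) as NIfTI
#'
#' @param atlas a `brain_atlas`.
#' @param label_path,mask_path output file paths (`.nii` or `.nii.gz`).
#' @return invisibly, the two paths.
#' @export
write_atlas_nifti <- function(atlas, label_path, mask_path) {
  stopifnot(inherits(atlas, "brain_atlas"))
  write_volume_nifti(atlas$label_grid, atlas$affine, label_path)
  write_volume_nifti(atlas$mask + 0L, atlas$affine, mask_path)
  invisible(c(label_path, mask_path))
}

#' Write a 3-D volume as NIfTI with a given affine
#'
#' @param vol 3-D array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_volume_nifti <- function(vol, affine, path) {
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D volume from NIfTI
#'
#' @param path NIfTI file path.
#' @return list with `data` (3-D array) and `affine` (4x4 matrix).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}
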