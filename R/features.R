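#' Mean gray-matter volume per atlas ROI
#'
#' Reduces a voxelwise gray-matter map to one value per ROI: the unweighted
#' arithmetic mean of the map over the voxels carrying that ROI's label. The
#' map and atlas must share the voxel grid exactly; no resampling is
#' performed, so a shape mismatch is an error rather than a silent
#' interpolation.
#'
#' @param gm_map 3-D numeric array (a modulated, smoothed gray-matter map).
#' @param atlas a `brain_atlas`.
#' @return named numeric vector, one mean per `atlas$roi_ids` (in that order).
#' @export
extract_roi_means <- function(gm_map, atlas) {
  stopifnot(inherits(atlas, "brain_atlas"))
  if (!identical(dim(gm_map), dim(atlas$label_grid)))
    stop(sprintf("grid mismatch: map is %s, atlas is %s",
                 paste(dim(gm_map), collapse = "x"),
                 paste(dim(atlas$label_grid), collapse = "x")))
  if (!all(is.finite(gm_map[atlas$label_grid > 0])))
    stop("non-finite values inside labeled voxels")
  lab <- atlas$label_grid[atlas$label_grid > 0L]
  val <- gm_map[atlas$label_grid > 0L]
  sums <- rowsum(val, lab)
  counts <- tabulate(lab, nbins = max(atlas$roi_ids))
  present <- as.integer(rownames(sums))
  if (!all(atlas$roi_ids %in% present))
    stop(sprintf("ROI(s) %s have no voxels in the grid",
                 paste(setdiff(atlas$roi_ids, present), collapse = ", ")))
  means <- as.vector(sums[match(atlas$roi_ids, present), 1]) /
    counts[atlas$roi_ids]
  names(means) <- paste0("ROI", atlas$roi_ids)
  means
}

#' Build a subjects x ROI GMV table from voxelwise maps
#'
#' @param maps named list of 3-D gray-matter maps, one per subject; names are
#'   subject ids.
#' @param atlas a `brain_atlas`.
#' @return matrix (subjects x ROIs) with subject ids as rownames; column
#'   order follows `atlas$roi_ids`.
#' @export
gmv_table_from_maps <- function(maps, atlas) {
  stopifnot(is.list(maps), length(maps) >= 1)
  if (is.null(names(maps)))
    names(maps) <- sprintf("S%04d", seq_along(maps))
  out <- t(vapply(maps, extract_roi_means, numeric(length(atlas$roi_ids)),
                  atlas = atlas))
  rownames(out) <- names(maps)
  out
}

#' Total intracranial volume from tissue probability maps
#'
#' TIV is the summed gray-matter, white-matter and CSF volume: the voxelwise
#' sum of the three tissue fractions times the voxel volume, converted from
#' mm^3 to ml.
#'
#' @param gray,white,csf non-negative 3-D arrays on a common grid.
#' @param voxel_volume_mm3 volume of one voxel in mm^3.
#' @return TIV in millilitres.
#' @export
compute_tiv <- function(gray, white, csf, voxel_volume_mm3) {
  stopifnot(voxel_volume_mm3 > 0)
  if (!identical(dim(gray), dim(white)) || !identical(dim(gray), dim(csf)))
    stop("tissue maps must share one grid")
  if (min(gray, white, csf) < 0)
    stop("negative tissue fraction")
  sum(gray + white + csf) * voxel_volume_mm3 / 1000
}

#' Write / read a GMV table as tab-separated text
#'
#' @param gmv subjects x ROI matrix with subject rownames.
#' @param path file path.
#' @return `write_gmv_table()` returns `path` invisibly; `read_gmv_table()`
#'   returns the matrix.
#' @export
write_gmv_table <- function(gmv, path) {
  df <- data.frame(subject_id = rownames(gmv), gmv, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gmv_table
#' @export
read_gmv_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
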