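#' Remove one network's ROIs from a GMV table
#'
#' @param gmv subjects x ROI matrix whose columns follow the atlas ROI order.
#' @param network_of_roi integer vector mapping each column's ROI to its
#'   network id.
#' @param network_id the network to lesion.
#' @return the matrix without that network's columns, remaining column order
#'   preserved. A network with no assigned ROIs returns the table unchanged
#'   with a warning; removing the only network is an error.
#' @export
lesion_feature_set <- function(gmv, network_of_roi, network_id) {
  gmv <- as.matrix(gmv)
  network_of_roi <- as.integer(network_of_roi)
  stopifnot(length(network_of_roi) == ncol(gmv))
  drop_cols <- which(network_of_roi == network_id)
  if (length(drop_cols) == 0L) {
    warning(sprintf("network %s has no assigned ROIs; table unchanged",
                    network_id))
    return(gmv)
  }
  if (length(drop_cols) == ncol(gmv))
    stop("lesioning this network would leave no features")
  gmv[, -drop_cols, drop = FALSE]
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Tests `r1 = cor(x, y1)` against `r2 = cor(x, y2)` given
#' `r12 = cor(y1, y2)`, all estimated on the same n observations
#' (Steiger 1980, with the mean-correlation substitution):
#' `z_i = artanh(r_i)`, `rbar = (r1 + r2)/2`,
#' `psi = r12 (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r12^2) / 2`,
#' `c = psi / (1 - rbar^2)^2`,
#' `Z = (z1 - z2) sqrt(n - 3) / sqrt(2 - 2 c)`.
#'
#' @param r1,r2 the two dependent correlations, each in (-1, 1).
#' @param r12 correlation between the two non-shared variables, in (-1, 1).
#' @param n sample size (>= 4).
#' @return the Z statistic (positive when `r1 > r2`).
#' @export
steiger_z <- function(r1, r2, r12, n) {
  if (any(abs(c(r1, r2, r12)) >= 1))
    stop("correlations must lie strictly inside (-1, 1)")
  if (n < 4) stop("n must be at least 4")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rbar <- (r1 + r2) / 2
  psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
  cc <- psi / (1 - rbar^2)^2
  if (cc >= 1) stop("degenerate covariance between the two correlations")
  (z1 - z2) * sqrt(n - 3) / sqrt(2 - 2 * cc)
}

#' Two-tailed normal p-value for a Z statistic
#'
#' @param z finite Z value(s).
#' @return `2 (1 - Phi(|z|))`.
#' @export
z_to_p <- function(z) {
  stopifnot(all(is.finite(z)))
  2 * stats::pnorm(-abs(z))
}

#' Computational lesion analysis over brain networks
#'
#' Re-runs the cross-validated brain-age prediction once per network with
#' that network's ROIs excluded, reusing the full model's fold partitions
#' bit-for-bit so the comparison isolates the lesion (lesioned
#' hyperparameters are re-optimized). Each network is scored with Steiger's Z
#' comparing the age-prediction correlation of the full model (`r_full`)
#' against the lesioned model (`r_lesioned`), given the correlation between
#' the two prediction vectors (`r_pred`); the sign convention is
#' `Z = Z(r_full vs r_lesioned)`, so a *positive* Z means the lesion degraded
#' performance and a higher Z marks a more important network. Correlations
#' use the per-subject mean out-of-fold predictions across repeats; a
#' secondary per-repeat-averaged Z (`z_per_repeat`) is also reported.
#'
#' @param cohort a `cohort` (or a list with `gmv` matrix and `phenotypes`
#'   containing `age`).
#' @param atlas a `brain_atlas`.
#' @param k,repeats,seed,kernel,control cross-validation settings, as in
#'   [run_cv()].
#' @param full optional precomputed full-model [run_cv()] result on the same
#'   fold partitions (`make_folds(n, k, seed, repeats)`).
#' @return object of class `lesion_result`: list with `table` (data.frame
#'   ranked by Z descending: network, n_rois, r_full, r_lesioned, r_pred, z,
#'   p, z_per_repeat), `full` (the full-model `prediction_result`), and the
#'   CV settings.
#' @export
run_lesion_analysis <- function(cohort, atlas, k = 10L, repeats = 100L,
                                seed = 1L, kernel = "linear",
                                control = list(), full = NULL) {
  stopifnot(inherits(atlas, "brain_atlas"))
  gmv <- cohort$gmv
  ages <- cohort$phenotypes$age
  n <- nrow(gmv)
  net <- as.integer(atlas$network_of_roi)
  folds <- make_folds(n, k, seed, repeats)
  if (is.null(full))
    full <- run_cv(gmv, ages, seed = seed, kernel = kernel, folds = folds,
                   control = control)
  r_full <- stats::cor(ages, full$mean_predicted)

  nets <- seq_len(atlas$n_networks)
  rows <- lapply(nets, function(nw) {
    les_gmv <- lesion_feature_set(gmv, net, nw)
    if (identical(dim(les_gmv), dim(gmv))) {
      les <- full
    } else {
      les <- run_cv(les_gmv, ages, seed = seed, kernel = kernel,
                    folds = folds, control = control)
    }
    identical_pred <- isTRUE(all.equal(full$mean_predicted,
                                       les$mean_predicted,
                                       tolerance = 1e-12))
    r_les <- stats::cor(ages, les$mean_predicted)
    r_pred <- if (identical_pred) 1 else
      stats::cor(full$mean_predicted, les$mean_predicted)
    if (identical_pred) {
      z <- 0; p <- 1; z_rep <- 0
    } else {
      z <- steiger_z(r_full, r_les, r_pred, n)
      p <- z_to_p(z)
      z_rep <- mean(vapply(seq_len(nrow(full$predicted)), function(r) {
        pf <- full$predicted[r, ]; pl <- les$predicted[r, ]
        if (isTRUE(all.equal(pf, pl, tolerance = 1e-12))) return(0)
        steiger_z(stats::cor(ages, pf), stats::cor(ages, pl),
                  stats::cor(pf, pl), n)
      }, numeric(1)))
    }
    data.frame(network = nw, n_rois = sum(net == nw), r_full = r_full,
               r_lesioned = r_les, r_pred = r_pred, z = z, p = p,
               z_per_repeat = z_rep)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$z), ]
  rownames(tab) <- NULL
  structure(list(table = tab, full = full, k = k, repeats = repeats,
                 seed = seed, kernel = kernel,
                 steiger_variant = "Steiger (1980), shared variable, mean-r"),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf("lesion_result: %d networks, top network %d (Z=%.3f, p=%.3g)\n",
              nrow(x$table), x$table$network[1], x$table$z[1], x$table$p[1]))
  invisible(x)
}

#' Per-network mean-GMV vs age correlations
#'
#' @param cohort a `cohort`.
#' @param atlas a `brain_atlas`.
#' @return data.frame: network, n_rois, r (Pearson correlation of the
#'   network's mean GMV with age), p (two-tailed).
#' @export
network_age_correlations <- function(cohort, atlas) {
  stopifnot(inherits(atlas, "brain_atlas"))
  ages <- cohort$phenotypes$age
  if (length(ages) < 3) stop("need at least 3 subjects")
  net <- as.integer(atlas$network_of_roi)
  nets <- sort(unique(net))
  do.call(rbind, lapply(nets, function(nw) {
    cols <- which(net == nw)
    if (length(cols) == 0L) stop(sprintf("network %d is empty", nw))
    m <- rowMeans(cohort$gmv[, cols, drop = FALSE])
    ct <- stats::cor.test(ages, m)
    data.frame(network = nw, n_rois = length(cols),
               r = unname(ct$estimate), p = ct$p.value)
  }))
}
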