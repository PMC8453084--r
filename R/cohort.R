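#' Ground-truth parameters for synthetic aging cohorts
#'
#' Encodes the generative model behind [generate_cohort()]: each ROI's mean
#' gray-matter volume declines linearly with an *effective* age
#' `age + d + sex_effect * sex`, where `d ~ N(0, subject_sd)` is a latent
#' per-subject brain-age offset. The offset caps the achievable age-prediction
#' accuracy: even a perfect predictor recovers effective age, so the
#' population correlation between predicted and chronological age is
#' `sd(age) / sqrt(sd(age)^2 + subject_sd^2)`. With ages uniform on 19-80
#' (sd 17.6 years) the default `subject_sd = 9` places that ceiling at 0.89,
#' the design target for the cross-validated accuracy of the predictor.
#'
#' @param n_networks number of networks.
#' @param network_slopes per-network mean GMV slope (volume units per year);
#'   a scalar is recycled. All negative by default: gray matter atrophies
#'   with age in every network.
#' @param roi_slope_sd sd of per-ROI slopes around their network mean.
#' @param network_noise_sd per-network sd of ROI-level measurement noise
#'   (volume units); scalar recycled.
#' @param subject_sd sd (years) of the latent per-subject brain-age offset.
#' @param important_network network id given a boosted slope and shrunken
#'   noise, or `NA` for none.
#' @param important_slope_mult,important_noise_mult multipliers applied to the
#'   important network's slope magnitude and noise sd.
#' @param sex_effect brain-age shift (years) added to the effective age of
#'   subjects with sex code 1; 0 disables any sex effect.
#' @param sex_ratio probability of sex code 1 (1 = female, 0 = male).
#' @param baseline_mean,baseline_sd distribution of per-ROI intercepts
#'   (volume units at age 0).
#' @param tiv_mean,tiv_sd total-intracranial-volume distribution (ml),
#'   independent of age and GMV residuals.
#' @param seed integer seed used by [generate_cohort()].
#' @return object of class `cohort_truth`.
#' @export
cohort_truth <- function(n_networks = 17L,
                         network_slopes = -0.25,
                         roi_slope_sd = 0.05,
                         network_noise_sd = 3,
                         subject_sd = 9,
                         important_network = NA_integer_,
                         important_slope_mult = 1,
                         important_noise_mult = 1,
                         sex_effect = 0,
                         sex_ratio = 308 / 495,
                         baseline_mean = 100, baseline_sd = 5,
                         tiv_mean = 1450, tiv_sd = 120,
                         seed = 1L) {
  n_networks <- as.integer(n_networks)
  network_slopes <- rep_len(network_slopes, n_networks)
  network_noise_sd <- rep_len(network_noise_sd, n_networks)
  stopifnot(all(network_noise_sd >= 0), roi_slope_sd >= 0, subject_sd >= 0,
            sex_ratio >= 0, sex_ratio <= 1, tiv_sd >= 0)
  if (!is.na(important_network) &&
      !(important_network %in% seq_len(n_networks)))
    stop("important_network is not a valid network id")
  structure(list(n_networks = n_networks, network_slopes = network_slopes,
                 roi_slope_sd = roi_slope_sd,
                 network_noise_sd = network_noise_sd,
                 subject_sd = subject_sd,
                 important_network = important_network,
                 important_slope_mult = important_slope_mult,
                 important_noise_mult = important_noise_mult,
                 sex_effect = sex_effect, sex_ratio = sex_ratio,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 tiv_mean = tiv_mean, tiv_sd = tiv_sd,
                 seed = as.integer(seed)),
            class = "cohort_truth")
}

#' Truth for a cohort whose age signal sits in a single network
#'
#' Convenience constructor for planted-network recovery studies: the planted
#' network keeps the default atrophy slope while every other network's slope
#' is zero, so its ROIs are the only informative features.
#'
#' @param n_networks number of networks.
#' @param planted_network the network carrying the age signal.
#' @param slope the planted network's slope (volume units per year).
#' @param ... passed on to [cohort_truth()].
#' @return object of class `cohort_truth`.
#' @export
planted_network_truth <- function(n_networks = 17L, planted_network = 1L,
                                  slope = -0.25, ...) {
  slopes <- rep(0, n_networks)
  slopes[planted_network] <- slope
  cohort_truth(n_networks = n_networks, network_slopes = slopes,
               important_network = planted_network, ...)
}

#' Generate a synthetic aging cohort
#'
#' Draws `n_subjects` ages uniformly over `age_range` and builds a
#' subjects x ROI gray-matter-volume matrix
#' `gmv[i, j] = b0[j] + b1[j] * age_eff[i] + eps[i, j]`,
#' with per-ROI slopes `b1[j]` drawn around the network slope of ROI `j`'s
#' network, ROI noise `eps` Gaussian with the network's noise sd, and
#' `age_eff` the effective age described in [cohort_truth()]. TIV and sex are
#' drawn independently of the GMV residuals.
#'
#' @param atlas a `brain_atlas`; its ROI/network structure shapes the matrix.
#' @param n_subjects cohort size (>= 10 so cross-validation is feasible).
#' @param age_range numeric `(lo, hi)` in years, `lo < hi`.
#' @param truth a [cohort_truth()]; must match the atlas's network count.
#' @return object of class `cohort`: list with `phenotypes` (data.frame:
#'   subject_id, age, sex, tiv), `gmv` (matrix, rownames = subjects,
#'   colnames = ROI ids), and `truth`.
#' @export
generate_cohort <- function(atlas, n_subjects = 492L, age_range = c(19, 80),
                            truth = cohort_truth(atlas$n_networks)) {
  stopifnot(inherits(atlas, "brain_atlas"), inherits(truth, "cohort_truth"),
            length(age_range) == 2, age_range[1] < age_range[2])
  if (truth$n_networks != atlas$n_networks)
    stop("truth and atlas disagree on the number of networks")
  if (n_subjects < 10)
    stop("n_subjects must be >= 10 (cross-validation infeasible below that)")

  n_roi <- length(atlas$roi_ids)
  net <- as.integer(atlas$network_of_roi)

  slopes <- truth$network_slopes
  noise <- truth$network_noise_sd
  if (!is.na(truth$important_network)) {
    slopes[truth$important_network] <-
      slopes[truth$important_network] * truth$important_slope_mult
    noise[truth$important_network] <-
      noise[truth$important_network] * truth$important_noise_mult
  }

  withr::with_seed(truth$seed, {
    age <- stats::runif(n_subjects, age_range[1], age_range[2])
    sex <- stats::rbinom(n_subjects, 1L, truth$sex_ratio)
    tiv <- stats::rnorm(n_subjects, truth$tiv_mean, truth$tiv_sd)
    d <- stats::rnorm(n_subjects, 0, truth$subject_sd)
    b0 <- stats::rnorm(n_roi, truth$baseline_mean, truth$baseline_sd)
    b1 <- stats::rnorm(n_roi, slopes[net], truth$roi_slope_sd)
    eps <- matrix(stats::rnorm(n_subjects * n_roi, 0,
                               rep(noise[net], each = n_subjects)),
                  n_subjects, n_roi)
    age_eff <- age + d + truth$sex_effect * sex
    gmv <- rep(1, n_subjects) %o% b0 + age_eff %o% b1 + eps
  })

  subject_ids <- sprintf("S%04d", seq_len(n_subjects))
  dimnames(gmv) <- list(subject_ids, paste0("ROI", atlas$roi_ids))
  phen <- data.frame(subject_id = subject_ids, age = age, sex = sex,
                     tiv = tiv, stringsAsFactors = FALSE)
  structure(list(phenotypes = phen, gmv = gmv, truth = truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, %d ROIs, ages %.1f-%.1f\n",
              nrow(x$gmv), ncol(x$gmv),
              min(x$phenotypes$age), max(x$phenotypes$age)))
  invisible(x)
}
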