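#' Seeded k-fold partitions
#'
#' One partition per repeat: subjects are permuted with a seed advanced by
#' the repeat index and cut into k contiguous blocks whose sizes differ by at
#' most one, so full and lesioned runs can share partitions bit-for-bit.
#'
#' @param n number of subjects.
#' @param k number of folds (2 <= k <= n).
#' @param seed base integer seed; repeat r uses `seed + r - 1`.
#' @param repeats number of partitions.
#' @return list of length `repeats`; each element is a list of `k` integer
#'   index vectors.
#' @export
make_folds <- function(n, k, seed, repeats = 1L) {
  stopifnot(k >= 2, k <= n)
  lapply(seq_len(repeats), function(r) {
    perm <- withr::with_seed(as.integer(seed) + r - 1L, sample.int(n))
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    split(perm, rep(seq_len(k), sizes))
  })
}

#' Repeated k-fold cross-validated brain-age prediction
#'
#' For every repeat, subjects are partitioned into `k` folds; a GP regression
#' model is fitted on k-1 folds (feature standardization and target centring
#' computed on the training folds only, inside [fit_gpr()]) and predicts the
#' held-out fold, so each subject is predicted exactly once per repeat.
#' Headline metrics (MAE, Pearson correlation with chronological age) are
#' computed on the per-subject *mean* out-of-fold prediction across repeats;
#' per-repeat metrics are retained as well. The brain-predicted age
#' difference (brain-PAD) is mean predicted minus chronological age.
#'
#' @param gmv subjects x ROI feature matrix.
#' @param ages chronological ages (years).
#' @param k folds, default 10.
#' @param repeats number of repeats, default 100.
#' @param seed integer seed for the fold partitions.
#' @param kernel passed to [fit_gpr()].
#' @param folds optional precomputed partitions from [make_folds()]
#'   (overrides `k`, `repeats`, `seed`); used to share partitions between
#'   full and lesioned runs.
#' @param control optimizer control passed to [fit_gpr()].
#' @return object of class `prediction_result`: list with `predicted`
#'   (repeats x subjects matrix), `mean_predicted`, `age`, `brain_pad`,
#'   `mae`, `r` (on mean predictions), `mae_per_repeat`, `r_per_repeat`,
#'   and metadata (`k`, `repeats`, `seed`, `kernel`).
#' @export
run_cv <- function(gmv, ages, k = 10L, repeats = 100L, seed = 1L,
                   kernel = "linear", folds = NULL, control = list()) {
  gmv <- as.matrix(gmv)
  n <- nrow(gmv)
  stopifnot(length(ages) == n)
  if (!all(is.finite(gmv)) || !all(is.finite(ages)))
    stop("non-finite features or ages")
  if (is.null(folds)) {
    folds <- make_folds(n, k, seed, repeats)
  } else {
    repeats <- length(folds)
    k <- length(folds[[1]])
  }
  if (k > n) stop("more folds than subjects")

  predicted <- matrix(NA_real_, repeats, n)
  for (r in seq_len(repeats)) {
    for (fold in folds[[r]]) {
      train <- setdiff(seq_len(n), fold)
      model <- fit_gpr(gmv[train, , drop = FALSE], ages[train],
                       kernel = kernel, control = control)
      predicted[r, fold] <- predict_gpr(model, gmv[fold, , drop = FALSE])
    }
  }
  stopifnot(!anyNA(predicted))

  mean_pred <- colMeans(predicted)
  structure(list(predicted = predicted, mean_predicted = mean_pred,
                 age = ages, brain_pad = mean_pred - ages,
                 mae = mean(abs(mean_pred - ages)),
                 r = stats::cor(ages, mean_pred),
                 mae_per_repeat = rowMeans(abs(sweep(predicted, 2, ages))),
                 r_per_repeat = apply(predicted, 1, stats::cor, y = ages),
                 k = k, repeats = repeats, seed = seed, kernel = kernel),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "prediction_result: n=%d, %d-fold x %d repeats, MAE=%.2f y, r=%.3f\n",
    length(x$age), x$k, x$repeats, x$mae, x$r))
  invisible(x)
}

#' Sex difference in brain-PAD, controlling for age and age^2
#'
#' Regresses brain-PAD on age and age squared by least squares, then compares
#' the residuals between the two sex groups with a pooled-variance two-sample
#' t-test.
#'
#' @param brain_pad per-subject brain-PAD scores.
#' @param sex binary codes (two levels present).
#' @param age chronological ages.
#' @return list of class `covariate_test`: `test`, `statistic`, `p`, `df`.
#' @export
test_sex_difference <- function(brain_pad, sex, age) {
  stopifnot(length(brain_pad) == length(sex), length(sex) == length(age))
  if (length(unique(sex)) != 2)
    stop("both sexes must be present")
  res <- stats::resid(stats::lm(brain_pad ~ age + I(age^2)))
  if (stats::sd(res) < 1e-12)
    stop("degenerate brain-PAD: zero residual variance")
  tt <- stats::t.test(res ~ sex, var.equal = TRUE)
  structure(list(test = "two-sample t (brain-PAD ~ sex | age + age^2)",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter)),
            class = "covariate_test")
}

#' Correlation between TIV and brain-PAD
#'
#' Pearson correlation with the usual t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` for the two-tailed p-value.
#'
#' @param brain_pad per-subject brain-PAD scores.
#' @param tiv total intracranial volumes (ml).
#' @return list of class `covariate_test`: `test`, `statistic` (r), `p`, `n`.
#' @export
test_tiv_association <- function(brain_pad, tiv) {
  stopifnot(length(brain_pad) == length(tiv))
  n <- length(tiv)
  if (n < 3) stop("need at least 3 subjects")
  if (stats::sd(tiv) < 1e-12 || stats::sd(brain_pad) < 1e-12)
    stop("zero-variance input")
  ct <- stats::cor.test(brain_pad, tiv)
  structure(list(test = "Pearson correlation (brain-PAD, TIV)",
                 statistic = unname(ct$estimate), p = ct$p.value, n = n),
            class = "covariate_test")
}

#' @export
print.covariate_test <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4f, p=%.4g\n", x$test, x$statistic, x$p))
  invisible(x)
}
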