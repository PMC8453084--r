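#' Gaussian-process-regression hyperparameters
#'
#' The default kernel is linear + bias + white noise,
#' `k(x, x') = sigma_f^2 x.x' + sigma_b^2`, with observation noise
#' `sigma_n^2 I` — the standard choice for high-dimensional regional-volume
#' brain-age models, where the number of features is comparable to the number
#' of subjects and the age signal is close to linear. `kernel = "linear+rbf"`
#' adds an isotropic squared-exponential component
#' `sigma_f^2 exp(-||x - x'||^2 / (2 l^2))` sharing the signal scale.
#' All scales are positive and are optimized on the log scale.
#'
#' @param kernel `"linear"` or `"linear+rbf"`.
#' @param sigma_f signal scale.
#' @param sigma_b bias scale.
#' @param sigma_n observation-noise sd.
#' @param length_scale RBF length-scale (only used by `"linear+rbf"`).
#' @return object of class `gpr_hyperparams`.
#' @export
gpr_hyperparams <- function(kernel = c("linear", "linear+rbf"),
                            sigma_f = 1, sigma_b = 1, sigma_n = 0.1,
                            length_scale = 1) {
  kernel <- match.arg(kernel)
  stopifnot(sigma_f > 0, sigma_b > 0, sigma_n > 0, length_scale > 0,
            is.finite(sigma_f + sigma_b + sigma_n + length_scale))
  structure(list(kernel = kernel, sigma_f = sigma_f, sigma_b = sigma_b,
                 sigma_n = sigma_n, length_scale = length_scale),
            class = "gpr_hyperparams")
}

hp_to_theta <- function(hp) {
  if (hp$kernel == "linear") {
    log(c(sigma_f = hp$sigma_f, sigma_b = hp$sigma_b, sigma_n = hp$sigma_n))
  } else {
    log(c(sigma_f = hp$sigma_f, sigma_b = hp$sigma_b,
          length_scale = hp$length_scale, sigma_n = hp$sigma_n))
  }
}

theta_to_hp <- function(theta, kernel) {
  e <- exp(theta)
  if (kernel == "linear") {
    gpr_hyperparams("linear", e[1], e[2], e[3])
  } else {
    gpr_hyperparams("linear+rbf", e[1], e[2], e[4], e[3])
  }
}

#' Kernel (covariance) matrix
#'
#' @param X1,X2 feature matrices with a common number of columns.
#' @param hyperparams a [gpr_hyperparams()].
#' @return `nrow(X1)` x `nrow(X2)` covariance matrix.
#' @export
kernel_matrix <- function(X1, X2, hyperparams) {
  stopifnot(inherits(hyperparams, "gpr_hyperparams"))
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2))
    stop("feature dimension mismatch")
  K <- hyperparams$sigma_f^2 * tcrossprod(X1, X2) + hyperparams$sigma_b^2
  if (hyperparams$kernel == "linear+rbf") {
    d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
    d2[d2 < 0] <- 0
    K <- K + hyperparams$sigma_f^2 *
      exp(-d2 / (2 * hyperparams$length_scale^2))
  }
  K
}

chol_with_jitter <- function(M) {
  # plain factorization first; jitter only rescues a borderline matrix
  L <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(L)) {
    n <- nrow(M)
    jit <- 1e-8 * sum(diag(M)) / n
    L <- tryCatch(chol(M + diag(jit, n)), error = function(e) NULL)
    if (is.null(L))
      L <- tryCatch(chol(M + diag(10 * jit, n)), error = function(e) NULL)
  }
  if (is.null(L))
    stop("covariance not positive definite after jitter")
  L
}

#' Log marginal likelihood of a GP regression model
#'
#' Evaluates `-1/2 y' (K + sigma_n^2 I)^-1 y - 1/2 log det(K + sigma_n^2 I)
#' - (n/2) log 2 pi` together with its gradient with respect to the
#' log-hyperparameters (via the standard trace identity). `y` is expected to
#' be centred by the training mean.
#'
#' @param hyperparams a [gpr_hyperparams()].
#' @param X feature matrix (n x p).
#' @param y centred targets, length n.
#' @return list with `value` (scalar) and `gradient` (named numeric vector
#'   over the log-hyperparameters).
#' @export
log_marginal_likelihood <- function(hyperparams, X, y) {
  stopifnot(inherits(hyperparams, "gpr_hyperparams"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  sf2 <- hyperparams$sigma_f^2
  sb2 <- hyperparams$sigma_b^2
  sn2 <- hyperparams$sigma_n^2
  lin <- tcrossprod(X)
  K <- sf2 * lin + sb2
  rbf <- NULL
  if (hyperparams$kernel == "linear+rbf") {
    d2 <- outer(rowSums(X^2), rowSums(X^2), `+`) - 2 * lin
    d2[d2 < 0] <- 0
    rbf <- exp(-d2 / (2 * hyperparams$length_scale^2))
    K <- K + sf2 * rbf
  }
  L <- chol_with_jitter(K + diag(sn2, n))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  value <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv
  g <- c(sigma_f = sf2 * sum(W * (lin + if (is.null(rbf)) 0 else rbf)),
         sigma_b = sb2 * sum(W),
         sigma_n = sn2 * sum(diag(W)))
  if (!is.null(rbf)) {
    g <- c(g[1:2],
           length_scale = 0.5 * sf2 *
             sum(W * (rbf * d2 / hyperparams$length_scale^2)),
           g[3])
  }
  list(value = value, gradient = g)
}

# Weight-space (primal) evaluation of the same marginal likelihood for the
# linear+bias kernel: O(q^3) per evaluation after an O(n q^2) precomputation,
# q = p + 1. Exact — identical to the dual value up to round-off.
primal_precompute <- function(X, y) {
  Phi <- cbind(X, 1)
  G <- crossprod(Phi)
  q <- ncol(Phi)
  list(Phi = Phi, G = G, q = q, p = q - 1L, n = nrow(X),
       H = tcrossprod(G[, seq_len(q - 1L), drop = FALSE]),
       g1 = G[, q], trXX = sum(diag(G)[seq_len(q - 1L)]),
       Py = crossprod(Phi, y)[, 1], yy = sum(y^2))
}

primal_value <- function(theta, pre) {
  sf2 <- exp(2 * theta[1]); sb2 <- exp(2 * theta[2]); sn2 <- exp(2 * theta[3])
  p <- pre$p; q <- pre$q; n <- pre$n
  a <- c(rep(sf2, p), sb2)
  Z <- pre$G + diag(sn2 / a, q)
  L <- tryCatch(chol(Z), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  u <- backsolve(L, forwardsolve(t(L), pre$Py))
  uPy <- sum(u * pre$Py)
  quad <- (pre$yy - uPy) / sn2
  logdet <- (n - q) * log(sn2) + 2 * sum(log(diag(L))) + sum(log(a))
  list(value = -0.5 * quad - 0.5 * logdet - n / 2 * log(2 * pi),
       u = u, L = L, uPy = uPy, sf2 = sf2, sb2 = sb2, sn2 = sn2)
}

primal_gradient <- function(val, pre) {
  p <- pre$p; q <- pre$q; n <- pre$n
  sn2 <- val$sn2
  u <- val$u
  Gu <- pre$G %*% u
  w <- (pre$Py - Gu)[, 1] / sn2
  Zi <- chol2inv(val$L)
  trX <- (pre$trXX - sum(Zi * pre$H)) / sn2
  trJ <- (n - sum(pre$g1 * (Zi %*% pre$g1))) / sn2
  trI <- (n - sum(Zi * pre$G)) / sn2
  alpha2 <- (pre$yy - 2 * val$uPy + sum(u * Gu)) / sn2^2
  c(val$sf2 * (sum(w[seq_len(p)]^2) - trX),
    val$sb2 * (w[q]^2 - trJ),
    sn2 * (alpha2 - trI))
}

primal_lml <- function(theta, pre, grad = TRUE) {
  val <- primal_value(theta, pre)
  if (is.null(val)) return(NULL)
  if (grad) val$gradient <- primal_gradient(val, pre)
  val
}

#' Fit a GP regression model by marginal-likelihood maximization
#'
#' Features are z-scored and targets centred internally using the supplied
#' (training) data; the stored statistics are reapplied at prediction time.
#' Hyperparameters are optimized by Polak-Ribiere conjugate gradients on the
#' log scale with analytic gradients. For the linear kernel the marginal
#' likelihood is evaluated in weight space (cost cubic in the number of
#' features plus one pass over the data) whenever that is cheaper than the
#' kernel-space form; the two forms are algebraically identical.
#'
#' @param X training feature matrix (n x p), n >= 2.
#' @param y training targets, length n.
#' @param kernel `"linear"` (default) or `"linear+rbf"`.
#' @param init optional [gpr_hyperparams()] starting point; default
#'   `sigma_f = sigma_b = 1`, `sigma_n = 0.1 sd(y)`.
#' @param control optimizer settings: `maxit` (default 50) and `reltol`
#'   (default 1e-7) passed to conjugate gradients.
#' @param optimize if `FALSE`, skip hyperparameter optimization and condition
#'   the model on `init` as given.
#' @return object of class `gpr_model`.
#' @export
fit_gpr <- function(X, y, kernel = c("linear", "linear+rbf"), init = NULL,
                    control = list(), optimize = TRUE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite features or targets")

  xm <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[!is.finite(xs) | xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, `/`)
  ym <- mean(y)
  yc <- y - ym

  base <- list(X = X, x_center = xm, x_scale = xs, y_mean = ym,
               n = n, p = ncol(X), kernel = kernel)

  if (stats::sd(y) < 1e-12) {
    # degenerate targets: the posterior mean is the training mean everywhere
    hp <- gpr_hyperparams(kernel, 1, 1, 1e-3)
    model <- c(base, list(hyperparams = hp, degenerate = TRUE))
    class(model) <- "gpr_model"
    return(model)
  }

  if (is.null(init))
    init <- gpr_hyperparams(kernel, 1, 1, 0.1 * stats::sd(y))
  theta0 <- hp_to_theta(init)

  use_primal <- kernel == "linear" && ncol(Xs) + 1L < n
  if (use_primal) {
    pre <- primal_precompute(Xs, yc)
    evaluate <- function(theta) primal_value(theta, pre)
    finish_grad <- function(val) primal_gradient(val, pre)
  } else {
    evaluate <- function(theta) {
      hp <- theta_to_hp(theta, kernel)
      tryCatch(log_marginal_likelihood(hp, Xs, yc), error = function(e) NULL)
    }
    finish_grad <- function(val) val$gradient
  }

  # gradients are completed lazily: line-search calls only need the value
  cache <- new.env(parent = emptyenv())
  cache$best <- list(value = -Inf, theta = theta0)
  eval_cached <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta))
      return(cache$res)
    res <- if (any(!is.finite(theta)) || any(abs(theta) > 25)) NULL
           else evaluate(theta)
    cache$theta <- theta
    cache$res <- res
    if (!is.null(res) && is.finite(res$value) &&
        res$value > cache$best$value)
      cache$best <- list(value = res$value, theta = theta)
    res
  }
  fn <- function(theta) {
    res <- eval_cached(theta)
    if (is.null(res) || !is.finite(res$value)) 1e10 else -res$value
  }
  gr <- function(theta) {
    res <- eval_cached(theta)
    if (is.null(res) || !is.finite(res$value)) return(rep(0, length(theta)))
    if (is.null(res$gradient)) {
      res$gradient <- finish_grad(res)
      cache$res <- res
    }
    -res$gradient
  }

  if (optimize) {
    ctl <- list(type = 2, maxit = 50, reltol = 1e-7)
    ctl[names(control)] <- control
    opt <- stats::optim(theta0, fn, gr, method = "CG", control = ctl)
    theta <- opt$par
    if (!is.finite(opt$value) || opt$value >= 1e10) {
      if (!is.finite(cache$best$value))
        stop("GPR optimizer diverged; no finite marginal likelihood found")
      theta <- cache$best$theta
    } else if (cache$best$value > -opt$value) {
      theta <- cache$best$theta
    }
    convergence <- opt$convergence
    counts <- opt$counts
  } else {
    theta <- theta0
    if (!is.finite(fn(theta)))
      stop("marginal likelihood not finite at the supplied hyperparameters")
    convergence <- NA_integer_
    counts <- c(`function` = 1L, gradient = 0L)
  }
  hp <- theta_to_hp(theta, kernel)

  model <- c(base, list(hyperparams = hp, degenerate = FALSE,
                        log_marginal = cache$best$value,
                        convergence = convergence,
                        counts = counts))
  if (use_primal) {
    final <- primal_lml(theta, pre, grad = FALSE)
    model$path <- "primal"
    model$beta <- final$u       # posterior mean weights in (X, 1) basis
    model$cholZ <- final$L
  } else {
    Ky <- kernel_matrix(Xs, Xs, hp) + diag(hp$sigma_n^2, n)
    L <- chol_with_jitter(Ky)
    model$path <- "dual"
    model$Xs <- Xs
    model$cholK <- L
    model$alpha <- backsolve(L, forwardsolve(t(L), yc))
  }
  class(model) <- "gpr_model"
  model
}

#' Predict from a fitted GP regression model
#'
#' @param model a `gpr_model` from [fit_gpr()].
#' @param Xnew matrix of new feature rows (may be empty).
#' @param se if `TRUE`, also return the latent predictive sd.
#' @return numeric vector of predicted targets, or (with `se`) a list with
#'   `mean` and `sd`.
#' @export
predict_gpr <- function(model, Xnew, se = FALSE) {
  stopifnot(inherits(model, "gpr_model"))
  Xnew <- as.matrix(Xnew)
  if (nrow(Xnew) > 0 && ncol(Xnew) != model$p)
    stop("feature dimension mismatch")
  if (nrow(Xnew) == 0)
    return(if (se) list(mean = numeric(0), sd = numeric(0)) else numeric(0))
  Xn <- sweep(sweep(Xnew, 2, model$x_center), 2, model$x_scale, `/`)
  if (isTRUE(model$degenerate)) {
    mu <- rep(model$y_mean, nrow(Xn))
    if (se) return(list(mean = mu, sd = rep(0, nrow(Xn))))
    return(mu)
  }
  hp <- model$hyperparams
  if (model$path == "primal") {
    Pn <- cbind(Xn, 1)
    mu <- as.vector(Pn %*% model$beta) + model$y_mean
    if (!se) return(mu)
    V <- backsolve(model$cholZ, forwardsolve(t(model$cholZ), t(Pn)))
    sd <- sqrt(pmax(0, hp$sigma_n^2 * colSums(t(Pn) * V)))
    return(list(mean = mu, sd = sd))
  }
  ks <- kernel_matrix(Xn, model$Xs, hp)
  mu <- as.vector(ks %*% model$alpha) + model$y_mean
  if (!se) return(mu)
  v <- forwardsolve(t(model$cholK), t(ks))
  kss <- hp$sigma_f^2 * (rowSums(Xn^2) +
           (hp$kernel == "linear+rbf")) + hp$sigma_b^2
  sd <- sqrt(pmax(0, kss - colSums(v^2)))
  list(mean = mu, sd = sd)
}

#' @export
print.gpr_model <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(
    "gpr_model (%s, %s): n=%d p=%d  sigma_f=%.3g sigma_b=%.3g sigma_n=%.3g\n",
    hp$kernel, if (isTRUE(x$degenerate)) "degenerate" else x$path,
    x$n, x$p, hp$sigma_f, hp$sigma_b, hp$sigma_n))
  invisible(x)
}
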