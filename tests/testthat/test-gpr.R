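test_that("kernel matrix matches its definition", {
  hp <- gpr_hyperparams("linear", sigma_f = 2, sigma_b = 3, sigma_n = 1)
  # zero input -> bias only
  expect_equal(kernel_matrix(matrix(0, 1, 4), matrix(0, 1, 4), hp),
               matrix(9, 1, 1))
  # orthonormal rows with sigma_f = 1, sigma_b -> 0
  hp1 <- gpr_hyperparams("linear", 1, 1e-8, 1)
  expect_equal(kernel_matrix(diag(2), diag(2), hp1), diag(2),
               tolerance = 1e-10)
  # brute-force pairwise oracle, both kernels
  set.seed(1)
  X1 <- matrix(rnorm(12), 4, 3)
  X2 <- matrix(rnorm(15), 5, 3)
  for (kern in c("linear", "linear+rbf")) {
    hp2 <- gpr_hyperparams(kern, 1.4, 0.6, 0.5, length_scale = 1.3)
    K <- kernel_matrix(X1, X2, hp2)
    for (i in 1:4) for (j in 1:5) {
      kij <- 1.4^2 * sum(X1[i, ] * X2[j, ]) + 0.6^2
      if (kern == "linear+rbf")
        kij <- kij + 1.4^2 * exp(-sum((X1[i, ] - X2[j, ])^2) / (2 * 1.3^2))
      expect_equal(K[i, j], kij, tolerance = 1e-12)
    }
  }
  expect_error(kernel_matrix(X1, matrix(0, 2, 2), hp), "dimension")
})

test_that("log marginal likelihood matches the n = 1 closed form", {
  hp <- gpr_hyperparams("linear", sigma_f = 1, sigma_b = 1, sigma_n = 1)
  y <- 0.7
  got <- log_marginal_likelihood(hp, matrix(0, 1, 1), y)
  expect_equal(got$value, -0.5 * y^2 / 2 - 0.5 * log(2) - 0.5 * log(2 * pi),
               tolerance = 1e-7)
})

test_that("marginal-likelihood gradients match finite differences", {
  set.seed(4)
  X <- matrix(rnorm(30), 6, 5)
  y <- rnorm(6)
  for (kern in c("linear", "linear+rbf")) {
    hp <- gpr_hyperparams(kern, 1.2, 0.8, 0.5, length_scale = 0.9)
    got <- log_marginal_likelihood(hp, X, y)
    theta <- log(c(hp$sigma_f, hp$sigma_b,
                   if (kern == "linear+rbf") hp$length_scale else NULL,
                   hp$sigma_n))
    make_hp <- function(th) {
      e <- exp(th)
      if (kern == "linear") gpr_hyperparams(kern, e[1], e[2], e[3])
      else gpr_hyperparams(kern, e[1], e[2], e[4], e[3])
    }
    for (j in seq_along(theta)) {
      h <- 1e-6
      up <- theta; up[j] <- up[j] + h
      dn <- theta; dn[j] <- dn[j] - h
      fd <- (log_marginal_likelihood(make_hp(up), X, y)$value -
               log_marginal_likelihood(make_hp(dn), X, y)$value) / (2 * h)
      expect_equal(unname(got$gradient[j]), fd, tolerance = 1e-5)
    }
  }
})

test_that("weight-space and kernel-space evaluations agree", {
  set.seed(8)
  X <- matrix(rnorm(60), 12, 5)
  y <- rnorm(12)
  for (theta in list(log(c(1, 1, 0.5)), log(c(2.3, 0.4, 1.7)),
                     c(-1.2, 0.3, -0.8))) {
    pre <- netbrainage:::primal_precompute(X, y - mean(y))
    pri <- netbrainage:::primal_lml(theta, pre)
    e <- exp(theta)
    dual <- log_marginal_likelihood(gpr_hyperparams("linear", e[1], e[2], e[3]),
                                    X, y - mean(y))
    expect_equal(pri$value, dual$value, tolerance = 1e-6)
    expect_equal(unname(pri$gradient), unname(dual$gradient),
                 tolerance = 1e-5)
  }
})

test_that("fitting recovers noiseless linear data", {
  set.seed(2)
  X <- matrix(rnorm(200), 40, 5)
  w <- rnorm(5)
  y <- as.vector(X %*% w) + 3
  m <- fit_gpr(X, y)
  expect_lt(m$hyperparams$sigma_n, 0.05 * sd(y))
  expect_lt(mean(abs(predict_gpr(m, X) - y)), 1e-3)
})

test_that("degenerate and deterministic fits behave", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  m <- fit_gpr(X, rep(5, 10))
  expect_equal(predict_gpr(m, X), rep(5, 10))
  y <- rnorm(10)
  m1 <- fit_gpr(X, y)
  m2 <- fit_gpr(X, y)
  expect_identical(m1$hyperparams, m2$hyperparams)
  expect_identical(predict_gpr(m1, X), predict_gpr(m2, X))
})

test_that("prediction interpolates training targets as noise vanishes", {
  set.seed(5)
  X <- matrix(rnorm(24), 8, 3)
  y <- as.vector(X %*% c(1, -2, 0.5))        # noiseless target
  m <- fit_gpr(X, y, kernel = "linear+rbf")  # kernel-space path
  expect_lt(max(abs(predict_gpr(m, X) - y)), 1e-3)
  sd_at_train <- predict_gpr(m, X, se = TRUE)$sd
  expect_true(all(sd_at_train < 0.1 * sd(y)))
})

test_that("predictive means match an independent dense solve", {
  set.seed(6)
  for (p in c(2, 6)) {
    X <- matrix(rnorm(8 * p), 8, p)
    y <- rnorm(8, mean = 50, sd = 10)
    Xnew <- matrix(rnorm(3 * p), 3, p)
    m <- fit_gpr(X, y, init = gpr_hyperparams("linear", 1.5, 0.7, 0.4),
                 optimize = FALSE)
    expect_lt(max(abs(predict_gpr(m, Xnew) - gpr_mean_oracle(m, X, y, Xnew))),
              1e-8)
    # optimized hyperparameters can sit near an interpolating optimum, so
    # allow round-off amplification there
    mo <- fit_gpr(X, y)
    expect_lt(max(abs(predict_gpr(mo, Xnew) -
                        gpr_mean_oracle(mo, X, y, Xnew))), 1e-6)
  }
  m <- fit_gpr(matrix(rnorm(20), 10, 2), rnorm(10))
  expect_identical(predict_gpr(m, matrix(numeric(0), 0, 2)), numeric(0))
  expect_error(predict_gpr(m, matrix(0, 1, 5)), "dimension")
})

test_that("a constant shift of the targets keeps the fit finite", {
  set.seed(9)
  X <- matrix(rnorm(50), 10, 5)
  y <- rnorm(10)
  m1 <- fit_gpr(X, y)
  m2 <- fit_gpr(X, y + 100)
  expect_true(is.finite(m2$log_marginal))
  expect_equal(predict_gpr(m2, X), predict_gpr(m1, X) + 100, tolerance = 0.1)
})
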