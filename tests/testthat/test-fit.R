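# Per-group least-squares deconvolution and variance estimation.

test_that("single constant predictor reduces to the sample mean", {
  fit <- fit_cell_type_expression(rbind(g1 = c(1, 2, 3)),
                                  matrix(1, 3, 1,
                                         dimnames = list(NULL, "c1")))
  expect_equal(unname(fit$betas[1, 1]), 2)
  expect_equal(unname(fit$mse), 1)            # ((-1)^2 + 0 + 1^2) / (3 - 1)
  expect_equal(unname(fit$coef_var[1, 1]), 1 / 3)
})

test_that("noise-free expression is recovered exactly", {
  ts <- toy_study()
  Y <- ts$betas %*% t(ts$proportions)
  fit <- fit_cell_type_expression(Y, ts$proportions)
  expect_equal(fit$betas, ts$betas, tolerance = 1e-10)
  expect_equal(max(fit$mse), 0, tolerance = 1e-18)
  expect_equal(max(abs(fit$coef_var)), 0, tolerance = 1e-18)
})

test_that("fit agrees with an independent least-squares solver", {
  X <- cbind(c1 = c(0.7, 0.6, 0.5, 0.4), c2 = c(0.3, 0.4, 0.5, 0.6))
  y <- c(1, 2, 3, 4)
  fit <- fit_cell_type_expression(rbind(g1 = y), X)
  oracle <- lm(y ~ 0 + X)
  osum <- suppressWarnings(summary(oracle))   # near-perfect toy fit
  expect_equal(unname(fit$betas[1, ]), unname(coef(oracle)),
               tolerance = 1e-10)
  expect_equal(unname(fit$mse[1]), osum$sigma^2, tolerance = 1e-10)
  expect_equal(unname(sqrt(fit$coef_var[1, ])),
               unname(osum$coefficients[, "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(fit$residuals[1, ], unname(residuals(oracle)),
               tolerance = 1e-10)
})

test_that("per-gene MSE equals the brute-force summation", {
  set.seed(7)
  R <- matrix(rnorm(50 * 9), 50, 9)
  got <- mse_per_gene(R, M = 9, P = 3)
  byhand <- numeric(50)
  for (j in 1:50) {
    acc <- 0
    for (m in 1:9) acc <- acc + R[j, m]^2
    byhand[j] <- acc / (9 - 3)
  }
  expect_equal(got, byhand, tolerance = 1e-14)
  expect_equal(mse_per_gene(c(-1, 0, 1), 3, 1), 1.0)
  expect_equal(mse_per_gene(rep(0, 5), 5, 2), 0.0)
  expect_error(mse_per_gene(R, M = 9, P = 9), "exceed")
})

test_that("coefficient covariance is mse times (X'X)^-1, linear in mse", {
  xtx_inv <- matrix(c(2, -0.5, -0.5, 1), 2, 2)
  expect_equal(coef_covariance(0, xtx_inv), matrix(0, 2, 2))
  expect_equal(coef_covariance(3, xtx_inv), 3 * xtx_inv)
  expect_equal(coef_covariance(6, xtx_inv), 2 * coef_covariance(3, xtx_inv))
})

test_that("matrix pipeline matches the scalar simple-regression variance", {
  # single predictor plus intercept column: the matrix covariance diagonal
  # must equal RSS/(M-2) / sum((x - xbar)^2)
  set.seed(11)
  M <- 12
  x <- runif(M)
  X <- cbind(intercept = rep(1, M), slope = x)
  y <- 2 + 3 * x + rnorm(M)
  fit <- fit_cell_type_expression(rbind(g1 = y), X)
  rss <- sum(fit$residuals^2)
  scalar_var <- (rss / (M - 2)) / sum((x - mean(x))^2)
  expect_equal(unname(fit$coef_var[1, "slope"]), scalar_var,
               tolerance = 1e-12)
})

test_that("P = 1 matrix pipeline equals the scalar formulas exactly", {
  set.seed(3)
  x <- matrix(runif(10, 0.5, 1), 10, 1, dimnames = list(NULL, "c1"))
  y <- rbind(g1 = as.vector(x) * 4 + rnorm(10, sd = 0.3))
  fit <- fit_cell_type_expression(y, x)
  beta_scalar <- sum(as.vector(x) * as.vector(y)) / sum(x^2)
  expect_equal(unname(fit$betas[1, 1]), beta_scalar)
  mse_scalar <- sum((as.vector(y) - beta_scalar * as.vector(x))^2) / (10 - 1)
  expect_equal(unname(fit$mse[1]), mse_scalar)
  expect_equal(unname(fit$coef_var[1, 1]), mse_scalar / sum(x^2))
})

test_that("residuals are orthogonal to the design for every gene", {
  for (seed in 1:5) {
    ts <- toy_study(J = 20, M = 10, P = 3, seed = seed)
    fit <- fit_cell_type_expression(ts$expression, ts$proportions)
    ortho <- crossprod(ts$proportions, t(fit$residuals))
    scale <- max(abs(crossprod(ts$proportions, t(ts$expression))))
    expect_lt(max(abs(ortho)) / scale, 1e-8)
  }
})

test_that("coefficient estimates are unbiased over replicates", {
  set.seed(19)
  M <- 10; P <- 3
  X <- matrix(runif(M * P, 0.2, 0.8), M, P)
  X <- X / rowSums(X)
  colnames(X) <- paste0("c", 1:P)
  true_beta <- c(4, 7, 9)
  n_rep <- 1000
  # each "gene" is an independent replicate at the same true coefficients
  Y <- matrix(rep(as.vector(X %*% true_beta), each = n_rep), n_rep, M) +
    matrix(rnorm(n_rep * M, sd = 1), n_rep, M)
  rownames(Y) <- paste0("r", 1:n_rep)
  fit <- fit_cell_type_expression(Y, X)
  mc_se <- apply(fit$betas, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(colMeans(fit$betas) - true_beta) < 3 * mc_se))
})

test_that("empirical coefficient variance matches the model variance", {
  set.seed(23)
  M <- 10; P <- 3
  X <- matrix(runif(M * P, 0.2, 0.8), M, P)
  X <- X / rowSums(X)
  colnames(X) <- paste0("c", 1:P)
  n_rep <- 5000
  Y <- matrix(rep(as.vector(X %*% c(5, 6, 7)), each = n_rep), n_rep, M) +
    matrix(rnorm(n_rep * M, sd = sqrt(2)), n_rep, M)
  rownames(Y) <- paste0("r", 1:n_rep)
  fit <- fit_cell_type_expression(Y, X)
  for (k in 1:P) {
    empirical <- var(fit$betas[, k])
    model <- mean(fit$coef_var[, k])
    expect_lt(abs(empirical / model - 1), 0.10)
  }
})

test_that("degenerate designs are refused", {
  ts <- toy_study()
  expect_error(fit_cell_type_expression(ts$expression[, 1:2],
                                        ts$proportions[1:2, ]),
               "insufficient degrees of freedom")
  Xs <- cbind(ts$proportions[, 1], ts$proportions[, 1])
  expect_error(fit_cell_type_expression(ts$expression, Xs),
               "singular")
})
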