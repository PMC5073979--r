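# Controlled simulator: proportions, cell expression, mixing, assembly.

test_that("proportion simulator hits the SD and condition-number targets", {
  X <- simulate_proportions(5, 14, 0.1, 100, seed = 1)
  frac <- X / rowSums(X)
  expect_true(sd(frac[, 1]) >= 0.09 && sd(frac[, 1]) <= 0.11)
  cd <- condition_number(X)$cd
  expect_true(cd >= 90 && cd <= 110)
  expect_equal(unname(rowSums(X)), rep(100, 14))
  expect_true(all(X >= 0))
  expect_equal(attr(X, "achieved_sd"), sd(frac[, 1]), tolerance = 1e-12)
})

test_that("proportion simulator is deterministic in the seed", {
  a <- simulate_proportions(5, 10, 0.1, 1000, seed = 9)
  b <- simulate_proportions(5, 10, 0.1, 1000, seed = 9)
  c <- simulate_proportions(5, 10, 0.1, 1000, seed = 10)
  expect_identical(a, b)
  expect_false(identical(unname(a), unname(c)))
})

test_that("degenerate proportion requests are refused", {
  expect_error(simulate_proportions(1, 10, 0.1, 100, seed = 1),
               "P must be >= 2")
  expect_error(simulate_proportions(5, 4, 0.1, 100, seed = 1),
               "M must exceed P")
  # requested CD below what any positive sum-to-one design can attain here
  expect_error(simulate_proportions(5, 10, 0.1, 1.0000001, seed = 1),
               "search failed")
})

test_that("fraction unit yields rows summing to one", {
  X <- simulate_proportions(5, 12, 0.1, 500, seed = 2, unit = "fraction")
  expect_equal(unname(rowSums(X)), rep(1, 12))
  expect_equal(sd(X[, 1]), 0.1, tolerance = 1e-6)
})

test_that("effect grid covers the stated range with even spacing", {
  cfg <- sim_config(n_genes = 1000, seed = 5)
  bet <- simulate_cell_expression(cfg)
  nz <- bet$truth[bet$truth != 0]
  expect_length(nz, 500)
  expect_equal(min(nz), 0.001)
  expect_equal(max(nz), 1.0)
  expect_equal(diff(sort(nz)), rep((1.0 - 0.001) / 499, 499),
               tolerance = 1e-12)
  # effects live only in the target cell
  expect_true(all(bet$truth[, -cfg$target_cell] == 0))
  expect_equal(bet$true_betas_cases - bet$true_betas_controls, bet$truth)
})

test_that("zero changed fraction leaves the groups identical", {
  cfg <- sim_config(n_genes = 50, frac_changed = 0, seed = 6)
  bet <- simulate_cell_expression(cfg)
  expect_identical(bet$true_betas_controls, bet$true_betas_cases)
  expect_true(all(bet$truth == 0))
})

test_that("mixing is exact without noise and refitting recovers the betas", {
  ts <- toy_study(J = 15, M = 10, P = 3, seed = 2)
  Y <- mix_to_heterogeneous(ts$betas[, 1:3], ts$proportions, 0, seed = 1)
  expect_equal(Y, ts$betas[, 1:3] %*% t(ts$proportions))
  fit <- fit_cell_type_expression(Y, ts$proportions)
  expect_equal(fit$betas, ts$betas[, 1:3], tolerance = 1e-10)
  expect_error(mix_to_heterogeneous(ts$betas, ts$proportions, -1, 1),
               "non-negative")
})

test_that("noise calibration: mean refitted MSE matches the target", {
  cfg <- sim_config(n_genes = 1000, n_per_group = 14, mse_target = 1.5,
                    seed = 12)
  sim <- assemble_study(cfg)
  g <- sim$dataset$groups
  fit <- fit_cell_type_expression(
    sim$dataset$expression[, g == "controls"],
    sim$dataset$proportions[g == "controls", ])
  expect_true(mean(fit$mse) >= 1.40 && mean(fit$mse) <= 1.60)
})

test_that("assembled studies have the stated two-group structure", {
  cfg <- sim_config(n_genes = 30, n_per_group = 9, seed = 8)
  sim <- assemble_study(cfg)
  d <- sim$dataset
  expect_equal(ncol(d$expression), 18)
  expect_equal(unname(as.vector(table(d$groups))), c(9L, 9L))
  # identical proportions for both groups
  expect_equal(unname(d$proportions[d$groups == "controls", ]),
               unname(d$proportions[d$groups == "cases", ]))
  expect_equal(sum(sim$truth != 0), round(30 * 0.5))
  expect_true(abs(sim$achieved_cd / cfg$target_cd - 1) <= 0.1)
  expect_true(abs(sim$achieved_sd / cfg$target_sd - 1) <= 0.1)
})

test_that("the full simulated study is a pure function of its config", {
  cfg <- sim_config(n_genes = 25, n_per_group = 8, seed = 14)
  s1 <- assemble_study(cfg)
  s2 <- assemble_study(cfg)
  expect_identical(s1$dataset$expression, s2$dataset$expression)
  expect_identical(s1$truth, s2$truth)
  s3 <- assemble_study(sim_config(n_genes = 25, n_per_group = 8, seed = 15))
  expect_false(identical(s1$dataset$expression, s3$dataset$expression))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_group = 5, n_cells = 5), "exceed")
  expect_error(sim_config(target_sd = 0), "positive")
  expect_error(sim_config(frac_changed = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(effect_lo = 2, effect_hi = 1), "<=")
})
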