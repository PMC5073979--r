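# Welch statistics, p-values, power and multiplicity adjustment.

test_that("Welch statistic matches direct evaluation of the formulas", {
  w <- welch_statistic(1.0, 0.04, 5, 0.5, 0.04, 5)
  expect_equal(w$t, 0.5 / sqrt(0.08), tolerance = 1e-12)
  expect_equal(w$df, 0.08^2 / (0.04^2 / 5 + 0.04^2 / 5), tolerance = 1e-12)
  expect_equal(w$df, 10)                    # equal variances, equal df: 2d

  expect_equal(welch_statistic(2, 1, 4, 2, 3, 7)$t, 0)

  # zero-variance limits
  z <- welch_statistic(c(1, 1), c(0, 0), 5, c(0.5, 1), c(0, 0), 5)
  expect_identical(z$t[1], Inf)
  expect_identical(z$t[2], 0)
  expect_error(welch_statistic(1, -0.1, 5, 0, 1, 5), "non-negative")
})

test_that("Welch statistic is antisymmetric; p and power are invariant", {
  ab <- welch_statistic(1.3, 0.2, 6, 0.4, 0.5, 9)
  ba <- welch_statistic(0.4, 0.5, 9, 1.3, 0.2, 6)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$df, ba$df)
  expect_equal(t_p_value(ab$t, ab$df), t_p_value(ba$t, ba$df))
  expect_equal(detection_power(ab$t, ab$df), detection_power(ba$t, ba$df))
})

test_that("two-sided p-values agree with numerical integration of the t density", {
  for (case in list(c(1.77, 10), c(2.5, 4), c(0.3, 25))) {
    p <- t_p_value(case[1], case[2])
    oracle <- 2 * integrate(function(u) dt(u, df = case[2]), case[1], Inf,
                            rel.tol = 1e-12)$value
    expect_equal(p, oracle, tolerance = 1e-10)
  }
  expect_equal(t_p_value(0, 7), 1)
  expect_equal(t_p_value(Inf, 7), 0)
  expect_lt(t_p_value(50, 7), 1e-8)
})

test_that("detection power follows the shifted-t construction", {
  expect_equal(detection_power(1.0, 20, alpha = 0.05), 0.05)   # below crit
  t_crit <- qt(0.975, 20)
  expect_equal(detection_power(t_crit, 20), 0.5)               # boundary
  oracle <- integrate(function(u) dt(u, df = 20), -2, Inf,
                      rel.tol = 1e-12)$value
  expect_equal(detection_power(t_crit + 2, 20), oracle, tolerance = 1e-10)
  expect_equal(detection_power(Inf, 20), 1)
})

test_that("power is monotone in |t| with floor alpha, on a (t, df) grid", {
  for (df in c(5, 10, 30)) {
    tt <- seq(0, 8, by = 0.05)
    pw <- detection_power(tt, df, alpha = 0.05)
    expect_true(all(diff(pw) >= -1e-12))
    expect_true(all(pw >= 0.05))
    expect_true(all(pw[tt < qt(0.975, df)] == 0.05))
    expect_true(all(pw <= 1))
  }
})

test_that("Bonferroni adjustment caps at one and none is the identity", {
  expect_equal(adjust_p(0.001, n = 10), 0.01)
  expect_equal(adjust_p(0.5, n = 10), 1.0)
  p <- runif(20)
  expect_identical(adjust_p(p, method = "none"), p)
  expect_true(all(adjust_p(p) >= p))
  expect_error(adjust_p(1.2), "\\[0, 1\\]")
})

test_that("the fitted model object exposes the full gene-by-cell table", {
  ts <- toy_study(J = 10, M = 10, P = 2, seed = 5)
  data <- align_study(ts$expression, ts$proportions, ts$groups)
  fit <- lrcde(data)
  expect_s3_class(fit, "lrcde")
  expect_equal(nrow(fit$table), 10 * 2)
  expect_equal(fit$table$delta,
               fit$table$beta_cases - fit$table$beta_controls)
  expect_true(all(fit$table$p_adj >= fit$table$p))
  expect_true(all(fit$table$power >= fit$alpha - 1e-15))
  # table p-values are exactly the two-sided Welch p at the table's df
  expect_equal(fit$table$p, t_p_value(fit$table$t, fit$table$df))
})

test_that("model methods are consistent with the stored fits", {
  ts <- toy_study(J = 8, M = 10, P = 2, seed = 9)
  fit <- lrcde(align_study(ts$expression, ts$proportions, ts$groups))
  cf <- coef(fit)
  expect_named(cf, c("controls", "cases"))
  expect_equal(predict(fit, group = "controls"),
               fitted(fit, group = "controls"))
  g <- fit$data$groups
  expect_equal(fitted(fit, "controls") + residuals(fit, "controls"),
               fit$data$expression[, g == "controls"])
  newX <- ts$proportions[1:3, ]
  expect_equal(predict(fit, newX, group = "cases"),
               cf$cases %*% t(newX))
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "lrcde_data")
  expect_false(identical(sims[[1]]$expression, sims[[2]]$expression))
  expect_identical(simulate(fit, 1, seed = 4)[[1]]$expression,
                   sims[[1]]$expression)
})

test_that("noise-free studies give exact effect recovery and zero p", {
  cfg <- sim_config(n_genes = 40, n_per_group = 10, mse_target = 0,
                    seed = 3)
  sim <- assemble_study(cfg)
  fit <- lrcde(sim$dataset, adjust = "none")
  d <- matrix(fit$table$delta, 40, 5)
  expect_equal(unname(d), unname(sim$truth), tolerance = 1e-10)
  changed <- as.vector(sim$truth != 0)
  expect_true(all(fit$table$p[changed] < 1e-8))
})
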