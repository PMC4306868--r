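test_that("least squares matches an independent normal-equations solve", {
  set.seed(3)
  X <- cbind(1, matrix(rnorm(100), 50, 2))
  colnames(X) <- c("(Intercept)", "a", "b")
  y <- rnorm(50)
  fit <- ols_fit(X, y)
  oracle <- drop(solve(t(X) %*% X, t(X) %*% y))
  expect_lt(max(abs(fit$coefficients - oracle)), 1e-8)
  # residuals orthogonal to the design
  expect_lt(max(abs(t(X) %*% fit$residuals)), 1e-8)
})

test_that("degenerate responses give the forced least-squares answers", {
  set.seed(4)
  X <- cbind(1, rnorm(20), rnorm(20))
  colnames(X) <- c("(Intercept)", "a", "b")
  fit <- ols_fit(X, X[, "a"])
  expect_equal(unname(fit$coefficients), c(0, 1, 0), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  const <- ols_fit(X, rep(5, 20))
  expect_equal(unname(const$coefficients[1]), 5, tolerance = 1e-10)
  expect_equal(const$r_squared, 0)
})

test_that("cluster sandwich matches brute-force summation on a fixture", {
  X <- cbind(`(Intercept)` = 1,
             x = c(0.3, -1.2, 2.5, 0.7, -0.4, 1.1),
             z = c(1, 0, 1, 1, 0, 0))
  u <- c(0.5, -0.2, 1.4, -0.9, 0.3, -1.1)
  cl <- c("a", "a", "b", "b", "c", "c")
  expect_lt(max(abs(cluster_robust_cov(X, u, cl, type = "CR0") -
                      brute_cluster_cov(X, u, cl))), 1e-10)
  expect_lt(max(abs(cluster_robust_cov(X, u, cl, type = "CR1") -
                      brute_cluster_cov(X, u, cl, correct = TRUE))), 1e-10)
})

test_that("singleton clusters without correction reduce to HC0", {
  set.seed(6)
  n <- 25
  X <- cbind(1, rnorm(n)); colnames(X) <- c("(Intercept)", "x")
  u <- rnorm(n)
  hc0 <- solve(t(X) %*% X) %*% (t(X) %*% diag(u^2) %*% X) %*% solve(t(X) %*% X)
  expect_lt(max(abs(cluster_robust_cov(X, u, seq_len(n), "CR0") - hc0)),
            1e-10)
})

test_that("cluster sandwich agrees with the sandwich package", {
  skip_if_not_installed("sandwich")
  set.seed(2)
  n <- 30
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  dat$y <- 1 + 2 * dat$x1 - dat$x2 + rnorm(n)
  cl <- rep(1:10, each = 3)
  m <- lm(y ~ x1 + x2, data = dat)
  X <- model.matrix(m)
  u <- residuals(m)
  expect_lt(max(abs(cluster_robust_cov(X, u, cl, "CR0") -
                      sandwich::vcovCL(m, cluster = cl, type = "HC0",
                                       cadjust = FALSE))), 1e-12)
  expect_lt(max(abs(cluster_robust_cov(X, u, cl, "CR1") -
                      sandwich::vcovCL(m, cluster = cl, type = "HC1",
                                       cadjust = TRUE))), 1e-12)
})

test_that("duplicating clusters keeps estimates, shrinks CR0 SEs by sqrt(2)", {
  set.seed(8)
  n <- 24
  X <- cbind(1, rnorm(n), rnorm(n)); colnames(X) <- c("(Intercept)", "a", "b")
  y <- drop(X %*% c(1, 0.5, -0.5)) + rnorm(n)
  cl <- rep(1:8, each = 3)
  f1 <- ols_fit(X, y)
  X2 <- rbind(X, X); y2 <- c(y, y); cl2 <- c(cl, cl + 100)
  f2 <- ols_fit(X2, y2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  V1 <- cluster_robust_cov(X, f1$residuals, cl, "CR0")
  V2 <- cluster_robust_cov(X2, f2$residuals, cl2, "CR0")
  expect_lt(max(abs(V2 - V1 / 2)), 1e-10)
  expect_lt(max(abs(V2 - brute_cluster_cov(X2, f2$residuals, cl2))), 1e-10)
})

test_that("degenerate clustering inputs are rejected", {
  X <- cbind(1, 1:4); u <- rnorm(4)
  expect_error(cluster_robust_cov(X, u, rep(1, 4)), "two clusters")
  f <- factor(c("a", "a", "b", "b"), levels = c("a", "b", "c"))
  expect_error(cluster_robust_cov(X, u, f), "empty")
})

test_that("DF regression recovers ACE shares and matches Falconer", {
  d <- simulate_twins(sim_config(3000, 3000, h2 = 0.3, c2 = 0.4, seed = 61,
                                 percentile_output = FALSE))
  f <- fit_df(d)
  vd <- f$variance_decomposition
  expect_lt(abs(vd$c2 - 0.4), 0.05)
  expect_lt(abs(vd$h2 - 0.3), 0.05)
  expect_equal(vd$residual, 1 - vd$c2 - vd$h2)
  fal <- falconer_estimates(d)
  expect_lt(abs(vd$h2 - fal[["h2"]]), 0.05)
  expect_equal(f$n_rows, 2L * f$n_pairs)
  expect_true(all(f$p >= 0 & f$p <= 1))
  expect_equal(f$df, f$n_pairs - 1L)
})

test_that("variance shares are location invariant and scale free", {
  d <- simulate_twins(sim_config(300, 300, h2 = 0.3, c2 = 0.4, seed = 62,
                                 percentile_output = FALSE,
                                 covariates = list(
                                   covariate_spec("x", "binary", prob = 0.4))))
  spec <- df_model_spec("EQ3", "x")
  f0 <- fit_df(d, spec)
  shifted <- d; shifted$outcome <- d$outcome + 100
  f1 <- fit_df(shifted, spec)
  expect_equal(f0$coefficients[-1], f1$coefficients[-1], tolerance = 1e-10)
  # centering absorbs the shift from the predictors, so it lands on b0 alone
  expect_equal(unname(f1$coefficients[1] - f0$coefficients[1]), 100,
               tolerance = 1e-8)
  scaled <- d; scaled$outcome <- d$outcome * 3
  f3 <- fit_df(scaled, spec)
  expect_equal(f0$coefficients["K2_centered"], f3$coefficients["K2_centered"],
               tolerance = 1e-10)
  expect_equal(f0$coefficients["R_x_K2_centered"],
               f3$coefficients["R_x_K2_centered"], tolerance = 1e-10)
  # ENVDIF effects are in outcome units, so they scale with the outcome
  expect_equal(unname(3 * f0$coefficients["envdif_x"]),
               unname(f3$coefficients["envdif_x"]), tolerance = 1e-10)
})

test_that("estimates are invariant to row shuffling and member order", {
  d <- simulate_twins(sim_config(200, 200, h2 = 0.3, c2 = 0.4, seed = 63,
                                 percentile_output = FALSE,
                                 covariates = list(
                                   covariate_spec("x", "count", size = 7,
                                                  prob = 0.3))))
  spec <- df_model_spec("EQ3", "x")
  f0 <- fit_df(d, spec)
  set.seed(1)
  f1 <- fit_df(d[sample(nrow(d)), ], spec)
  expect_equal(f0$coefficients, f1$coefficients, tolerance = 1e-12)
  expect_equal(f0$se, f1$se, tolerance = 1e-12)
  swap <- d
  flip <- swap$pair_id %% 3 == 0
  swap$twin_index[flip] <- 3L - swap$twin_index[flip]
  f2 <- fit_df(swap, spec)
  expect_equal(f0$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f0$se, f2$se, tolerance = 1e-10)
})

test_that("ENVDIF estimates center on the population projection", {
  # closed-form oracle for the double-entered EQ3 projection coefficient
  beta <- -1; v <- 7 * 0.32 * 0.68
  target <- envdif_estimand(beta, v, h2 = 0.3, c2 = 0.4)
  set.seed(64)
  est <- replicate(200, {
    cfg <- sim_config(500, 500, h2 = 0.3, c2 = 0.4,
                      percentile_output = FALSE,
                      covariates = list(covariate_spec("x", "count", size = 7,
                                                       prob = 0.32,
                                                       beta = beta)))
    unname(coef(fit_df(simulate_twins(cfg),
                       df_model_spec("EQ3", "x")))["envdif_x"])
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - target), 2 * mc_se)
})

test_that("variance decomposition is unconstrained arithmetic on b1, b2", {
  vd <- decompose_variance(c(0.44, 0.27))
  expect_equal(vd$residual, 0.29)
  expect_equal(decompose_variance(c(0, 0))$residual, 1)
  expect_warning(out <- decompose_variance(c(0.6, 0.5)), "outside")
  expect_equal(out$residual, -0.1)
})

test_that("undetermined zygosity and missing covariates are excluded with logs", {
  d <- simulate_twins(sim_config(50, 50, h2 = 0.3, c2 = 0.4, seed = 65,
                                 percentile_output = FALSE,
                                 covariates = list(
                                   covariate_spec("x", "binary", prob = 0.4))))
  d$zygosity[d$pair_id == 1] <- "UN"
  d$x[d$pair_id == 2 & d$twin_index == 1] <- NA
  msgs <- capture_messages(f <- fit_df(d, df_model_spec("EQ3", "x")))
  expect_match(paste(msgs, collapse = " "), "undetermined zygosity")
  expect_match(paste(msgs, collapse = " "), "listwise deletion")
  expect_equal(f$n_pairs, 98L)
})
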