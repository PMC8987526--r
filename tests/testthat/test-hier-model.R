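test_that("posterior summaries match a deterministic grid-integration oracle", {
  y <- c(2.8, 0.8, -0.3, 0.7, -0.1, 0.1, 1.8, 1.2)
  se <- rep(0.4, 8)
  fit <- fit_hierarchical(fake_estimates(y, se),
                          mcmc_control(chains = 4, warmup = 1000,
                                       iter = 1500, seed = 7))
  oracle <- grid_posterior(y, se)
  expect_lt(abs(mean(fit$mu) - oracle$mu_mean), 0.03)
  expect_lt(abs(sd(fit$mu) - oracle$mu_sd), 0.03)
  expect_lt(abs(mean(fit$tau) - oracle$tau_mean), 0.05)
  theta_means <- colMeans(fit$theta[, 1, ])
  expect_equal(unname(theta_means), oracle$theta_mean, tolerance = 0.05)
  expect_true(all(fit$diagnostics$converged))
  expect_true(all(fit$tau >= 0))
})

test_that("posterior matches an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  y <- c(0.2, 1.4, 0.9, -0.5, 0.3, 2.1)
  se <- c(0.3, 0.5, 0.4, 0.3, 0.6, 0.4)
  fit <- fit_hierarchical(fake_estimates(y, se),
                          mcmc_control(chains = 4, warmup = 1000,
                                       iter = 2000, seed = 3))
  model <- "model {
    for (j in 1:J) {
      y[j] ~ dnorm(theta[j], 1 / (se[j] * se[j]))
      theta[j] <- mu + tau * eta[j]
      eta[j] ~ dnorm(0, 1)
    }
    mu ~ dnorm(0, 0.01)
    tau ~ dt(0, 0.16, 1) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = y, se = se, J = length(y)),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 11))
  update(jm, 2000, progress.bar = "none")
  sam <- rjags::coda.samples(jm, c("mu", "tau", "theta"), 8000,
                             progress.bar = "none")
  post <- colMeans(as.matrix(sam))
  expect_lt(abs(mean(fit$mu) - post[["mu"]]), 0.05)
  expect_lt(abs(mean(fit$tau) - post[["tau"]]), 0.07)
  expect_equal(unname(colMeans(fit$theta[, 1, ])),
               unname(post[paste0("theta[", seq_along(y), "]")]),
               tolerance = 0.07)
})

test_that("complete-pooling and no-pooling limits are recovered", {
  y <- c(1.2, 0.4, 0.9, 1.6, 0.2)
  se <- c(0.2, 0.3, 0.25, 0.2, 0.4)
  # tau prior collapsed to zero: every theta_j is the precision-weighted
  # mean (R-hat on the degenerate tau draws is meaningless; its warning is
  # expected here)
  fit0 <- suppressWarnings(fit_hierarchical(
    fake_estimates(y, se),
    mcmc_control(chains = 2, warmup = 500, iter = 1000, seed = 5,
                 tau_prior_scale = 1e-8)))
  pooled <- sum(y / se^2) / sum(1 / se^2)
  expect_equal(unname(colMeans(fit0$theta[, 1, ])), rep(pooled, 5),
               tolerance = 0.02)
  # vanishing measurement error: theta_j sticks to y_j
  fitN <- fit_hierarchical(
    fake_estimates(y, rep(1e-4, 5)),
    mcmc_control(chains = 2, warmup = 500, iter = 1000, seed = 5))
  expect_equal(unname(colMeans(fitN$theta[, 1, ])), y, tolerance = 1e-3)
})

test_that("fits are deterministic given seed and settings", {
  y <- c(0.5, 1.1, -0.2, 0.8); se <- rep(0.3, 4)
  ctl <- mcmc_control(chains = 2, warmup = 200, iter = 300, seed = 99)
  f1 <- fit_hierarchical(fake_estimates(y, se), ctl)
  f2 <- fit_hierarchical(fake_estimates(y, se), ctl)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$mu, f2$mu)
  f3 <- fit_hierarchical(fake_estimates(y, se),
                         mcmc_control(chains = 2, warmup = 200, iter = 300,
                                      seed = 100))
  expect_false(identical(f1$mu, f3$mu))
})

test_that("fit inputs are validated", {
  expect_error(fit_hierarchical(fake_estimates(1.0, 0.2)), "two exposure")
  bad <- fake_estimates(c(1, 2), c(0.1, 0))
  expect_error(fit_hierarchical(bad), "positive")
  two <- dplyr::bind_rows(
    transform(fake_estimates(c(1, 2), c(.1, .1)), chemical = "a"),
    transform(fake_estimates(c(1, 2), c(.1, .1), probe_id = "p2"),
              chemical = "b"))
  expect_error(fit_hierarchical(two), "single chemical")
})

test_that("hdi matches the independent HPD routine and nails known cases", {
  set.seed(21)
  x <- rnorm(20000, 0.8, 0.1)
  h <- hdi(x, 0.95)
  expect_equal(unname(h), c(0.604, 0.996), tolerance = 0.01)
  ref <- coda::HPDinterval(coda::as.mcmc(x), prob = 0.95)
  expect_equal(unname(h["lower"]), ref[1, "lower"], tolerance = 1e-6)
  expect_equal(unname(h["upper"]), ref[1, "upper"], tolerance = 1e-6)
  # skewed draws: HDI is narrower than the equal-tailed interval
  sk <- rlnorm(20000)
  hs <- hdi(sk, 0.9)
  et <- quantile(sk, c(0.05, 0.95))
  expect_lt(hs["upper"] - hs["lower"], et[2] - et[1])
})

test_that("posterior differences behave on identity and shift cases", {
  est <- dplyr::bind_rows(
    tibble::tibble(probe_id = "p1", dose_level = "control",
                   time_value = 24, time_unit = "hour", y = 1, se = 0.2),
    tibble::tibble(probe_id = "p1", dose_level = c("low", "high"),
                   time_value = 24, time_unit = "hour",
                   y = c(1.1, 2.4), se = 0.2))
  fit <- fit_hierarchical(est, mcmc_control(chains = 2, warmup = 500,
                                            iter = 500, seed = 2))
  ctrl <- group_id("control", 24, "hour")
  same <- posterior_difference(fit, ctrl, ctrl)
  expect_equal(same$median, 0)
  expect_equal(same$hdi_low, 0)
  expect_equal(same$hdi_high, 0)
  d <- posterior_difference(fit, group_id("high", 24, "hour"), ctrl)
  draws <- attr(d, "draws")
  expect_equal(unname(hdi(draws[, 1])), c(d$hdi_low, d$hdi_high))
  expect_error(posterior_difference(fit, "nope", ctrl), "unknown group")
  # exact +1 shift between the draws of two groups
  fit2 <- fit
  fit2$theta[, 1, 2] <- fit2$theta[, 1, 1] + 1
  d2 <- posterior_difference(fit2, fit2$groups$group_id[2],
                             fit2$groups$group_id[1])
  expect_equal(d2$median, 1)
  expect_equal(c(d2$hdi_low, d2$hdi_high), c(1, 1))
})

test_that("recovery of the population mean across replicated experiments", {
  # 50 replicate 8-group experiments drawn from mu = 1, tau = 0.5,
  # sigma_j = 0.2, fitted jointly as independent probes
  set.seed(2024)
  n_rep <- 50; J <- 8; mu_true <- 1; tau_true <- 0.5; sig <- 0.2
  est <- dplyr::bind_rows(lapply(seq_len(n_rep), function(r) {
    theta <- rnorm(J, mu_true, tau_true)
    tibble::tibble(probe_id = sprintf("rep%02d", r), dose_level = "low",
                   time_value = seq_len(J), time_unit = "hour",
                   y = rnorm(J, theta, sig), se = sig)
  }))
  fit <- fit_hierarchical(est, mcmc_control(chains = 2, warmup = 500,
                                            iter = 1000, seed = 31))
  mu_mean <- colMeans(fit$mu)
  mu_sd <- apply(fit$mu, 2, sd)
  covered <- abs(mu_mean - mu_true) <= 3 * mu_sd
  expect_gte(mean(covered), 0.90)
  # tau is recovered on average across replicates
  expect_lt(abs(mean(colMeans(fit$tau)) - tau_true), 0.2)
})
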