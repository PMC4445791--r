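test_that("HPD interval equals the brute-force shortest window", {
  set.seed(50)
  # integer ramp: every window ties, the first (smallest lower bound) wins
  expect_equal(hpd_interval(1:100, 0.95), c(lower = 1, upper = 95))
  for (i in 1:10) {
    x <- switch(1 + i %% 3, rnorm(100), rexp(150), c(rnorm(80), rnorm(40, 6)))
    p <- sample(c(0.5, 0.9, 0.95), 1)
    expect_equal(unname(hpd_interval(x, p)), brute_hpd(x, p))
  }
})

test_that("HPD handles boundary masses and short chains", {
  x <- rnorm(150)
  expect_equal(unname(hpd_interval(x, 1)), range(x))
  expect_error(hpd_interval(rnorm(50)), "at least 100")
  # symmetric unimodal: HPD close to the equal-tail interval
  set.seed(51)
  z <- rnorm(1e5)
  h <- hpd_interval(z, 0.95)
  et <- quantile(z, c(0.025, 0.975))
  expect_lt(max(abs(h - et)), 0.02 * diff(range(et)))
  # agrees with the coda implementation (window lengths differ by at most
  # one draw because coda rounds where the Chen-Shao rule takes the ceiling)
  expect_equal(unname(hpd_interval(z, 0.95)),
               as.numeric(coda::HPDinterval(coda::mcmc(z))), tolerance = 1e-3)
})

test_that("Geweke diagnostic separates stationary from trending chains", {
  set.seed(52)
  iid <- matrix(rnorm(10000 * 3), ncol = 3)
  g <- geweke_diagnostic(iid)
  expect_true(all(abs(g$z) < 3))
  expect_false(any(g$degenerate))
  trended <- cbind(drift = rnorm(2000) + seq(0, 3, length.out = 2000))
  expect_true(geweke_diagnostic(trended)$flagged)
  const <- cbind(c0 = rep(1, 500))
  gc <- geweke_diagnostic(const)
  expect_true(gc$degenerate)
  expect_error(geweke_diagnostic(rnorm(100)), "too short")
  # comparing two identical halves gives z = 0
  half <- rnorm(300)
  sym <- geweke_diagnostic(cbind(s = c(half, half)),
                           frac1 = 0.5, frac2 = 0.5)
  expect_lt(abs(sym$z), 0.1)
})

test_that("DIC arithmetic matches the defining formula", {
  dev <- c(10, 12, 11, 13, 9)
  out <- dic_from_deviance(dev, deviance_at_means = 8)
  expect_equal(out$mean_deviance, 11)
  expect_equal(out$pD, 3)
  expect_equal(out$dic, 14)
  expect_warning(dic_from_deviance(dev, 20), "negative")
  # conditional deviance is additive: duplicating all data doubles it
  set.seed(53)
  vals <- matrix(sample(0:2, 30, replace = TRUE), 10, 3)
  items <- item_params(c(1, 2, 1.5), rbind(c(-1, 0), c(-.5, .5), c(0, 1)))
  th <- rnorm(10)
  d1 <- -2 * grm_loglik(vals, items, th)
  d2 <- -2 * grm_loglik(rbind(vals, vals), items, c(th, th))
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
})

test_that("discrimination is recovered with abilities clamped at truth", {
  set.seed(54)
  n <- 5000
  theta <- rnorm(n)
  ip <- item_params(1.6, rbind(c(-0.5, 0.8)))
  vals <- mlgrm:::sample_grm_matrix(ip, theta, "probit")
  bank <- item_bank("i1", domain = "mobility")
  rm <- response_matrix(vals, bank, paste0("p", 1:n))
  dw <- dwelling_index(rm$person_ids, rm$person_ids)
  names(theta) <- rm$person_ids
  cfg <- mcmc_config(n_iter = 1200, burn_in = 400, seed = 2,
                     fix_theta = theta, tau2_fixed = 0)
  fit <- run_mcmc(rm, dw, config = cfg)
  expect_lt(abs(mean(fit$draws$a) - 1.6), 0.1)
  kap <- matrix(colMeans(fit$draws$kappa), ncol = 2, byrow = TRUE)
  expect_lt(max(abs(kap - ip$kappa)), 0.1)
})

test_that("structural conditionals match the conjugate-regression oracle", {
  set.seed(55)
  n <- 5000
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  beta_true <- c(0.9, -0.17)
  theta <- drop(X %*% beta_true) + rnorm(n, 0, sqrt(0.3))
  names(theta) <- paste0("p", 1:n)
  rownames(X) <- names(theta)
  dw <- dwelling_index(names(theta), names(theta))
  cfg <- mcmc_config(n_iter = 1500, burn_in = 500, seed = 4,
                     fix_theta = theta, tau2_fixed = 0)
  fit <- run_mcmc(NULL, dw, person_covariates = X, config = cfg)
  est <- colMeans(fit$draws$beta)
  psd <- apply(fit$draws$beta, 2, sd)
  # closed-form conjugate posterior given the true residual variance
  s2 <- mean(fit$draws$sigma2)
  D <- cbind(1, X)
  V <- solve(crossprod(D) / s2 + diag(1 / 100, 3))
  bhat <- V %*% crossprod(D, theta) / s2
  expect_lt(max(abs(est - drop(bhat))), 3 * max(psd))
  expect_true(all(abs(est[-1] - beta_true) < 2.5 * psd[-1] + 0.02))
  # intercept-only, singleton dwellings, tau2 pinned: beta0 ~ mean(theta)
  cfg0 <- mcmc_config(n_iter = 600, burn_in = 200, seed = 5,
                      fix_theta = theta, tau2_fixed = 0)
  fit0 <- run_mcmc(NULL, dw, config = cfg0)
  expect_lt(abs(mean(fit0$draws$beta[, 1]) - mean(theta)), 0.02)
  # dwelling variance draws can never go negative
  expect_true(all(fit$draws$tau2 >= 0))
})

test_that("identification holds exactly at every stored iteration", {
  b <- small_bundle(seed = 301, n_dwellings = 250, n_items = 6)
  cfg <- mcmc_config(n_iter = 400, burn_in = 150, seed = 6)
  fit <- run_mcmc(b$bio, b$dwellings, config = cfg)
  expect_lt(fit$identify$max_abs_mean, 1e-12)
  expect_lt(fit$identify$max_abs_var_dev, 1e-12)
  expect_lt(fit$identify$max_loglik_drift, 1e-8)
  # thresholds stay strictly ordered in every stored draw
  K <- fit$dims$K
  kap1 <- fit$draws$kappa[, seq(1, 2 * K, by = 2)]
  kap2 <- fit$draws$kappa[, seq(2, 2 * K, by = 2)]
  expect_true(all(kap2 > kap1))
  expect_true(all(fit$draws$a > 0))
})

test_that("the sampler is bit-reproducible under a fixed seed", {
  b <- small_bundle(seed = 302, n_dwellings = 150, n_items = 5)
  cfg <- mcmc_config(n_iter = 250, burn_in = 100, seed = 11)
  f1 <- run_mcmc(b$bio, b$dwellings, config = cfg)
  f2 <- run_mcmc(b$bio, b$dwellings, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$theta_mean, f2$theta_mean)
})

test_that("persons with no observed items draw from the structural prior", {
  b <- small_bundle(seed = 303, n_dwellings = 120, n_items = 5,
                    missing_rate = 0)
  vals <- b$bio$values
  vals[1:3, ] <- NA_integer_
  rm <- response_matrix(vals, b$bio$bank, b$bio$person_ids)
  cfg <- mcmc_config(n_iter = 300, burn_in = 100, seed = 12)
  fit <- run_mcmc(rm, b$dwellings, config = cfg)
  expect_true(all(is.finite(fit$theta_mean)))
  # an unmeasured ability has much higher posterior variance than measured ones
  expect_gt(mean(fit$theta_var[1:3]), mean(fit$theta_var[-(1:3)]))
})

test_that("an item answered in a single category does not break the fit", {
  b <- small_bundle(seed = 304, n_dwellings = 100, n_items = 4,
                    missing_rate = 0)
  vals <- b$bio$values
  vals[, 2] <- 0L
  rm <- response_matrix(vals, b$bio$bank, b$bio$person_ids)
  cfg <- mcmc_config(n_iter = 300, burn_in = 100, seed = 13)
  fit <- run_mcmc(rm, b$dwellings, config = cfg)
  expect_true(all(is.finite(fit$draws$a)))
})

test_that("exchangeable persons receive exchangeable ability estimates", {
  b <- small_bundle(seed = 305, n_dwellings = 300, n_items = 8,
                    missing_rate = 0)
  vals <- b$bio$values
  vals[2, ] <- vals[1, ]                       # identical response patterns
  di <- b$dwellings
  di$dwelling_id[2] <- di$dwelling_id[1]       # same dwelling
  rm <- response_matrix(vals, b$bio$bank, b$bio$person_ids)
  cfg <- mcmc_config(n_iter = 1500, burn_in = 300, seed = 14)
  fit <- run_mcmc(rm, di, config = cfg)
  mc_se <- sqrt(fit$theta_var[1] / 30)  # generous effective-sample guess
  expect_lt(abs(fit$theta_mean[1] - fit$theta_mean[2]), 6 * mc_se)
})

test_that("the logit fallback fits and stays identified", {
  b <- small_bundle(seed = 306, n_dwellings = 400, n_items = 8,
                    link = "logit", missing_rate = 0)
  cfg <- mcmc_config(n_iter = 900, burn_in = 400, seed = 15, link = "logit")
  fit <- run_mcmc(b$lived_complete, b$dwellings,
                  person_covariates = b$truth$person_design,
                  config = cfg)
  expect_lt(fit$identify$max_abs_mean, 1e-12)
  expect_lt(fit$identify$max_loglik_drift, 1e-8)
  # the dominant structural effect is recovered in sign and rough size
  bio_coef <- mean(fit$draws$beta[, "biological"])
  expect_gt(bio_coef, 0.4)
  expect_gt(cor(colMeans(fit$draws$a), b$truth$items$lived$a), 0.6)
})

test_that("configuration errors are caught before sampling", {
  expect_error(mcmc_config(n_iter = 100, burn_in = 100, seed = 1), "burn_in")
  expect_error(mcmc_config(), "seed")
  b <- small_bundle(seed = 307, n_dwellings = 60, n_items = 4)
  cfg <- mcmc_config(n_iter = 200, burn_in = 50, seed = 1)
  X <- cbind(x = rep(1, nrow(b$bio$values)))  # collinear with intercept
  expect_error(run_mcmc(b$bio, b$dwellings, person_covariates = X,
                        config = cfg), "rank deficient")
})
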