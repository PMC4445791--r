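test_that("nesting reproduces the near-singleton dwelling structure", {
  cfg <- generator_config(seed = 1, n_dwellings = 10000)
  nest <- generate_nesting(cfg)
  ratio <- nrow(nest) / cfg$n_dwellings
  expect_gt(ratio, 1.10)
  expect_lt(ratio, 1.17)
  # mean size 1 -> all singletons
  cfg1 <- generator_config(seed = 1, n_dwellings = 50, mean_cluster_size = 1)
  expect_true(all(attr(generate_nesting(cfg1), "sizes") == 1L))
  # determinism
  expect_identical(generate_nesting(cfg), generate_nesting(cfg))
})

test_that("generated truth respects its declared invariants", {
  cfg <- generator_config(seed = 8, n_dwellings = 1500)
  tr <- generate_truth(cfg)
  # thresholds strictly increasing for every item
  for (role in c("biological", "lived")) {
    expect_true(all(apply(tr$items[[role]]$kappa, 1, function(k)
      all(diff(k) > 0))))
    expect_true(all(tr$items[[role]]$a >= cfg$disc_range[1] &
                      tr$items[[role]]$a <= cfg$disc_range[2]))
  }
  # abilities standardized exactly on the identified scale
  expect_equal(mean(tr$theta_lived), 0, tolerance = 1e-12)
  expect_equal(mean(tr$theta_lived^2), 1, tolerance = 1e-12)
  # residual variance split matches the configured ICC
  expect_equal(tr$coefs_raw$tau2 / (tr$coefs_raw$tau2 + tr$coefs_raw$sigma2),
               cfg$icc)
})

test_that("raw latent variance matches the moment identity", {
  cfg <- generator_config(seed = 15, n_dwellings = 4000)
  tr <- generate_truth(cfg)
  pc <- cfg$person_coefs
  expected <- pc[["biological"]]^2 * 1 +
    pc[["male"]]^2 * 0.376 * 0.624 +
    pc[["age_over65"]]^2 * 0.596 * 0.404 +
    pc[["discriminated"]]^2 * 0.25 * 0.75 +
    pc[["work_change_occupation"]]^2 * 0.2 * 0.8 +
    pc[["work_change_relation"]]^2 * 0.2 * 0.8 +
    2 * pc[["work_change_occupation"]] * pc[["work_change_relation"]] *
      (-0.2 * 0.2) +
    cfg$dwelling_coefs[["no_adaptation"]]^2 * 0.25 +
    cfg$resid_var
  # empirical scale^2 is the realized Var(theta_raw)
  expect_equal(unname(tr$scale["scale"]^2), unname(expected), tolerance = 0.08)
})

test_that("zero coefficients and zero ICC give iid standard-normal abilities", {
  cfg <- generator_config(seed = 21, n_dwellings = 3000,
                          person_coefs = zero_coefs,
                          dwelling_coefs = c(no_adaptation = 0),
                          icc = 0, resid_var = 1)
  tr <- generate_truth(cfg)
  expect_equal(mean(tr$theta_lived), 0, tolerance = 1e-10)
  expect_equal(stats::shapiro.test(sample(tr$theta_lived, 1000))$p.value > 0.001,
               TRUE)
  # no dwelling clustering: random effects all zero variance
  expect_equal(tr$coefs_raw$tau2, 0)
})

test_that("response sampling follows the GRM category probabilities", {
  set.seed(99)
  n <- 50000
  ip <- item_params(1, rbind(c(-1, 1)))
  vals <- mlgrm:::sample_grm_matrix(ip, rep(0, n), "logit")
  freq <- tabulate(vals[, 1] + 1L, 3) / n
  expected <- c(plogis(-(-1)) * 0 + 1 - plogis(1), # P(Y=0) = 1 - F(1)
                plogis(1) - plogis(-1),
                plogis(-1))
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(freq - expected) < 3 * se))
  # huge discrimination: category fully determined by threshold exceedance
  ip2 <- item_params(500, rbind(c(-0.5, 0.5)))
  th <- c(-2, 0, 2)
  v2 <- mlgrm:::sample_grm_matrix(ip2, th, "probit")
  expect_identical(as.integer(v2), c(0L, 1L, 2L))
})

test_that("same seed reproduces the identical bundle", {
  b1 <- small_bundle(seed = 300)
  b2 <- small_bundle(seed = 300)
  expect_identical(b1$bio$values, b2$bio$values)
  expect_identical(b1$lived_observed$values, b2$lived_observed$values)
  expect_identical(b1$aid_use, b2$aid_use)
  expect_identical(b1$truth$coefs, b2$truth$coefs)
})

test_that("MCAR masking hits the configured rate independently of values", {
  rm <- tiny_rm(seed = 41, n = 500, n_items = 20)  # 10^4 cells
  rm$values[] <- sample(0:2, length(rm$values), replace = TRUE)
  out <- inject_missingness(rm, 0.1, seed = 5)
  new_na <- is.na(out$values) & !is.na(rm$values)
  rate <- sum(new_na) / sum(!is.na(rm$values))
  expect_gt(rate, 0.094 - 0.006)
  expect_lt(rate, 0.106 + 0.006)
  # masked-cell values are distributed like retained ones (MCAR)
  masked_vals <- rm$values[new_na]
  kept_vals <- out$values[!is.na(out$values)]
  tab <- rbind(tabulate(masked_vals + 1L, 3), tabulate(kept_vals + 1L, 3))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  # boundary behaviour
  expect_identical(inject_missingness(rm, 0)$values, rm$values)
  expect_error(inject_missingness(rm, 1), "rate")
})

test_that("aid use responds to lived health and hits its extremes", {
  cfg <- generator_config(seed = 55, n_dwellings = 2000)
  tr <- generate_truth(cfg)
  aid <- generate_aid_use(tr)
  q <- stats::quantile(tr$theta_lived, c(0.25, 0.75))
  worst <- rowMeans(aid[tr$theta_lived >= q[2], ])
  best <- rowMeans(aid[tr$theta_lived <= q[1], ])
  expect_gt(mean(worst), mean(best))
  # probability one: everyone answers lived questions directly
  cfg1 <- generator_config(seed = 55, n_dwellings = 200, aid_base_prob = 1)
  tr1 <- generate_truth(cfg1)
  expect_true(all(generate_aid_use(tr1)))
  # probability zero: equating forces lived == biological
  cfg0 <- generator_config(seed = 56, n_dwellings = 200, aid_base_prob = 0,
                           aid_theta_slope = 0, missing_rate = 0)
  b0 <- simulate_survey(cfg0)
  eq <- equate_lived_with_biological(b0$bio, b0$lived_observed, b0$aid_use,
                                     b0$item_map)
  expect_identical(unname(eq$values), unname(b0$bio$values))
})

test_that("bundles survive the CSV round trip", {
  b <- small_bundle(seed = 71, n_dwellings = 120, n_items = 6)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  r <- read_bundle(dir)
  expect_identical(r$bio$values, b$bio$values)
  expect_identical(r$lived_observed$values, b$lived_observed$values)
  expect_identical(r$aid_use, b$aid_use)
  expect_equal(r$weights, b$weights, tolerance = 1e-12)
  expect_identical(r$item_map, b$item_map)
  expect_equal(unname(unlist(r$truth$coefs$beta)),
               unname(b$truth$coefs$beta), tolerance = 1e-12)
})

test_that("generator configuration is validated", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(seed = 1, icc = 1.5), "icc")
  expect_error(generator_config(seed = 1, missing_rate = 1), "missing_rate")
  expect_error(generator_config(seed = 1, threshold_range = c(0, 0.1)),
               "threshold")
})
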