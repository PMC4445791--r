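test_that("one-factor data raises no local-dependence flags", {
  lam <- rep(c(0.7, 0.55, 0.65), 3)
  vals <- sim_factor_items(5000, lam, seed = 41)
  ld <- local_dependence(polychoric_matrix(vals), threshold = 0.25)
  expect_identical(nrow(ld$flagged), 0L)
})

test_that("a constructed doublet pair is flagged and order does not matter", {
  set.seed(42)
  n <- 4000
  f <- rnorm(n); d <- rnorm(n)   # shared doublet factor for items 2 and 5
  K <- 8
  vals <- matrix(0L, n, K)
  for (k in 1:K) {
    lam_d <- if (k %in% c(2, 5)) 0.72 else 0
    x <- 0.55 * f + lam_d * d + sqrt(1 - 0.55^2 - lam_d^2) * rnorm(n)
    vals[, k] <- as.integer(cut(x, c(-Inf, -0.4, 0.8, Inf))) - 1L
  }
  colnames(vals) <- paste0("it", 1:K)
  ld <- local_dependence(polychoric_matrix(vals))
  expect_true(any(ld$flagged$item_i == "it2" & ld$flagged$item_j == "it5"))
  # permuting item order leaves the flag set unchanged
  perm <- c(4, 2, 6, 1, 8, 5, 7, 3)
  ld2 <- local_dependence(polychoric_matrix(vals[, perm]))
  pairs1 <- with(ld$flagged, paste(pmin(item_i, item_j), pmax(item_i, item_j)))
  pairs2 <- with(ld2$flagged, paste(pmin(item_i, item_j), pmax(item_i, item_j)))
  expect_setequal(pairs1, pairs2)
  # a threshold of 1 can never flag
  expect_identical(nrow(local_dependence(polychoric_matrix(vals),
                                         threshold = 1)$flagged), 0L)
})

test_that("monotonicity verdicts separate GRM items from reversed items", {
  cfg <- generator_config(seed = 43, n_dwellings = 4400, missing_rate = 0)
  tr <- generate_truth(cfg)
  rm <- generate_responses(tr, "biological")
  mono <- monotonicity_check(rm)
  expect_true(all(mono$verdicts == "pass"))
  # reverse one item: its mean score now falls with the rest score
  vals <- rm$values
  vals[, 3] <- 2L - vals[, 3]
  mono_rev <- monotonicity_check(response_matrix(vals, rm$bank, rm$person_ids))
  expect_identical(unname(mono_rev$verdicts[3]), "fail")
  # constant item is non-decreasing, hence a pass
  vals2 <- rm$values
  vals2[, 1] <- 1L
  mono_const <- monotonicity_check(response_matrix(vals2, rm$bank,
                                                   rm$person_ids))
  expect_identical(unname(mono_const$verdicts[1]), "pass")
})

test_that("monotonicity verdicts are invariant to person permutation", {
  rm <- generate_responses(generate_truth(
    generator_config(seed = 44, n_dwellings = 900)), "biological")
  perm <- sample(nrow(rm$values))
  rm_p <- response_matrix(rm$values[perm, ], rm$bank, rm$person_ids[perm])
  expect_identical(monotonicity_check(rm)$verdicts,
                   monotonicity_check(rm_p)$verdicts)
})

test_that("too few persons yields an indeterminate verdict", {
  rm <- tiny_rm(seed = 45, n = 30)
  expect_true(all(monotonicity_check(rm, min_bin_size = 50)$verdicts ==
                    "indeterminate"))
})

test_that("item selection applies the retention rules", {
  items <- c("i1", "i2", "i3", "i4", "i5")
  # no flags: everything retained
  expect_identical(as.character(select_items(items)), items)
  # monotonicity failures are dropped outright
  mono <- structure(list(verdicts = c(i1 = "pass", i2 = "fail", i3 = "pass",
                                      i4 = "pass", i5 = "pass")),
                    class = "monotonicity_check")
  # within a dependent subset the highest provisional discrimination stays
  dep <- structure(list(flagged = data.frame(item_i = c("i3", "i4"),
                                             item_j = c("i4", "i5"),
                                             residual = c(0.4, 0.3))),
                   class = "local_dependence")
  disc <- c(i1 = 1.0, i2 = 3.0, i3 = 1.2, i4 = 2.4, i5 = 0.9)
  keep <- select_items(items, monotonicity = mono, dependence = dep,
                       discriminations = disc)
  expect_setequal(as.character(keep), c("i1", "i4"))
  expect_identical(attr(keep, "dropped_monotonicity"), "i2")
  expect_setequal(attr(keep, "dropped_dependence"), c("i3", "i5"))
  # flagged domains only warn
  bf <- structure(list(flagged_domains = "mobility"), class = "bifactor_check")
  expect_warning(select_items(items, bifactor = bf), "mobility")
})

test_that("robustness verdicts follow correlation and mean difference", {
  x <- rnorm(1000)
  same <- robustness_check(x, x)
  expect_equal(same$correlation, 1)
  expect_equal(same$mean_abs_diff, 0)
  expect_true(same$robust)
  noisy <- robustness_check(x, x + rnorm(1000, 0, 0.01))
  expect_true(noisy$robust)
  anti <- robustness_check(x, -x)
  expect_false(anti$robust)
  names(x) <- paste0("p", seq_along(x))
  y <- x[sample(length(x))]
  expect_true(robustness_check(x, y)$robust)  # name alignment, not order
  expect_error(robustness_check(x, unname(x)[1:10]), "different persons")
})
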