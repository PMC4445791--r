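test_that("responses round-trip through CSV with codes and mask intact", {
  rm0 <- tiny_rm(seed = 3, n = 25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(rm0, path)
  rm1 <- load_responses(path, rm0$bank, drop_all_missing = FALSE)
  expect_identical(rm1$values, rm0$values)
  expect_identical(rm1$person_ids, rm0$person_ids)
})

test_that("load_responses shifts the 1-based survey scale and masks blanks", {
  bank <- item_bank(c("i1", "i2"), domain = "mobility", n_categories = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,i1,i2", "p1,1,4", "p2,,2"), path)
  rm <- load_responses(path, bank)
  expect_identical(rm$values["p1", ], c(i1 = 0L, i2 = 3L))
  expect_true(is.na(rm$values["p2", "i1"]))
  expect_identical(rm$values["p2", "i2"], 1L)
})

test_that("load_responses rejects bad codes and unknown columns by name", {
  bank <- item_bank(c("i1", "i2"), domain = "mobility", n_categories = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,i1,i2", "p1,5,1"), path)
  expect_error(load_responses(path, bank), "i1.*p1|p1.*i1")
  writeLines(c("person_id,i1,i2,bogus", "p1,1,1,1"), path)
  expect_error(load_responses(path, bank), "bogus")
})

test_that("all-missing persons are dropped with a warning on load", {
  bank <- item_bank(c("i1", "i2"), domain = "selfcare", n_categories = 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,i1,i2", "p1,1,2", "p2,,"), path)
  expect_warning(rm <- load_responses(path, bank), "all responses missing")
  expect_identical(rm$person_ids, "p1")
})

test_that("category collapsing merges codes, preserves missing, validates maps", {
  bank <- item_bank("i1", domain = "mobility", n_categories = 4L)
  vals <- matrix(c(0L, 1L, 2L, 3L, NA), ncol = 1)
  rm <- response_matrix(vals, bank, paste0("p", 1:5))
  out <- collapse_categories(rm, c(0L, 1L, 1L, 2L))
  expect_identical(as.integer(out$values), c(0L, 1L, 1L, 2L, NA))
  expect_identical(out$bank$n_categories, 3L)
  # identity map leaves the matrix unchanged (idempotence)
  idt <- collapse_categories(rm, 0:3)
  expect_identical(idt$values, rm$values)
  expect_error(collapse_categories(rm, c(0L, 2L, 1L, 3L)), "non-decreasing")
  expect_error(collapse_categories(rm, c(0L, 0L, 0L, 2L)), "non-decreasing")
})

test_that("collapsing commutes with row filtering", {
  rm <- tiny_rm(seed = 9, n = 40, n_categories = 4L)
  mapping <- c(0L, 1L, 1L, 2L)
  ids <- rm$person_ids[seq(1, 40, by = 3)]
  a <- collapse_categories(subset_persons(rm, ids), mapping)
  b <- subset_persons(collapse_categories(rm, mapping), ids)
  expect_identical(a$values, b$values)
})

test_that("respondent filter keeps exactly the persons reporting difficulty", {
  bank <- item_bank(c("i1", "i2"), domain = "mobility", n_categories = 3L)
  vals <- rbind(c(0L, 0L),       # no difficulty -> dropped
                c(1L, 0L),       # one positive code -> kept
                c(NA, 0L),       # observed zero only -> dropped
                c(NA, 2L))       # kept
  rm <- response_matrix(vals, bank, paste0("p", 1:4))
  out <- filter_respondents(rm)
  expect_identical(out$kept, c("p2", "p4"))
  expect_identical(out$n_kept, 2L)
  # property: never removes a person holding any positive code
  rm2 <- tiny_rm(seed = 5, n = 60)
  kept <- filter_respondents(rm2)$kept
  has_pos <- apply(rm2$values, 1, function(v) any(v > 0, na.rm = TRUE))
  expect_setequal(kept, rm2$person_ids[has_pos])
  # empty result is an explicit error
  rm0 <- response_matrix(matrix(0L, 2, 2), bank, c("a", "b"))
  expect_error(filter_respondents(rm0), "no person")
})

test_that("filter keeps the empirically counted share of a generated survey", {
  b <- small_bundle(seed = 61, n_dwellings = 800)
  out <- filter_respondents(b$bio)
  prevalence <- mean(apply(b$bio$values, 1, function(v)
    any(v > 0, na.rm = TRUE)))
  expect_equal(out$n_kept / out$n_total, prevalence)
})

test_that("equating copies biological responses for non-aid users only", {
  bank_b <- item_bank(c("b1", "b2"), domain = c("mobility", "selfcare"))
  bank_l <- item_bank(c("l1", "l2"), domain = c("mobility", "selfcare"),
                      role = "lived")
  bio <- response_matrix(rbind(c(2L, 1L), c(1L, NA)), bank_b, c("p1", "p2"))
  lived <- response_matrix(rbind(c(NA, 0L), c(NA, NA)), bank_l, c("p1", "p2"))
  aid <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2,
                dimnames = list(c("p1", "p2"), c("mobility", "selfcare")))
  out <- equate_lived_with_biological(bio, lived, aid,
                                      item_map = c(l1 = "b1", l2 = "b2"))
  expect_identical(out$values["p1", "l1"], 2L)  # copied
  expect_identical(out$values["p1", "l2"], 0L)  # aid user keeps own
  expect_identical(out$values["p2", "l1"], 1L)
  expect_true(is.na(out$values["p2", "l2"]))            # bio missing -> missing
  # lived item with no biological partner errors when a copy is needed
  expect_error(
    equate_lived_with_biological(bio, lived, aid,
                                 item_map = c(l1 = "b1", l2 = NA)),
    "no matched biological item")
})

test_that("weighted descriptives match hand arithmetic and are order-invariant", {
  cov <- data.frame(grp = c("A", "B"), sex = c("f", "m"))
  out <- weighted_descriptives(cov, c(2, 1))
  expect_equal(out$pct[out$variable == "grp" & out$category == "A"], 200 / 3)
  # equal weights reproduce unweighted proportions
  cov2 <- data.frame(g = c("x", "x", "y"))
  expect_equal(weighted_descriptives(cov2, NULL)$pct, c(200 / 3, 100 / 3))
  # permutation invariance
  set.seed(4)
  cov3 <- data.frame(g = sample(letters[1:3], 30, replace = TRUE))
  w <- runif(30)
  perm <- sample(30)
  expect_equal(weighted_descriptives(cov3, w),
               weighted_descriptives(cov3[perm, , drop = FALSE], w[perm]))
  expect_error(weighted_descriptives(cov3, -w), "negative")
  # percentages sum to 100 within each variable
  expect_equal(sum(weighted_descriptives(cov3, w)$pct), 100)
})

test_that("dwelling index enforces one dwelling per person", {
  expect_error(dwelling_index(c("p1", "p1"), c("d1", "d2")), "exactly one")
  di <- dwelling_index(c("p1", "p2"), c("d1", "d1"))
  expect_identical(di$dwelling_id, c("d1", "d1"))
})
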