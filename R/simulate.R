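#' Configuration of the synthetic nested-survey generator
#'
#' Defaults emulate the structure of a national disability survey of
#' community-dwelling adults: near-singleton dwellings (mean cluster size
#' 17303/15263), three-category collapsed ordinal items in several
#' functioning domains, lived-health items answered only by users of
#' technical aids or personal assistance, and missing item responses missing
#' completely at random.
#'
#' The default structural coefficients are the published estimates for the
#' corresponding survey covariates (biological health 0.902, male gender
#' -0.172, age over 65 0.101, feeling discriminated -0.103, change of
#' occupation 0.269, change in work activity 0.148). The dwelling-level
#' coefficient (0.6) and the residual variance (0.235, split by a residual
#' intraclass correlation of 0.15) are generator choices that reproduce a
#' variance structure in which covariates explain roughly three quarters of
#' the latent-trait variance at both levels; see the methods vignette.
#'
#' @param n_dwellings number of dwellings J.
#' @param mean_cluster_size mean persons per dwelling; cluster sizes are drawn
#'   as `1 + Poisson(mean - 1)`.
#' @param n_items items per role (biological and lived).
#' @param n_categories ordered categories per item.
#' @param disc_range range from which item discriminations are drawn
#'   uniformly.
#' @param threshold_range range for item thresholds; per item, `C - 1` sorted
#'   uniform draws with minimum spacing `threshold_gap`.
#' @param threshold_gap minimum spacing between adjacent thresholds.
#' @param person_coefs named coefficients for the person-level design columns
#'   `biological`, `male`, `age_over65`, `discriminated`,
#'   `work_change_occupation`, `work_change_relation`.
#' @param dwelling_coefs named coefficient for the dwelling-level column
#'   `no_adaptation`.
#' @param icc residual intraclass correlation `tau2 / (tau2 + sigma2)`.
#' @param resid_var total residual variance `tau2 + sigma2` on the raw scale.
#' @param missing_rate MCAR missingness rate applied to item responses.
#' @param aid_base_prob marginal aid-use probability at average lived health.
#' @param aid_theta_slope logit-scale dependence of aid use on lived health
#'   (positive: worse health, more aid use).
#' @param link response function used to generate responses.
#' @param seed mandatory integer seed; the whole bundle is reproducible from
#'   it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_dwellings = 2000,
                             mean_cluster_size = 17303 / 15263,
                             n_items = 15L,
                             n_categories = 3L,
                             disc_range = c(0.865, 3.218),
                             threshold_range = c(-0.5, 2.5),
                             threshold_gap = 0.3,
                             person_coefs = c(biological = 0.902,
                                              male = -0.172,
                                              age_over65 = 0.101,
                                              discriminated = -0.103,
                                              work_change_occupation = 0.269,
                                              work_change_relation = 0.148),
                             dwelling_coefs = c(no_adaptation = 0.6),
                             icc = 0.15,
                             resid_var = 0.235,
                             missing_rate = 0.05,
                             aid_base_prob = 0.5,
                             aid_theta_slope = 1,
                             link = "probit",
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility", call. = FALSE)
  if (n_dwellings < 1) stop("need at least one dwelling", call. = FALSE)
  if (mean_cluster_size < 1) stop("mean cluster size must be >= 1", call. = FALSE)
  if (icc < 0 || icc > 1) stop("icc must lie in [0, 1]", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (diff(disc_range) < 0 || disc_range[1] <= 0) {
    stop("invalid discrimination range", call. = FALSE)
  }
  if (diff(threshold_range) < threshold_gap * (n_categories - 1L)) {
    stop("threshold range cannot hold ", n_categories - 1L,
         " thresholds spaced by ", threshold_gap, call. = FALSE)
  }
  structure(list(n_dwellings = as.integer(n_dwellings),
                 mean_cluster_size = mean_cluster_size,
                 n_items = as.integer(n_items),
                 n_categories = as.integer(n_categories),
                 disc_range = disc_range,
                 threshold_range = threshold_range,
                 threshold_gap = threshold_gap,
                 person_coefs = person_coefs,
                 dwelling_coefs = dwelling_coefs,
                 icc = icc, resid_var = resid_var,
                 missing_rate = missing_rate,
                 aid_base_prob = aid_base_prob,
                 aid_theta_slope = aid_theta_slope,
                 link = match.arg(link, c("probit", "logit")),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Assign persons to dwellings
#'
#' Cluster sizes are `1 + Poisson(mean_cluster_size - 1)`, matching the
#' near-singleton household structure of community-dwelling survey data.
#'
#' @param config a [generator_config()]. The generator seed is used unless
#'   the call happens inside a longer seeded simulation.
#' @param use_seed set the seed from the config before drawing (default TRUE;
#'   [simulate_survey()] seeds once globally and turns this off).
#' @return A [dwelling_index()] with attribute `"sizes"`.
#' @export
generate_nesting <- function(config, use_seed = TRUE) {
  if (use_seed) set.seed(config$seed)
  J <- config$n_dwellings
  sizes <- 1L + stats::rpois(J, config$mean_cluster_size - 1)
  dwelling_id <- sprintf("d%05d", seq_len(J))
  person_dwelling <- rep(dwelling_id, sizes)
  person_id <- sprintf("p%06d", seq_along(person_dwelling))
  out <- dwelling_index(person_id, person_dwelling)
  attr(out, "sizes") <- sizes
  out
}

default_domains <- c("communication", "mobility", "selfcare")

draw_item_params <- function(config, role) {
  K <- config$n_items
  C <- config$n_categories
  a <- stats::runif(K, config$disc_range[1], config$disc_range[2])
  kappa <- matrix(NA_real_, K, C - 1L)
  for (k in seq_len(K)) {
    repeat {
      kk <- sort(stats::runif(C - 1L, config$threshold_range[1],
                              config$threshold_range[2]))
      if (C == 2L || min(diff(kk)) >= config$threshold_gap) break
    }
    kappa[k, ] <- kk
  }
  prefix <- if (role == "biological") "bio" else "liv"
  item_params(a, kappa, sprintf("%s_%02d", prefix, seq_len(K)))
}

#' Draw the generating truth of a synthetic survey
#'
#' Generates item parameters for the biological and lived item sets,
#' covariates, dwelling random effects and latent traits. Lived health
#' follows the structural model
#' `theta = x'beta + w'gamma + u_j + e_ij`, `u_j ~ N(0, tau2)`,
#' `e_ij ~ N(0, sigma2)`; the biological-health covariate doubles as the
#' latent trait generating the biological item responses. Both latent traits
#' are standardized empirically (mean 0, variance 1), so the stored truth —
#' including coefficients, random effects and variances — lives on the
#' identified scale that a fitted model reports; the raw configured
#' coefficients are kept alongside.
#'
#' @inheritParams generate_nesting
#' @return A list of class `synthetic_truth`.
#' @export
generate_truth <- function(config, use_seed = TRUE) {
  if (use_seed) set.seed(config$seed)
  nesting <- generate_nesting(config, use_seed = FALSE)
  n <- nrow(nesting)
  J <- config$n_dwellings
  j_of <- match(nesting$dwelling_id, unique(nesting$dwelling_id))

  items <- list(biological = draw_item_params(config, "biological"),
                lived = draw_item_params(config, "lived"))

  # person covariates; marginal frequencies follow the survey descriptives
  # (62.4% female, 40.4% aged <= 65)
  bio_raw <- stats::rnorm(n)
  theta_bio <- (bio_raw - mean(bio_raw)) / stats::sd(bio_raw)
  male <- stats::rbinom(n, 1L, 0.376)
  age_over65 <- stats::rbinom(n, 1L, 0.596)
  discriminated <- stats::rbinom(n, 1L, 0.25)
  work_change <- sample(c("no_change", "occupation", "relation"), n,
                        replace = TRUE, prob = c(0.6, 0.2, 0.2))
  person_design <- cbind(biological = theta_bio,
                         male = male,
                         age_over65 = age_over65,
                         discriminated = discriminated,
                         work_change_occupation = as.numeric(work_change == "occupation"),
                         work_change_relation = as.numeric(work_change == "relation"))
  no_adaptation <- stats::rbinom(J, 1L, 0.5)
  dwelling_design <- cbind(no_adaptation = no_adaptation)
  rownames(dwelling_design) <- unique(nesting$dwelling_id)

  beta <- config$person_coefs[colnames(person_design)]
  beta[is.na(beta)] <- 0
  gamma <- config$dwelling_coefs[colnames(dwelling_design)]
  gamma[is.na(gamma)] <- 0

  tau2 <- config$icc * config$resid_var
  sigma2 <- (1 - config$icc) * config$resid_var
  u <- stats::rnorm(J, 0, sqrt(tau2))
  e <- stats::rnorm(n, 0, sqrt(sigma2))
  theta_raw <- drop(person_design %*% beta) +
    drop(dwelling_design[j_of, , drop = FALSE] %*% gamma) + u[j_of] + e
  m <- mean(theta_raw)
  s <- sqrt(mean((theta_raw - m)^2))
  if (s == 0) s <- 1
  theta <- (theta_raw - m) / s

  structure(list(
    config = config,
    nesting = nesting,
    dwelling_of = j_of,
    items = items,
    person_design = person_design,
    dwelling_design = dwelling_design,
    work_change = work_change,
    theta_bio = theta_bio,
    theta_lived = theta,
    coefs_raw = list(beta = beta, gamma = gamma,
                     tau2 = tau2, sigma2 = sigma2),
    # the truth on the identified (standardized) scale a fit reports
    coefs = list(intercept = -m / s, beta = beta / s, gamma = gamma / s,
                 u = u / s, tau2 = tau2 / s^2, sigma2 = sigma2 / s^2),
    scale = c(center = m, scale = s)
  ), class = "synthetic_truth")
}

sample_grm_matrix <- function(ip, theta, link) {
  n <- length(theta)
  K <- length(ip$a)
  C <- ncol(ip$kappa) + 1L
  F <- link_cdf(link)
  out <- matrix(NA_integer_, n, K)
  for (k in seq_len(K)) {
    cum <- F(outer(theta, ip$kappa[k, ], function(t, kk) ip$a[k] * (t - kk)))
    out[, k] <- as.integer(rowSums(stats::runif(n) < cum))
  }
  out
}

#' Sample item responses from the graded response model
#'
#' @param truth a [generate_truth()] result.
#' @param role `"biological"` or `"lived"`: which item set and latent trait.
#' @param link response function; defaults to the generator config.
#' @param use_seed seed from the config first (see [generate_nesting()]).
#' @return A [response_matrix()] with a matching [item_bank()].
#' @export
generate_responses <- function(truth, role = c("lived", "biological"),
                               link = truth$config$link, use_seed = FALSE) {
  role <- match.arg(role)
  if (use_seed) set.seed(truth$config$seed)
  ip <- truth$items[[role]]
  theta <- if (role == "lived") truth$theta_lived else truth$theta_bio
  vals <- sample_grm_matrix(ip, theta, link)
  domains <- rep_len(default_domains, length(ip$a))
  bank <- item_bank(ip$item_id, domain = domains, role = role,
                    n_categories = truth$config$n_categories)
  response_matrix(vals, bank, truth$nesting$person_id)
}

#' Simulate graded responses for a fixed item bank
#'
#' Samples a persons-by-items matrix from the graded response model at given
#' abilities and item parameters — the building block for designed
#' parameter-recovery experiments with a known, fixed item bank.
#'
#' @param items an [item_params()].
#' @param theta ability vector.
#' @param link `"probit"` or `"logit"`.
#' @param domains optional domain labels for the item bank (recycled).
#' @param role item role for the bank.
#' @return A [response_matrix()].
#' @export
simulate_grm_responses <- function(items, theta, link = "probit",
                                   domains = default_domains,
                                   role = "biological") {
  vals <- sample_grm_matrix(items, theta, link)
  bank <- item_bank(items$item_id, domain = rep_len(domains, length(items$a)),
                    role = role, n_categories = ncol(items$kappa) + 1L)
  response_matrix(vals, bank, sprintf("p%06d", seq_along(theta)))
}

#' Mask responses completely at random
#'
#' @param rm a [response_matrix()].
#' @param rate missingness probability in `[0, 1)`, independent of everything.
#' @param seed optional seed.
#' @return The masked [response_matrix()].
#' @export
inject_missingness <- function(rm, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(rm)
  vals <- rm$values
  mask <- matrix(stats::runif(length(vals)) < rate, nrow(vals), ncol(vals))
  vals[mask] <- NA_integer_
  response_matrix(vals, rm$bank, rm$person_ids)
}

#' Draw aid-use indicators
#'
#' Whether a person uses technical aids and/or personal assistance in each
#' functioning domain; only aid users answer the lived-health questions. The
#' probability follows a logistic model in lived health, so people in worse
#' health are more likely to use aids.
#'
#' @param truth a [generate_truth()] result.
#' @param config a [generator_config()] (defaults to the truth's).
#' @param use_seed seed from the config first.
#' @return Logical matrix persons x domains.
#' @export
generate_aid_use <- function(truth, config = truth$config, use_seed = FALSE) {
  if (use_seed) set.seed(config$seed)
  domains <- unique(rep_len(default_domains, config$n_items))
  eta0 <- stats::qlogis(config$aid_base_prob)
  p <- stats::plogis(eta0 + config$aid_theta_slope * truth$theta_lived)
  n <- length(p)
  out <- matrix(stats::runif(n * length(domains)) < p, n, length(domains),
                dimnames = list(truth$nesting$person_id, domains))
  out
}

#' Generate a complete synthetic survey bundle
#'
#' Runs the whole generator under a single seed: nesting, truth, biological
#' and lived responses, aid use, MCAR missingness, sampling weights. The
#' lived response matrix is reduced to what a survey would observe: non-aid
#' users in a domain leave its lived items blank (the analysis later equates
#' them with biological health via [equate_lived_with_biological()]).
#'
#' @param config a [generator_config()].
#' @return A list of class `survey_bundle` with elements `truth`, `bio`,
#'   `lived_observed`, `lived_complete`, `aid_use`, `dwellings`,
#'   `covariates_person`, `covariates_dwelling`, `weights`, `item_map`.
#' @export
simulate_survey <- function(config) {
  set.seed(config$seed)
  truth <- generate_truth(config, use_seed = FALSE)
  bio <- generate_responses(truth, "biological")
  lived <- generate_responses(truth, "lived")
  aid <- generate_aid_use(truth)

  # lived questions are only answered by aid users in the item's domain
  lived_obs_vals <- lived$values
  for (k in seq_len(ncol(lived_obs_vals))) {
    dom <- lived$bank$domain[k]
    lived_obs_vals[!aid[, dom], k] <- NA_integer_
  }
  lived_observed <- response_matrix(lived_obs_vals, lived$bank, lived$person_ids)

  if (config$missing_rate > 0) {
    bio <- inject_missingness(bio, config$missing_rate)
    lived_observed <- inject_missingness(lived_observed, config$missing_rate)
  }

  item_map <- stats::setNames(truth$items$biological$item_id,
                              truth$items$lived$item_id)
  n <- nrow(truth$nesting)
  weights <- exp(stats::rnorm(n, 0, 0.3))

  covariates_person <- data.frame(
    person_id = truth$nesting$person_id,
    as.data.frame(truth$person_design),
    work_change = truth$work_change,
    stringsAsFactors = FALSE
  )
  covariates_dwelling <- data.frame(
    dwelling_id = rownames(truth$dwelling_design),
    as.data.frame(truth$dwelling_design),
    stringsAsFactors = FALSE
  )

  structure(list(truth = truth,
                 bio = bio,
                 lived_observed = lived_observed,
                 lived_complete = lived,
                 aid_use = aid,
                 dwellings = truth$nesting,
                 covariates_person = covariates_person,
                 covariates_dwelling = covariates_dwelling,
                 weights = weights,
                 item_map = item_map),
            class = "survey_bundle")
}

#' Write a survey bundle as delimited text files
#'
#' Writes the CSV bundle (`responses_biological.csv`, `responses_lived.csv`,
#' `covariates_person.csv`, `covariates_dwelling.csv`, `dwellings.csv`,
#' `aid_use.csv`, `weights.csv`, `items.csv`, `item_map.csv`) plus
#' `truth.json` with the generating parameters.
#'
#' @param bundle a [simulate_survey()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_responses(bundle$bio, fp("responses_biological.csv"))
  write_responses(bundle$lived_observed, fp("responses_lived.csv"))
  utils::write.csv(bundle$covariates_person, fp("covariates_person.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$covariates_dwelling, fp("covariates_dwelling.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$dwellings, fp("dwellings.csv"), row.names = FALSE)
  aid <- data.frame(person_id = rownames(bundle$aid_use),
                    bundle$aid_use * 1L)
  utils::write.csv(aid, fp("aid_use.csv"), row.names = FALSE)
  utils::write.csv(data.frame(person_id = bundle$dwellings$person_id,
                              weight = bundle$weights),
                   fp("weights.csv"), row.names = FALSE)
  banks <- rbind(bundle$bio$bank, bundle$lived_observed$bank)
  utils::write.csv(banks, fp("items.csv"), row.names = FALSE)
  utils::write.csv(data.frame(lived_id = names(bundle$item_map),
                              biological_id = unname(bundle$item_map)),
                   fp("item_map.csv"), row.names = FALSE)
  truth <- bundle$truth
  jsonlite::write_json(list(
    seed = truth$config$seed,
    items = lapply(truth$items, function(ip)
      list(item_id = ip$item_id, a = ip$a, kappa = ip$kappa)),
    coefs = truth$coefs[c("intercept", "beta", "gamma", "tau2", "sigma2")],
    coefs_raw = truth$coefs_raw,
    scale = as.list(truth$scale)
  ), fp("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a survey bundle written by [write_bundle()]
#'
#' @param dir directory holding the CSV bundle.
#' @return A list with the same data elements as [simulate_survey()] (without
#'   the full `truth` object; `truth.json` is attached as parsed JSON when
#'   present).
#' @export
read_bundle <- function(dir) {
  fp <- function(f) file.path(dir, f)
  for (f in c("responses_biological.csv", "responses_lived.csv", "items.csv",
              "dwellings.csv", "aid_use.csv")) {
    if (!file.exists(fp(f))) stop("bundle is missing ", f, call. = FALSE)
  }
  banks <- utils::read.csv(fp("items.csv"), stringsAsFactors = FALSE)
  mk_bank <- function(role) {
    b <- banks[banks$role == role, ]
    item_bank(b$item_id, b$domain, role, b$n_categories)
  }
  bio <- load_responses(fp("responses_biological.csv"), mk_bank("biological"))
  lived <- load_responses(fp("responses_lived.csv"), mk_bank("lived"),
                          drop_all_missing = FALSE)
  dw <- utils::read.csv(fp("dwellings.csv"), colClasses = "character")
  aid_df <- utils::read.csv(fp("aid_use.csv"), stringsAsFactors = FALSE)
  aid <- as.matrix(aid_df[, -1, drop = FALSE]) > 0
  rownames(aid) <- aid_df$person_id
  cp <- if (file.exists(fp("covariates_person.csv")))
    utils::read.csv(fp("covariates_person.csv"), stringsAsFactors = FALSE) else NULL
  cd <- if (file.exists(fp("covariates_dwelling.csv")))
    utils::read.csv(fp("covariates_dwelling.csv"), stringsAsFactors = FALSE) else NULL
  wt <- if (file.exists(fp("weights.csv")))
    utils::read.csv(fp("weights.csv"))$weight else NULL
  imap <- if (file.exists(fp("item_map.csv"))) {
    m <- utils::read.csv(fp("item_map.csv"), stringsAsFactors = FALSE)
    stats::setNames(m$biological_id, m$lived_id)
  } else NULL
  truth <- if (file.exists(fp("truth.json")))
    jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE) else NULL
  list(bio = bio, lived_observed = lived,
       aid_use = aid, dwellings = dwelling_index(dw$person_id, dw$dwelling_id),
       covariates_person = cp, covariates_dwelling = cd,
       weights = wt, item_map = imap, truth = truth)
}
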