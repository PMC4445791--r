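# Shared fixtures: everything is generated in code at test time.

# a small three-domain item bank
tiny_bank <- function(n_items = 4L, role = "biological", n_categories = 3L) {
  item_bank(sprintf("%s_%02d", substr(role, 1, 3), seq_len(n_items)),
            domain = rep_len(c("communication", "mobility", "selfcare"),
                             n_items),
            role = role, n_categories = n_categories)
}

# deterministic small response matrix with some missingness
tiny_rm <- function(seed = 1, n = 20L, n_items = 4L, n_categories = 3L) {
  set.seed(seed)
  bank <- tiny_bank(n_items, n_categories = n_categories)
  vals <- matrix(sample(0:(n_categories - 1L), n * n_items, replace = TRUE),
                 n, n_items)
  vals[sample(length(vals), floor(length(vals) / 10))] <- NA_integer_
  response_matrix(vals, bank, sprintf("p%03d", seq_len(n)))
}

# brute-force GRM cell log-likelihood, written independently of grm_loglik:
# explicit double loop and direct CDF differences
brute_loglik <- function(values, a, kappa, theta, link) {
  F <- if (link == "probit") pnorm else plogis
  total <- 0
  for (i in seq_len(nrow(values))) {
    for (k in seq_len(ncol(values))) {
      y <- values[i, k]
      if (is.na(y)) next
      C <- ncol(kappa) + 1L
      upper <- if (y == 0L) 1 else F(a[k] * (theta[i] - kappa[k, y]))
      lower <- if (y == C - 1L) 0 else F(a[k] * (theta[i] - kappa[k, y + 1L]))
      total <- total + log(max(upper - lower, 1e-300))
    }
  }
  total
}

# brute-force shortest-window HPD over all candidate windows
brute_hpd <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  keep <- min(ceiling(prob * n), n)
  best <- c(x[1], x[n])
  for (i in seq_len(n - keep + 1L)) {
    if (x[i + keep - 1L] - x[i] < best[2] - best[1]) {
      best <- c(x[i], x[i + keep - 1L])
    }
  }
  best
}

# quick generator shortcut for sampler tests
small_bundle <- function(seed, n_dwellings = 400L, n_items = 8L, ...) {
  simulate_survey(generator_config(seed = seed, n_dwellings = n_dwellings,
                                   n_items = n_items, ...))
}

zero_coefs <- c(biological = 0, male = 0, age_over65 = 0, discriminated = 0,
                work_change_occupation = 0, work_change_relation = 0)

# ordinal items from a general factor plus an optional group factor
sim_factor_items <- function(n, loadings, group = NULL, group_loading = 0,
                             groups = NULL, seed = 1) {
  set.seed(seed)
  K <- length(loadings)
  f <- rnorm(n)
  g <- if (!is.null(group)) rnorm(n) else NULL
  vals <- matrix(0L, n, K)
  for (k in seq_len(K)) {
    lam_g <- if (!is.null(group) && groups[k] == group) group_loading else 0
    uniq <- sqrt(max(1 - loadings[k]^2 - lam_g^2, 0.05))
    x <- loadings[k] * f + lam_g * (if (is.null(g)) 0 else g) + uniq * rnorm(n)
    vals[, k] <- as.integer(cut(x, c(-Inf, -0.4, 0.8, Inf))) - 1L
  }
  colnames(vals) <- paste0("it", seq_len(K))
  vals
}
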