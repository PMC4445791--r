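#' MCMC configuration for the multilevel graded response model
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded (must be < `n_iter`); proposal scales
#'   adapt only during burn-in.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed mandatory integer seed.
#' @param link `"probit"` (default; conjugate data augmentation) or `"logit"`
#'   (Metropolis-within-Gibbs).
#' @param prior_a_mean,prior_a_var normal prior for discriminations,
#'   truncated to a > 0.
#' @param prior_beta_var prior variance of each structural coefficient
#'   (mean-zero normal).
#' @param prior_var_shape,prior_var_rate inverse-gamma hyperparameters of the
#'   person residual variance (and of the dwelling variance when
#'   `prior_tau = "inverse_gamma"`).
#' @param prior_tau prior family for the dwelling standard deviation:
#'   `"half_cauchy"` (default) or `"inverse_gamma"` on the variance. With
#'   mostly-singleton clusters the dwelling variance is weakly identified and
#'   the vague inverse-gamma prior concentrates it towards zero; the
#'   half-Cauchy is the standard weakly-informative alternative.
#' @param prior_tau_scale scale of the half-Cauchy prior on the dwelling SD.
#' @param store_theta keep the full ability trace (memory-hungry); by default
#'   only running posterior means/variances per person are kept.
#' @param check_identify record, at every stored iteration, the ability mean
#'   and variance and the log-likelihood drift across the identification
#'   rescaling.
#' @param fix_theta optional numeric vector clamping the abilities at known
#'   values; skips the ability update and the identification rescaling
#'   (used for calibration and recovery checks).
#' @param tau2_fixed optionally pin the dwelling variance (e.g. 0 to drop the
#'   random effect).
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 5000L, burn_in = 1000L, thin = 1L, seed,
                        link = "probit",
                        prior_a_mean = 1, prior_a_var = 10,
                        prior_beta_var = 100,
                        prior_var_shape = 0.001, prior_var_rate = 0.001,
                        prior_tau = "half_cauchy", prior_tau_scale = 1,
                        store_theta = FALSE, check_identify = TRUE,
                        fix_theta = NULL, tau2_fixed = NULL) {
  if (missing(seed)) stop("an MCMC seed is mandatory", call. = FALSE)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 link = match.arg(link, c("probit", "logit")),
                 prior_a_mean = prior_a_mean, prior_a_var = prior_a_var,
                 prior_beta_var = prior_beta_var,
                 prior_var_shape = prior_var_shape,
                 prior_var_rate = prior_var_rate,
                 prior_tau = match.arg(prior_tau,
                                       c("half_cauchy", "inverse_gamma")),
                 prior_tau_scale = prior_tau_scale,
                 store_theta = store_theta, check_identify = check_identify,
                 fix_theta = fix_theta, tau2_fixed = tau2_fixed),
            class = "mcmc_config")
}

# ordinal log-likelihood of one item at cutpoints g (latent-normal scale,
# probit) given discrimination a and abilities theta; y is 1-based category
item_loglik_probit <- function(y, g, a_theta) {
  gg <- c(-Inf, g, Inf)
  p <- stats::pnorm(gg[y + 1L] - a_theta) - stats::pnorm(gg[y] - a_theta)
  sum(log(pmax(p, 1e-300)))
}

item_loglik_logit <- function(y, kappa, a, theta) {
  kk <- c(-Inf, kappa, Inf)
  p <- stats::plogis(a * (theta - kk[y])) - stats::plogis(a * (theta - kk[y + 1L]))
  sum(log(pmax(p, 1e-300)))
}

# per-person logit measurement log-likelihood (vector over persons)
person_loglik_logit <- function(Y, a, kappa, theta) {
  n <- nrow(Y)
  ll <- numeric(n)
  for (k in seq_len(ncol(Y))) {
    y <- Y[, k]
    obs <- which(!is.na(y))
    if (!length(obs)) next
    kk <- c(-Inf, kappa[k, ], Inf)
    p <- stats::plogis(a[k] * (theta[obs] - kk[y[obs] + 1L])) -
      stats::plogis(a[k] * (theta[obs] - kk[y[obs] + 2L]))
    ll[obs] <- ll[obs] + log(pmax(p, 1e-300))
  }
  ll
}

#' Fit the multilevel graded response model by MCMC
#'
#' Couples a graded response measurement model for ordinal items to a
#' two-level structural regression of the latent trait on person- and
#' dwelling-level covariates with dwelling random effects:
#' `theta_ij = x_ij' beta + w_j' gamma + u_j + e_ij`,
#' `u_j ~ N(0, tau2)`, `e_ij ~ N(0, sigma2)`.
#'
#' Under the probit link the measurement side uses truncated-normal data
#' augmentation with conjugate discrimination updates and a Metropolis step
#' (augmented data collapsed out) for the category cutpoints; abilities and
#' all structural parameters have conjugate normal / inverse-gamma full
#' conditionals. Under the logit link item parameters and abilities are
#' updated by adaptive random-walk Metropolis. After every iteration the
#' latent scale is identified by rescaling the sampled abilities to mean 0
#' and variance 1, with the compensating transform applied to all other
#' parameters, which leaves the observed-data likelihood unchanged.
#'
#' Missing responses are skipped cell-wise; persons with no observed items
#' draw their ability from the structural model alone.
#'
#' @param rm a [response_matrix()] (or `NULL` for a structural-only run with
#'   `fix_theta`). All items must share one number of categories.
#' @param dwellings a [dwelling_index()] covering the persons of `rm`.
#' @param person_covariates numeric matrix (persons x p) of reference-coded
#'   person-level covariates, aligned with (or rownamed by) the persons of
#'   `rm`; `NULL` for intercept-only.
#' @param dwelling_covariates numeric matrix (dwellings x q) rownamed by
#'   dwelling id; `NULL` for none.
#' @param config an [mcmc_config()].
#' @param fixed_covariates character vector naming covariate columns entered
#'   as error-free known predictors. In this two-step implementation every
#'   covariate column is a known design value (error fixed to zero), so the
#'   argument only labels them as such in the fit object.
#' @return An object of class `mlirt_fit`; see [summary.mlirt_fit()],
#'   [compute_dic()], [geweke_diagnostic()].
#' @export
run_mcmc <- function(rm, dwellings, person_covariates = NULL,
                     dwelling_covariates = NULL, config,
                     fixed_covariates = NULL) {
  stopifnot(inherits(config, "mcmc_config"))
  set.seed(config$seed)
  link <- config$link

  # ---- assemble data ----
  if (is.null(rm)) {
    if (is.null(config$fix_theta)) {
      stop("rm = NULL requires fix_theta (structural-only run)", call. = FALSE)
    }
    n <- length(config$fix_theta)
    person_ids <- if (!is.null(names(config$fix_theta)))
      names(config$fix_theta) else paste0("p", seq_len(n))
    Y <- matrix(NA_integer_, n, 0L)
    C <- 0L
  } else {
    Y <- rm$values
    n <- nrow(Y)
    person_ids <- rm$person_ids
    ncat <- unique(rm$bank$n_categories)
    if (length(ncat) != 1L) {
      stop("all items must share one number of categories at fit time",
           call. = FALSE)
    }
    C <- as.integer(ncat)
  }
  K <- ncol(Y)

  di <- dwellings[match(person_ids, dwellings$person_id), , drop = FALSE]
  if (anyNA(di$dwelling_id)) stop("persons missing from dwelling index", call. = FALSE)
  dw_ids <- unique(di$dwelling_id)
  j_of <- match(di$dwelling_id, dw_ids)
  J <- length(dw_ids)
  nj <- tabulate(j_of, J)

  Xp <- if (is.null(person_covariates)) NULL else {
    X <- as.matrix(person_covariates)
    if (!is.null(rownames(X)) && all(person_ids %in% rownames(X))) {
      X <- X[person_ids, , drop = FALSE]
    } else if (nrow(X) != n) {
      stop("person covariates misaligned with persons", call. = FALSE)
    }
    X
  }
  Wx <- if (is.null(dwelling_covariates)) NULL else {
    W <- as.matrix(dwelling_covariates)
    if (!is.null(rownames(W)) && all(dw_ids %in% rownames(W))) {
      W <- W[dw_ids, , drop = FALSE]
    } else if (nrow(W) != J) {
      stop("dwelling covariates misaligned with dwellings", call. = FALSE)
    }
    W[j_of, , drop = FALSE]
  }
  D <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(Xp)) D <- cbind(D, Xp)
  if (!is.null(Wx)) D <- cbind(D, Wx)
  P <- ncol(D)
  if (qr(D)$rank < P) stop("structural design matrix is rank deficient", call. = FALSE)
  n_person_cov <- if (is.null(Xp)) 0L else ncol(Xp)
  coef_block <- c("intercept",
                  rep("person", n_person_cov),
                  rep("dwelling", P - 1L - n_person_cov))

  obs_list <- lapply(seq_len(K), function(k) which(!is.na(Y[, k])))
  y_list <- lapply(seq_len(K), function(k) Y[obs_list[[k]], k] + 1L)

  # ---- initial state ----
  fix_theta <- config$fix_theta
  if (!is.null(fix_theta) && length(fix_theta) != n) {
    stop("fix_theta must have one value per person", call. = FALSE)
  }
  if (K > 0L) {
    a <- rep(1, K)
    qfun <- if (link == "probit") stats::qnorm else stats::qlogis
    cut0 <- matrix(0, K, C - 1L)
    for (k in seq_len(K)) {
      tabk <- tabulate(y_list[[k]], C)
      cp <- cumsum(tabk) / max(sum(tabk), 1L)
      cp <- pmin(pmax(cp[-C], 1 / (2 * max(sum(tabk), 2L))),
                 1 - 1 / (2 * max(sum(tabk), 2L)))
      cp <- cummax(cp + seq(0, 1e-6, length.out = C - 1L))  # enforce order
      cut0[k, ] <- qfun(cp)
    }
    g <- cut0                      # probit: latent cutpoints; logit: thresholds
    rs <- rowMeans(Y, na.rm = TRUE)
    rs[is.nan(rs)] <- mean(rs, na.rm = TRUE)
    theta <- as.numeric(scale(rs))
    if (any(!is.finite(theta))) theta <- stats::rnorm(n) * 0
  } else {
    a <- numeric(0); g <- matrix(0, 0L, 0L)
    theta <- numeric(n)
  }
  if (!is.null(fix_theta)) theta <- as.numeric(fix_theta)
  b <- numeric(P)
  u <- numeric(J)
  sigma2 <- 0.5
  tau2 <- if (!is.null(config$tau2_fixed)) config$tau2_fixed else 0.5

  A <- config$prior_a_var; mu_a <- config$prior_a_mean
  B <- config$prior_beta_var
  a0 <- config$prior_var_shape; b0 <- config$prior_var_rate
  XtX <- crossprod(D)

  step_g <- rep(0.1, K)
  step_a <- rep(0.1, K)
  step_t <- 0.5
  step_u <- 0.3
  acc_g <- rej_g <- rep(0L, K)
  acc_a <- rej_a <- rep(0L, K)
  acc_t <- rej_t <- 0L
  acc_u <- rej_u <- 0L
  adapt_block <- 50L

  n_store <- (config$n_iter - config$burn_in) %/% config$thin
  if (n_store < 1L) stop("no draws would be stored", call. = FALSE)
  S_a <- matrix(NA_real_, n_store, K)
  S_kappa <- matrix(NA_real_, n_store, K * max(C - 1L, 0L))
  S_b <- matrix(NA_real_, n_store, P, dimnames = list(NULL, colnames(D)))
  S_tau2 <- numeric(n_store); S_sigma2 <- numeric(n_store)
  S_dev <- rep(NA_real_, n_store)
  S_theta <- if (config$store_theta) matrix(NA_real_, n_store, n) else NULL
  theta_sum <- numeric(n); theta_sq <- numeric(n)
  u_sum <- numeric(J)
  id_mean <- id_var <- id_drift <- rep(NA_real_, n_store)

  item_ids <- if (K > 0L && !is.null(rm)) rm$bank$item_id else character(0)
  if (K > 0L) {
    colnames(S_a) <- item_ids
    colnames(S_kappa) <- paste0(rep(item_ids, each = C - 1L), ".thr",
                                rep(seq_len(C - 1L), K))
  }

  Z <- if (link == "probit" && K > 0L) matrix(NA_real_, n, K) else NULL
  meas_num <- numeric(n); meas_prec <- numeric(n)
  s_idx <- 0L

  for (it in seq_len(config$n_iter)) {
    adapting <- it <= config$burn_in
    meas_num[] <- 0; meas_prec[] <- 0

    if (K > 0L && link == "probit") {
      for (k in seq_len(K)) {
        obs <- obs_list[[k]]; y <- y_list[[k]]
        at <- a[k] * theta[obs]
        # cutpoint Metropolis step with the augmented data collapsed out
        gk <- g[k, ]
        prop <- gk + stats::rnorm(C - 1L, 0, step_g[k])
        if (C == 2L || all(diff(prop) > 0)) {
          llc <- item_loglik_probit(y, gk, at)
          llp <- item_loglik_probit(y, prop, at)
          if (log(stats::runif(1)) < llp - llc) {
            g[k, ] <- gk <- prop
            acc_g[k] <- acc_g[k] + 1L
          } else rej_g[k] <- rej_g[k] + 1L
        } else rej_g[k] <- rej_g[k] + 1L
        # truncated-normal augmentation
        gg <- c(-Inf, gk, Inf)
        z <- truncnorm::rtruncnorm(length(obs), a = gg[y], b = gg[y + 1L],
                                   mean = at, sd = 1)
        Z[obs, k] <- z
        # conjugate discrimination
        th <- theta[obs]
        prec_a <- sum(th^2) + 1 / A
        mean_a <- (sum(th * z) + mu_a / A) / prec_a
        a[k] <- truncnorm::rtruncnorm(1, a = 0, b = Inf, mean = mean_a,
                                      sd = sqrt(1 / prec_a))
        meas_num[obs] <- meas_num[obs] + a[k] * z
        meas_prec[obs] <- meas_prec[obs] + a[k]^2
      }
    } else if (K > 0L) {  # logit: Metropolis on thresholds and discriminations
      for (k in seq_len(K)) {
        obs <- obs_list[[k]]; y <- y_list[[k]]
        th <- theta[obs]
        kk <- g[k, ]
        prop <- kk + stats::rnorm(C - 1L, 0, step_g[k])
        if (C == 2L || all(diff(prop) > 0)) {
          llc <- item_loglik_logit(y, kk, a[k], th)
          llp <- item_loglik_logit(y, prop, a[k], th)
          if (log(stats::runif(1)) < llp - llc) {
            g[k, ] <- kk <- prop
            acc_g[k] <- acc_g[k] + 1L
          } else rej_g[k] <- rej_g[k] + 1L
        } else rej_g[k] <- rej_g[k] + 1L
        ap <- a[k] * exp(stats::rnorm(1, 0, step_a[k]))
        llc <- item_loglik_logit(y, kk, a[k], th) +
          stats::dnorm(a[k], mu_a, sqrt(A), log = TRUE) + log(a[k])
        llp <- item_loglik_logit(y, kk, ap, th) +
          stats::dnorm(ap, mu_a, sqrt(A), log = TRUE) + log(ap)
        if (log(stats::runif(1)) < llp - llc) {
          a[k] <- ap
          acc_a[k] <- acc_a[k] + 1L
        } else rej_a[k] <- rej_a[k] + 1L
      }
    }

    # ---- abilities ----
    mu_struct <- drop(D %*% b) + u[j_of]
    if (is.null(fix_theta)) {
      if (link == "probit" || K == 0L) {
        prec <- 1 / sigma2 + meas_prec
        mean_t <- (mu_struct / sigma2 + meas_num) / prec
        theta <- stats::rnorm(n, mean_t, sqrt(1 / prec))
      } else {
        prop_t <- theta + stats::rnorm(n, 0, step_t)
        ll_diff <- person_loglik_logit(Y, a, g, prop_t) -
          person_loglik_logit(Y, a, g, theta) +
          stats::dnorm(prop_t, mu_struct, sqrt(sigma2), log = TRUE) -
          stats::dnorm(theta, mu_struct, sqrt(sigma2), log = TRUE)
        take <- log(stats::runif(n)) < ll_diff
        theta[take] <- prop_t[take]
        acc_t <- acc_t + sum(take); rej_t <- rej_t + sum(!take)
      }
    }

    # ---- structural parameters ----
    V <- chol2inv(chol(XtX / sigma2 + diag(1 / B, P)))
    mb <- V %*% crossprod(D, theta - u[j_of]) / sigma2
    b <- drop(mb + t(chol(V)) %*% stats::rnorm(P))
    r <- theta - drop(D %*% b)
    if (is.null(config$tau2_fixed) || config$tau2_fixed > 0) {
      Sj <- rowsum(r, j_of, reorder = FALSE)[, 1]
      if (is.null(config$tau2_fixed)) {
        # collapsed update: Metropolis on log tau2 against the marginal
        # likelihood with u integrated out -- the elementwise u/tau2 scan
        # alone crawls along a ridge when most clusters are singletons
        log_prior_tau2 <- if (config$prior_tau == "half_cauchy") {
          # half-Cauchy(0, A) on the SD, expressed in the variance
          function(t2) -log1p(t2 / config$prior_tau_scale^2) - 0.5 * log(t2)
        } else {
          function(t2) (-a0 - 1) * log(t2) - b0 / t2
        }
        marg_ll <- function(t2) {
          -0.5 * sum(log1p(nj * t2 / sigma2)) +
            0.5 * sum(t2 * Sj^2 / (sigma2 * (sigma2 + nj * t2))) +
            log_prior_tau2(t2) + log(t2)  # + log-scale proposal Jacobian
        }
        for (rep_mh in 1:2) {
          t2p <- tau2 * exp(stats::rnorm(1, 0, step_u))
          if (log(stats::runif(1)) < marg_ll(t2p) - marg_ll(tau2)) {
            tau2 <- t2p
            acc_u <- acc_u + 1L
          } else rej_u <- rej_u + 1L
        }
      }
      prec_u <- nj / sigma2 + 1 / tau2
      u <- stats::rnorm(J, (Sj / sigma2) / prec_u, sqrt(1 / prec_u))
    } else {
      u[] <- 0
    }
    e <- r - u[j_of]
    sigma2 <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(e^2) / 2)

    if (!all(is.finite(theta)) || !is.finite(sigma2) || !all(is.finite(b))) {
      stop("non-finite sampler state at iteration ", it, call. = FALSE)
    }

    # ---- identification rescaling ----
    store_now <- it > config$burn_in &&
      (it - config$burn_in) %% config$thin == 0L
    ll_before <- NA_real_
    if (store_now && config$check_identify && K > 0L) {
      kap <- if (link == "probit") g / a else g
      ll_before <- grm_loglik_cells(Y, a, kap, theta, link)
    }
    if (is.null(fix_theta)) {
      m <- mean(theta)
      s <- sqrt(mean((theta - m)^2))
      if (s <= 0) stop("degenerate ability scale at iteration ", it, call. = FALSE)
      theta <- (theta - m) / s
      if (K > 0L) {
        if (link == "probit") {
          g <- g - a * m           # rows scale by a[k] via recycling
          if (!is.null(Z)) Z <- sweep(Z, 2L, a * m, "-")
          a <- a * s
        } else {
          g <- (g - m) / s
          a <- a * s
        }
      }
      b[1] <- (b[1] - m) / s
      if (P > 1L) b[-1] <- b[-1] / s
      u <- u / s
      sigma2 <- sigma2 / s^2
      tau2 <- tau2 / s^2
    }

    # ---- adaptation (burn-in only) ----
    if (adapting && it %% adapt_block == 0L) {
      if (acc_u + rej_u > 0L) {
        rate_u <- acc_u / (acc_u + rej_u)
        step_u <- min(max(step_u * exp(rate_u - 0.4), 1e-3), 2)
        acc_u <- rej_u <- 0L
      }
      if (K > 0L) {
        rate_g <- acc_g / pmax(acc_g + rej_g, 1L)
        step_g <- pmin(pmax(step_g * exp(rate_g - 0.35), 1e-4), 3)
        acc_g[] <- rej_g[] <- 0L
        if (link == "logit") {
          rate_a <- acc_a / pmax(acc_a + rej_a, 1L)
          step_a <- pmin(pmax(step_a * exp(rate_a - 0.35), 1e-4), 3)
          acc_a[] <- rej_a[] <- 0L
          rate_t <- acc_t / max(acc_t + rej_t, 1L)
          step_t <- min(max(step_t * exp(rate_t - 0.35), 1e-3), 3)
          acc_t <- rej_t <- 0L
        }
      }
    }

    # ---- storage ----
    if (store_now) {
      s_idx <- s_idx + 1L
      if (K > 0L) {
        kap <- if (link == "probit") g / a else g
        S_a[s_idx, ] <- a
        S_kappa[s_idx, ] <- as.numeric(t(kap))
        dev_ll <- grm_loglik_cells(Y, a, kap, theta, link)
        S_dev[s_idx] <- -2 * dev_ll
        if (config$check_identify) {
          id_drift[s_idx] <- abs(dev_ll - ll_before)
        }
      }
      S_b[s_idx, ] <- b
      S_tau2[s_idx] <- tau2
      S_sigma2[s_idx] <- sigma2
      theta_sum <- theta_sum + theta
      theta_sq <- theta_sq + theta^2
      u_sum <- u_sum + u
      if (config$store_theta) S_theta[s_idx, ] <- theta
      if (config$check_identify) {
        id_mean[s_idx] <- mean(theta)
        id_var[s_idx] <- mean((theta - mean(theta))^2)
      }
    }
  }

  theta_mean <- theta_sum / n_store
  theta_var <- pmax(theta_sq / n_store - theta_mean^2, 0)
  names(theta_mean) <- names(theta_var) <- person_ids

  fit <- structure(list(
    draws = list(a = S_a, kappa = S_kappa, beta = S_b,
                 tau2 = S_tau2, sigma2 = S_sigma2,
                 deviance = S_dev, theta = S_theta),
    theta_mean = theta_mean, theta_var = theta_var,
    u_mean = stats::setNames(u_sum / n_store, dw_ids),
    n_store = n_store,
    accept = list(
      threshold = if (K > 0L) (acc_g / pmax(acc_g + rej_g, 1L)) else NULL,
      scale_u = acc_u / max(acc_u + rej_u, 1L)),
    identify = if (config$check_identify) list(
      max_abs_mean = max(abs(id_mean), na.rm = TRUE),
      max_abs_var_dev = max(abs(id_var - 1), na.rm = TRUE),
      max_loglik_drift = if (K > 0L) suppressWarnings(
        max(id_drift, na.rm = TRUE)) else NA_real_) else NULL,
    dims = list(n = n, K = K, C = C, J = J, P = P),
    coef_block = coef_block,
    fixed_covariates = fixed_covariates,
    person_ids = person_ids, item_ids = item_ids,
    link = link, config = config
  ), class = "mlirt_fit")

  if (K > 0L) {
    fit$dic <- dic_from_fit(fit, Y)
  }
  fit
}

#' @export
print.mlirt_fit <- function(x, ...) {
  cat(sprintf("<mlirt_fit> %s link: %d persons, %d items, %d dwellings; %d stored draws\n",
              x$link, x$dims$n, x$dims$K, x$dims$J, x$n_store))
  if (!is.null(x$dic)) {
    cat(sprintf("  DIC %.1f (pD %.1f, mean deviance %.1f)\n",
                x$dic$dic, x$dic$pD, x$dic$mean_deviance))
  }
  invisible(x)
}

posterior_item_params <- function(fit) {
  K <- fit$dims$K; C <- fit$dims$C
  a_hat <- colMeans(fit$draws$a)
  kap_hat <- matrix(colMeans(fit$draws$kappa), K, C - 1L, byrow = TRUE)
  item_params(a_hat, kap_hat, fit$item_ids)
}

dic_from_fit <- function(fit, Y) {
  ip <- posterior_item_params(fit)
  dev_at_means <- -2 * grm_loglik_cells(Y, ip$a, ip$kappa,
                                        fit$theta_mean, fit$link)
  dic_from_deviance(fit$draws$deviance, dev_at_means)
}

#' Deviance information criterion from a deviance trace
#'
#' `pD = mean(D) - D(posterior means)`; `DIC = mean(D) + pD`. The deviance is
#' the conditional measurement-model deviance given the abilities. A negative
#' `pD` is returned with a warning (a known pathology, not an error).
#'
#' @param deviance_trace numeric vector of stored deviances.
#' @param deviance_at_means deviance evaluated at the posterior means.
#' @return List with `dic`, `pD`, `mean_deviance`, `deviance_at_means`.
#' @export
dic_from_deviance <- function(deviance_trace, deviance_at_means) {
  dbar <- mean(deviance_trace)
  pD <- dbar - deviance_at_means
  if (is.finite(pD) && pD < 0) {
    warning("negative effective number of parameters (pD = ",
            signif(pD, 4), ")", call. = FALSE)
  }
  list(dic = dbar + pD, pD = pD, mean_deviance = dbar,
       deviance_at_means = deviance_at_means)
}

#' Deviance information criterion of a fitted model
#'
#' Recomputes the DIC from the stored deviance trace and the deviance at the
#' posterior means; with `rm` supplied the latter is re-evaluated from the
#' data, otherwise the value cached at fit time is used.
#'
#' @param fit an `mlirt_fit`.
#' @param rm optionally, the [response_matrix()] the model was fitted to.
#' @return As [dic_from_deviance()].
#' @export
compute_dic <- function(fit, rm = NULL) {
  if (is.null(rm)) {
    if (is.null(fit$dic)) stop("fit has no measurement model", call. = FALSE)
    return(fit$dic)
  }
  dic_from_fit(fit, rm$values)
}
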