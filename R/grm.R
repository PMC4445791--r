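#' Item parameters of a graded response model
#'
#' Each item has a positive discrimination `a` and `C - 1` strictly increasing
#' thresholds ("response option difficulties") on the latent scale. The
#' threshold is the latent location where responding at-or-above a category
#' has probability one half.
#'
#' @param a numeric vector of discriminations, one per item, all > 0.
#' @param kappa numeric matrix (items x C-1) of thresholds, each row strictly
#'   increasing.
#' @param item_id optional item identifiers.
#' @return Object of class `item_params`.
#' @export
item_params <- function(a, kappa, item_id = NULL) {
  kappa <- as.matrix(kappa)
  if (length(a) != nrow(kappa)) stop("a and kappa disagree on item count", call. = FALSE)
  if (any(a <= 0)) stop("discriminations must be positive", call. = FALSE)
  if (ncol(kappa) > 1 && any(t(apply(kappa, 1L, diff)) <= 0)) {
    stop("thresholds must be strictly increasing within each item", call. = FALSE)
  }
  if (is.null(item_id)) item_id <- paste0("item", seq_along(a))
  structure(list(a = as.numeric(a), kappa = kappa,
                 item_id = as.character(item_id)),
            class = "item_params")
}

#' @export
print.item_params <- function(x, ...) {
  cat(sprintf("<item_params> %d items, %d thresholds each\n",
              length(x$a), ncol(x$kappa)))
  invisible(x)
}

link_cdf <- function(link) {
  switch(match.arg(link, c("probit", "logit")),
         probit = stats::pnorm,
         logit = stats::plogis)
}

#' Cumulative at-or-above response probability
#'
#' `P(Y >= c | theta) = F(a * (theta - kappa_c))` with `F` the probit or logit
#' response function. Strictly increasing in `theta`; equals 0.5 at
#' `theta = kappa_c`.
#'
#' @param a item discrimination (> 0).
#' @param kappa_c a single threshold.
#' @param theta latent trait value(s).
#' @param link `"probit"` or `"logit"`.
#' @return Probabilities, vectorized over `theta`.
#' @export
grm_cumulative <- function(a, kappa_c, theta, link = "probit") {
  if (any(a <= 0)) stop("discrimination must be positive", call. = FALSE)
  link_cdf(link)(a * (theta - kappa_c))
}

#' Category response probabilities
#'
#' Adjacent differences of the cumulative at-or-above probabilities:
#' `p_c = P(Y >= c) - P(Y >= c + 1)`, with `P(Y >= 0) = 1` and
#' `P(Y >= C) = 0`. Rows sum to one.
#'
#' @param a discrimination of one item.
#' @param kappa increasing threshold vector of length C-1.
#' @param theta latent trait value(s).
#' @inheritParams grm_cumulative
#' @return Matrix `length(theta) x C` of category probabilities.
#' @export
grm_probs <- function(a, kappa, theta, link = "probit") {
  if (a <= 0) stop("discrimination must be positive", call. = FALSE)
  kappa <- as.numeric(kappa)
  if (length(kappa) > 1 && any(diff(kappa) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  F <- link_cdf(link)
  cum <- cbind(1, F(outer(theta, kappa, function(t, k) a * (t - k))), 0)
  p <- cum[, -ncol(cum), drop = FALSE] - cum[, -1, drop = FALSE]
  pmax(p, 0)
}

# Log-likelihood matrix workhorse shared by the user-facing loglik and the
# sampler's deviance trace. Probabilities floored at 1e-300 before log so a
# single impossible cell degrades to a very negative, finite contribution.
grm_loglik_cells <- function(values, a, kappa, theta, link) {
  F <- link_cdf(link)
  n <- nrow(values); K <- ncol(values)
  ll <- 0
  warned <- FALSE
  for (k in seq_len(K)) {
    y <- values[, k]
    obs <- which(!is.na(y))
    if (!length(obs)) next
    kk <- c(-Inf, kappa[k, ], Inf)
    up <- F(a[k] * (theta[obs] - kk[y[obs] + 1L]))
    lo <- F(a[k] * (theta[obs] - kk[y[obs] + 2L]))
    p <- up - lo
    if (any(p <= 0) && !warned) {
      warning("zero-probability response cell; log-likelihood floored",
              call. = FALSE)
      warned <- TRUE
    }
    ll <- ll + sum(log(pmax(p, 1e-300)))
  }
  ll
}

#' Observed-data log-likelihood of a graded response model
#'
#' Sums the log category probabilities over all non-missing cells; missing
#' responses contribute nothing, so persons may differ in the questions they
#' completed.
#'
#' @param rm a [response_matrix()] (or plain integer matrix of 0-based codes).
#' @param items an [item_params()] aligned with the columns of `rm`.
#' @param theta latent trait vector, one value per person.
#' @inheritParams grm_cumulative
#' @return Scalar log-likelihood.
#' @export
grm_loglik <- function(rm, items, theta, link = "probit") {
  values <- if (inherits(rm, "response_matrix")) rm$values else as.matrix(rm)
  if (length(items$a) != ncol(values)) {
    stop("item parameters do not match the response columns", call. = FALSE)
  }
  if (length(theta) != nrow(values)) {
    stop("theta must have one entry per person", call. = FALSE)
  }
  link <- match.arg(link, c("probit", "logit"))
  grm_loglik_cells(values, items$a, items$kappa, theta, link)
}
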