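#' Highest posterior density interval (Chen-Shao)
#'
#' The shortest interval containing `ceiling(prob * n)` of the sorted draws:
#' all windows of that length are scanned and the narrowest returned.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param prob interval mass (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws for an HPD interval", call. = FALSE)
  if (prob <= 0 || prob > 1) stop("prob must lie in (0, 1]", call. = FALSE)
  x <- sort(draws)
  keep <- min(ceiling(prob * n), n)
  if (keep == n) return(c(lower = x[1], upper = x[n]))
  lo <- seq_len(n - keep + 1L)
  width <- x[lo + keep - 1L] - x[lo]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + keep - 1L])
}

#' Geweke convergence diagnostic
#'
#' Standard Geweke z-scores comparing the mean of the first `frac1` of each
#' chain with the last `frac2`, with spectral-density variance estimates
#' (delegated to `coda`). Parameters with `|z| > 2` are flagged; constant
#' chains are reported as degenerate.
#'
#' @param chains numeric vector, matrix (iterations x parameters), or an
#'   `mlirt_fit` (structural coefficients, variances and discriminations are
#'   examined).
#' @param frac1,frac2 window fractions.
#' @return Data frame with `parameter`, `z`, `flagged`, `degenerate`.
#' @export
geweke_diagnostic <- function(chains, frac1 = 0.1, frac2 = 0.5) {
  if (inherits(chains, "mlirt_fit")) {
    chains <- cbind(chains$draws$beta,
                    tau2 = chains$draws$tau2, sigma2 = chains$draws$sigma2,
                    if (chains$dims$K > 0L) chains$draws$a)
  }
  chains <- as.matrix(chains)
  if (is.null(colnames(chains))) {
    colnames(chains) <- paste0("par", seq_len(ncol(chains)))
  }
  if (nrow(chains) < 200L) stop("chain too short (< 200)", call. = FALSE)
  z <- vapply(seq_len(ncol(chains)), function(j) {
    x <- chains[, j]
    if (stats::var(x) == 0) return(NA_real_)
    out <- tryCatch(coda::geweke.diag(coda::mcmc(x),
                                      frac1 = frac1, frac2 = frac2)$z,
                    error = function(e) NA_real_)
    as.numeric(out)
  }, numeric(1))
  degenerate <- apply(chains, 2L, function(x) stats::var(x) == 0) | !is.finite(z)
  data.frame(parameter = colnames(chains), z = z,
             flagged = !is.na(z) & is.finite(z) & abs(z) > 2,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Posterior summary table of a fitted MLIRT model
#'
#' Per parameter: posterior mean, posterior SD and the 95% highest posterior
#' density interval, laid out by block — item discriminations and thresholds
#' first, then the structural fixed effects in declaration order
#' (intercept, person-level, dwelling-level), then the variance components.
#'
#' @param object an `mlirt_fit`.
#' @param prob HPD mass.
#' @param ... unused.
#' @return Data frame with columns `parameter`, `block`, `mean`, `sd`,
#'   `hpd_lower`, `hpd_upper`.
#' @export
summary.mlirt_fit <- function(object, prob = 0.95, ...) {
  summarize_block <- function(draws, names, block) {
    if (is.null(draws) || (is.matrix(draws) && ncol(draws) == 0L)) return(NULL)
    draws <- as.matrix(draws)
    hpd <- t(apply(draws, 2L, hpd_interval, prob = prob))
    data.frame(parameter = names, block = block,
               mean = colMeans(draws),
               sd = apply(draws, 2L, stats::sd),
               hpd_lower = hpd[, 1], hpd_upper = hpd[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- list()
  if (object$dims$K > 0L) {
    out$a <- summarize_block(object$draws$a,
                             paste0("discr.", colnames(object$draws$a)), "item")
    out$kappa <- summarize_block(object$draws$kappa,
                                 colnames(object$draws$kappa), "item")
  }
  bl <- object$coef_block
  out$beta <- summarize_block(object$draws$beta, colnames(object$draws$beta),
                              bl)
  out$var <- summarize_block(cbind(tau2 = object$draws$tau2,
                                   sigma2 = object$draws$sigma2),
                             c("tau2", "sigma2"), "variance")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mlirt_summary", "data.frame")
  res
}

#' @export
`[.mlirt_summary` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.mlirt_summary <- function(x, digits = 3, ...) {
  need <- c("parameter", "block", "mean", "sd", "hpd_lower", "hpd_upper")
  if (!all(need %in% names(x))) {
    return(print.data.frame(x, ...))
  }
  y <- x
  y$mean <- round(y$mean, digits)
  y$sd <- round(y$sd, digits)
  y$HPD <- sprintf("[%.*f, %.*f]", digits, x$hpd_lower, digits, x$hpd_upper)
  print.data.frame(y[, c("parameter", "block", "mean", "sd", "HPD")],
                   row.names = FALSE)
  invisible(x)
}
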