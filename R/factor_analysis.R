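#' Minimum-residual (minres) factor extraction
#'
#' Fits the common factor model `R ~ L L' + diag(psi)` by minimizing the sum
#' of squared off-diagonal residuals over the uniquenesses, with the loadings
#' solved in closed form from the eigendecomposition of the reduced
#' correlation matrix (ordinary unweighted least squares / minres).
#'
#' @param R correlation matrix (e.g. polychoric). Smoothed to positive
#'   semi-definite first if needed.
#' @param n_factors number of factors to extract.
#' @return List with `loadings` (items x factors), `uniquenesses`,
#'   `criterion`, `converged`.
#' @export
fa_minres <- function(R, n_factors = 1L) {
  R <- smooth_psd(as.matrix(R))
  p <- ncol(R)
  if (n_factors >= p) stop("too many factors for ", p, " items", call. = FALSE)
  off <- !diag(p)
  loadings_for <- function(psi) {
    Rs <- R
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(n_factors)], 0)
    e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(ev), n_factors)
  }
  objective <- function(psi) {
    L <- loadings_for(psi)
    res <- R - tcrossprod(L)
    sum(res[off]^2) / 2
  }
  start <- pmax(1 - 0.9 * smc(R), 0.05)
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = 0.005, upper = 1,
                      control = list(maxit = 500))
  L <- loadings_for(opt$par)
  # orient each factor so its loading sum is positive
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2L, sgn, "*")
  rownames(L) <- rownames(R)
  list(loadings = L, uniquenesses = opt$par, criterion = opt$value,
       converged = opt$convergence == 0)
}

# squared multiple correlations used as communality starting values
smc <- function(R) {
  Ri <- tryCatch(solve(R), error = function(e) solve(R + diag(0.01, ncol(R))))
  pmin(pmax(1 - 1 / diag(Ri), 0), 1)
}

# eigenvalue smoothing to the nearest positive semi-definite correlation
smooth_psd <- function(R, eps = 1e-6) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > eps) return(R)
  ev <- pmax(e$values, eps)
  S <- e$vectors %*% diag(ev) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(S)))
  out <- D %*% S %*% D
  dimnames(out) <- dimnames(R)
  out
}

# quartimin-type criterion of the group block (all columns but the first):
# the analytic bifactor criterion of Jennrich & Bentler. Returns the value
# and its gradient with respect to the loadings.
bifactor_criterion <- function(L) {
  G <- L[, -1, drop = FALSE]^2
  g <- ncol(G)
  if (g < 2L) return(list(f = 0, grad = matrix(0, nrow(L), ncol(L))))
  N <- matrix(1, g, g) - diag(g)
  GN <- G %*% N
  f <- sum(G * GN) / 4
  grad <- matrix(0, nrow(L), ncol(L))
  grad[, -1] <- L[, -1, drop = FALSE] * GN
  list(f = f, grad = grad)
}

#' Orthogonal analytic bifactor rotation (gradient projection)
#'
#' Rotates an unrotated loading matrix toward a bifactor pattern — one
#' general factor (first column) plus group factors — by minimizing the
#' bi-quartimin criterion with the Jennrich-style gradient-projection
#' algorithm on the orthogonal group.
#'
#' @param L unrotated loadings (items x (1 + G)).
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   projected gradient norm.
#' @param n_starts number of orthogonal starting rotations (identity plus
#'   deterministic random restarts); the solution with the lowest criterion
#'   value is kept. The criterion has local minima in which the general
#'   factor absorbs a group factor, so a single start is unreliable.
#' @return List with `loadings`, `rotation` matrix, `criterion`, `converged`,
#'   `iterations`.
#' @export
rotate_bifactor <- function(L, max_iter = 1000L, tol = 1e-5, n_starts = 12L) {
  m <- ncol(L)
  starts <- list(diag(m))
  if (n_starts > 1L) {
    # deterministic restarts that leave the caller's RNG stream untouched
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()), add = TRUE)
    set.seed(20240815L)
    for (r in seq_len(n_starts - 1L)) {
      starts[[r + 1L]] <- qr.Q(qr(matrix(stats::rnorm(m * m), m)))
    }
  }
  best <- NULL
  for (Tstart in starts) {
    cand <- tryCatch(rotate_bifactor_once(L, Tstart, max_iter, tol),
                     error = function(e) NULL)
    if (!is.null(cand) && (is.null(best) || cand$criterion < best$criterion)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("bifactor rotation did not converge from any start", call. = FALSE)
  }
  best
}

rotate_bifactor_once <- function(L, Tm, max_iter, tol) {
  m <- ncol(L)
  al <- 1
  Lr <- L %*% Tm
  crit <- bifactor_criterion(Lr)
  f <- crit$f
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  f_hist <- f
  for (it in seq_len(max_iter)) {
    G <- crossprod(L, crit$grad)        # d f / d T
    M <- crossprod(Tm, G)
    S <- (M + t(M)) / 2
    Gp <- G - Tm %*% S                  # projection on the tangent space
    s <- sqrt(sum(Gp^2))
    trace[it] <- s
    if (s < tol) { converged <- TRUE; break }
    # stationary for practical purposes: criterion no longer decreases
    if (it > 20L && f_hist[it - 20L] - f < 1e-8) {
      converged <- TRUE
      break
    }
    al <- 2 * al
    for (half in 1:20) {
      X <- Tm - al * Gp
      sv <- svd(X)
      Tt <- sv$u %*% t(sv$v)            # project back onto orthogonal group
      Lt <- L %*% Tt
      ct <- bifactor_criterion(Lt)
      if (ct$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt; Lr <- Lt; crit <- ct; f <- ct$f
    f_hist[it + 1L] <- f
  }
  if (!converged) {
    # a nearly flat criterion (e.g. group loadings all close to zero) leaves
    # the gradient small but above tol indefinitely; that is an optimum for
    # practical purposes, not a rotation failure
    if (min(utils::tail(trace, 10)) < 1e-3) {
      converged <- TRUE
    } else {
      stop("bifactor rotation did not converge; gradient norms: ",
           paste(signif(utils::tail(trace, 5), 3), collapse = ", "),
           call. = FALSE)
    }
  }
  # keep the general factor positively oriented and first
  sgn <- ifelse(colSums(Lr) < 0, -1, 1)
  Lr <- sweep(Lr, 2L, sgn, "*")
  list(loadings = Lr, rotation = Tm, criterion = f, converged = converged,
       iterations = it)
}
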