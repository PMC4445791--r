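#' Bifactor unidimensionality check
#'
#' Extracts `1 + G` factors from a polychoric correlation matrix (minres) and
#' applies the analytic orthogonal bifactor rotation. Essential
#' unidimensionality is supported when all items load highly on the general
#' factor; a domain is flagged when its items load higher (in mean absolute
#' loading) on their own group factor than on the general factor.
#'
#' Group factors are matched to item domains by the domain with the largest
#' mean absolute loading on each group column.
#'
#' @param R polychoric correlation matrix (items x items).
#' @param groups character vector assigning each item to a domain.
#' @param general_cutoff loading regarded as "high" on the general factor
#'   (reported, not used for flagging).
#' @return List of class `bifactor_check`: `general_loadings`,
#'   `group_loadings` (items x G, domain-labelled), `domain_summary`,
#'   `flagged_domains`, `unidimensional`.
#' @export
bifactor_check <- function(R, groups, general_cutoff = 0.5) {
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(R))
  doms <- unique(groups)
  G <- length(doms)
  fit <- fa_minres(R, n_factors = 1L + G)
  rot <- rotate_bifactor(fit$loadings)
  L <- rot$loadings
  # first column is oriented as the general factor by construction; map each
  # remaining column to the domain loading most heavily on it
  group_cols <- L[, -1, drop = FALSE]
  col_dom <- vapply(seq_len(G), function(g) {
    means <- vapply(doms, function(d)
      mean(abs(group_cols[groups == d, g])), numeric(1))
    doms[which.max(means)]
  }, character(1))
  colnames(group_cols) <- make.unique(col_dom)
  own <- vapply(seq_along(groups), function(i) {
    cand <- which(col_dom == groups[i])
    if (!length(cand)) return(0)
    max(abs(group_cols[i, cand]))
  }, numeric(1))
  general <- L[, 1]
  summary_df <- do.call(rbind, lapply(doms, function(d) {
    idx <- groups == d
    data.frame(domain = d,
               mean_general = mean(abs(general[idx])),
               mean_group = mean(own[idx]),
               stringsAsFactors = FALSE)
  }))
  summary_df$flagged <- summary_df$mean_group > summary_df$mean_general
  structure(list(general_loadings = general,
                 group_loadings = group_cols,
                 domain_summary = summary_df,
                 flagged_domains = summary_df$domain[summary_df$flagged],
                 unidimensional = !any(summary_df$flagged),
                 general_cutoff = general_cutoff,
                 rotation = rot),
            class = "bifactor_check")
}

#' Local dependence via single-factor residual correlations
#'
#' Fits a one-factor model to the polychoric correlation matrix and flags
#' item pairs whose off-diagonal residual correlation `R - lambda lambda'`
#' exceeds the threshold in absolute value — the working criterion for a
#' violation of local independence.
#'
#' @param R polychoric correlation matrix, or a [response_matrix()] from
#'   which one is computed.
#' @param threshold absolute residual correlation above which a pair is
#'   flagged (default 0.25).
#' @return List of class `local_dependence`: `residuals` matrix, `flagged`
#'   data frame (`item_i`, `item_j`, `residual`), `loadings`.
#' @export
local_dependence <- function(R, threshold = 0.25) {
  if (inherits(R, "response_matrix")) R <- polychoric_matrix(R)
  R <- as.matrix(R)
  if (ncol(R) < 3L) stop("need at least three items", call. = FALSE)
  fit <- fa_minres(R, 1L)
  lambda <- fit$loadings[, 1]
  heywood <- abs(lambda) > 1
  if (any(heywood)) {
    warning("Heywood case: clipping ", sum(heywood), " loading(s) to |1|",
            call. = FALSE)
    lambda <- pmin(pmax(lambda, -1), 1)
  }
  res <- R - tcrossprod(lambda)
  diag(res) <- 0
  idx <- which(upper.tri(res) & abs(res) > threshold, arr.ind = TRUE)
  flagged <- data.frame(item_i = colnames(R)[idx[, 1]],
                        item_j = colnames(R)[idx[, 2]],
                        residual = res[idx],
                        stringsAsFactors = FALSE)
  flagged <- flagged[order(-abs(flagged$residual)), , drop = FALSE]
  rownames(flagged) <- NULL
  structure(list(residuals = res, flagged = flagged, loadings = lambda,
                 threshold = threshold),
            class = "local_dependence")
}

#' Rest-score monotonicity check
#'
#' For each item, persons are grouped by their rest-score — the mean of their
#' other non-missing item scores — into decile bins merged until each holds
#' at least `min_bin_size` persons. The item passes when its binned mean
#' score is non-decreasing in the rest-score up to a small tolerance, an
#' automated analogue of inspecting rest-score curves.
#'
#' @param rm a [response_matrix()].
#' @param min_bin_size minimum persons per rest-score bin.
#' @param tolerance largest admissible systematic decrease between adjacent
#'   binned means. A decrease only fails the item when it exceeds
#'   `tolerance + 2 * SE` of the difference of the two bin means, so that
#'   ordinary sampling noise in small bins does not masquerade as a
#'   monotonicity violation (the graphical check this automates would not
#'   flag it either).
#' @return List of class `monotonicity_check`: `verdicts` (named character:
#'   pass / fail / indeterminate), `curves` (per item, data frame of bin
#'   mid-rest-score, mean item score, bin size).
#' @export
monotonicity_check <- function(rm, min_bin_size = 50L, tolerance = 0.03) {
  vals <- rm$values
  K <- ncol(vals)
  n <- nrow(vals)
  verdicts <- stats::setNames(rep("indeterminate", K), colnames(vals))
  curves <- vector("list", K)
  names(curves) <- colnames(vals)
  row_sum <- rowSums(vals, na.rm = TRUE)
  row_n <- rowSums(!is.na(vals))
  for (k in seq_len(K)) {
    y <- vals[, k]
    obs <- which(!is.na(y) & (row_n - 1L) > 0L)
    if (length(obs) < 2L * min_bin_size) next
    rest <- (row_sum[obs] - y[obs]) / (row_n[obs] - 1L)
    br <- unique(stats::quantile(rest, probs = seq(0, 1, 0.1), names = FALSE))
    bin <- if (length(br) > 2L) {
      cut(rest, breaks = br, include.lowest = TRUE, labels = FALSE)
    } else rep(1L, length(rest))
    # merge adjacent small bins left to right
    bin <- merge_small_bins(bin, min_bin_size)
    if (length(unique(bin)) < 2L) next
    means <- tapply(y[obs], bin, mean)
    vars <- tapply(y[obs], bin, stats::var)
    mids <- tapply(rest, bin, mean)
    sizes <- tapply(rest, bin, length)
    o <- order(mids)
    mu <- as.numeric(means[o]); vv <- as.numeric(vars[o])
    nn <- as.integer(sizes[o])
    curves[[k]] <- data.frame(rest_score = as.numeric(mids[o]),
                              mean_score = mu, n = nn)
    vv[is.na(vv)] <- 0
    se_diff <- sqrt(vv[-length(vv)] / nn[-length(nn)] + vv[-1] / nn[-1])
    drops <- diff(mu)
    verdicts[k] <- if (all(drops >= -(tolerance + 2 * se_diff)))
      "pass" else "fail"
  }
  structure(list(verdicts = verdicts, curves = curves,
                 min_bin_size = min_bin_size, tolerance = tolerance),
            class = "monotonicity_check")
}

merge_small_bins <- function(bin, min_size) {
  repeat {
    tab <- table(bin)
    if (length(tab) < 2L || min(tab) >= min_size) break
    small <- as.integer(names(tab)[which.min(tab)])
    lvls <- as.integer(names(tab))
    pos <- match(small, lvls)
    neighbour <- if (pos == 1L) lvls[2L] else lvls[pos - 1L]
    bin[bin == small] <- neighbour
  }
  bin
}

#' Select items surviving the assumption checks
#'
#' Items failing monotonicity are dropped outright. Within each connected
#' subset of locally dependent items, one item is retained — by default the
#' one with the highest provisional discrimination. Domains flagged by the
#' bifactor check produce a warning (with a recommendation to re-fit without
#' them as a sensitivity analysis) but no automatic removal.
#'
#' @param monotonicity a [monotonicity_check()] result (or NULL to skip).
#' @param dependence a [local_dependence()] result (or NULL to skip).
#' @param bifactor a [bifactor_check()] result (or NULL to skip).
#' @param discriminations named numeric vector of provisional item
#'   discriminations, used to pick the retained item within each dependent
#'   subset. Required when `dependence` has flagged pairs.
#' @param items character vector of all candidate item ids.
#' @return Character vector of retained item ids, with attributes
#'   `"dropped_monotonicity"` and `"dropped_dependence"`.
#' @export
select_items <- function(items, monotonicity = NULL, dependence = NULL,
                         bifactor = NULL, discriminations = NULL) {
  items <- as.character(items)
  drop_mono <- character(0)
  if (!is.null(monotonicity)) {
    drop_mono <- names(monotonicity$verdicts)[monotonicity$verdicts == "fail"]
  }
  keep <- setdiff(items, drop_mono)
  drop_dep <- character(0)
  if (!is.null(dependence) && nrow(dependence$flagged)) {
    pairs <- dependence$flagged[dependence$flagged$item_i %in% keep &
                                  dependence$flagged$item_j %in% keep, ]
    comps <- pair_components(pairs$item_i, pairs$item_j)
    for (comp in comps) {
      if (is.null(discriminations)) {
        stop("provisional discriminations are required to resolve locally ",
             "dependent subsets", call. = FALSE)
      }
      d <- discriminations[comp]
      retain <- comp[which.max(d)]
      drop_dep <- c(drop_dep, setdiff(comp, retain))
    }
    keep <- setdiff(keep, drop_dep)
  }
  if (!is.null(bifactor) && length(bifactor$flagged_domains)) {
    warning("domain(s) loading higher on their group factor than the general ",
            "factor: ", paste(bifactor$flagged_domains, collapse = ", "),
            "; consider a sensitivity re-fit without them", call. = FALSE)
  }
  structure(keep,
            dropped_monotonicity = drop_mono,
            dropped_dependence = drop_dep)
}

# connected components of the flagged-pair graph (union-find style)
pair_components <- function(a, b) {
  nodes <- unique(c(a, b))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(a)) {
    ra <- find(a[i]); rb <- find(b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  unname(split(nodes, roots))
}

#' Robustness of person scores to item-set changes
#'
#' Compares posterior-mean person scores from fits with and without flagged
#' items: Pearson correlation, mean and maximum absolute difference, and a
#' robustness verdict.
#'
#' @param scores_with,scores_without named numeric vectors over the same
#'   persons.
#' @param min_correlation,max_mad verdict cutoffs.
#' @return List of class `robustness_check`.
#' @export
robustness_check <- function(scores_with, scores_without,
                             min_correlation = 0.95, max_mad = 0.1) {
  if (!is.null(names(scores_with)) && !is.null(names(scores_without))) {
    if (!setequal(names(scores_with), names(scores_without))) {
      stop("score vectors cover different persons", call. = FALSE)
    }
    scores_without <- scores_without[names(scores_with)]
  } else if (length(scores_with) != length(scores_without)) {
    stop("score vectors cover different persons", call. = FALSE)
  }
  d <- scores_with - scores_without
  r <- if (stats::sd(scores_with) == 0 || stats::sd(scores_without) == 0) {
    if (all(d == 0)) 1 else 0
  } else stats::cor(scores_with, scores_without)
  mad_ <- mean(abs(d))
  structure(list(correlation = r,
                 mean_abs_diff = mad_,
                 max_abs_diff = max(abs(d)),
                 robust = r >= min_correlation && mad_ <= max_mad),
            class = "robustness_check")
}
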