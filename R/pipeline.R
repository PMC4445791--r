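#' Intraclass correlation of a two-level model
#'
#' Share of latent-trait variance attributable to dwellings:
#' `tau2 / (tau2 + sigma2)`.
#'
#' @param tau2 dwelling-level variance (>= 0).
#' @param sigma2 person-level residual variance.
#' @return Proportion in `[0, 1]`.
#' @export
icc <- function(tau2, sigma2) {
  if (tau2 < 0 || sigma2 < 0) stop("variances must be non-negative", call. = FALSE)
  if (tau2 + sigma2 == 0) stop("both variances are zero", call. = FALSE)
  tau2 / (tau2 + sigma2)
}

#' Proportional reduction in variance between empty and full models
#'
#' Person level: `(sigma2_0 - sigma2_1) / sigma2_0`; dwelling level:
#' `(tau2_0 - tau2_1) / tau2_0`, with the empty (intercept + random effect
#' only) model as baseline. Negative values are reported as-is with a
#' warning.
#'
#' @param empty_fit,full_fit `mlirt_fit` objects on the same data.
#' @return Named numeric vector `c(person, dwelling)`.
#' @export
variance_explained <- function(empty_fit, full_fit) {
  s0 <- mean(empty_fit$draws$sigma2); s1 <- mean(full_fit$draws$sigma2)
  t0 <- mean(empty_fit$draws$tau2); t1 <- mean(full_fit$draws$tau2)
  if (s0 <= 0 || t0 <= 0) stop("zero baseline variance", call. = FALSE)
  out <- c(person = (s0 - s1) / s0, dwelling = (t0 - t1) / t0)
  if (any(out < 0)) {
    warning("negative proportion of variance explained", call. = FALSE)
  }
  out
}

#' Step 1: biological-health scoring
#'
#' Fits the measurement-only MLIRT model to the biological items — no
#' person- or dwelling-level covariates, but dwelling random effects — and
#' returns each person's standardized posterior-mean ability (higher = worse
#' health).
#'
#' @param rm_bio filtered, collapsed biological [response_matrix()].
#' @param dwellings a [dwelling_index()].
#' @param config an [mcmc_config()].
#' @return List with `scores` (named, standardized to mean 0 / SD 1), `fit`,
#'   `summary`.
#' @export
step1_biological <- function(rm_bio, dwellings, config) {
  fit <- run_mcmc(rm_bio, dwellings, config = config)
  sc <- fit$theta_mean
  sc <- (sc - mean(sc)) / stats::sd(sc)
  list(scores = sc, fit = fit, summary = summary(fit))
}

#' Step 2: lived health on environmental factors, controlling for
#' biological health
#'
#' Fits the MLIRT model to the lived items with the step-1 biological score
#' entered as a known person-level predictor (error fixed to zero) next to
#' the demographic and environmental covariates, plus dwelling-level
#' covariates and random effects.
#'
#' @param rm_lived equated, collapsed lived [response_matrix()].
#' @param bio_scores named numeric vector of biological scores aligned to the
#'   persons of `rm_lived`.
#' @param person_covariates numeric matrix of reference-coded person-level
#'   covariates (may be `NULL`).
#' @param dwellings a [dwelling_index()].
#' @param dwelling_covariates numeric matrix rownamed by dwelling id (may be
#'   `NULL`).
#' @param config an [mcmc_config()].
#' @param include_biological set `FALSE` to omit the biological-health
#'   control column (for the model-comparison fit).
#' @return List with `fit`, `summary`.
#' @export
step2_lived <- function(rm_lived, bio_scores, person_covariates = NULL,
                        dwellings, dwelling_covariates = NULL, config,
                        include_biological = TRUE) {
  X <- person_covariates
  if (include_biological) {
    if (is.null(names(bio_scores)) ||
        !all(rm_lived$person_ids %in% names(bio_scores))) {
      stop("bio_scores must be named and cover all persons", call. = FALSE)
    }
    bio <- bio_scores[rm_lived$person_ids]
    X <- cbind(biological = bio, X)
    rownames(X) <- rm_lived$person_ids
  }
  fit <- run_mcmc(rm_lived, dwellings, person_covariates = X,
                  dwelling_covariates = dwelling_covariates, config = config,
                  fixed_covariates = if (include_biological) "biological")
  list(fit = fit, summary = summary(fit))
}

#' Empty (intercept + dwelling random effect) MLIRT model
#'
#' Baseline for the variance decomposition and the DIC comparison.
#'
#' @inheritParams step1_biological
#' @param rm a [response_matrix()] (normally the lived items).
#' @return List with `fit`, `summary`, `tau2`, `sigma2`, `dic`.
#' @export
fit_empty_model <- function(rm, dwellings, config) {
  fit <- run_mcmc(rm, dwellings, config = config)
  list(fit = fit, summary = summary(fit),
       tau2 = mean(fit$draws$tau2), sigma2 = mean(fit$draws$sigma2),
       dic = fit$dic)
}

#' Run the full two-step analysis pipeline
#'
#' Executes, on a survey bundle: category collapsing, respondent filtering,
#' lived/biological equating, the three IRT assumption checks with item
#' selection and a robustness re-fit, the step-1 biological scoring, the
#' step-2 structural model, the empty baseline model, and the variance /
#' model-fit summaries (ICC, variance explained, DIC comparison).
#'
#' @param bundle a [simulate_survey()] result or [read_bundle()] output.
#' @param mcmc an [mcmc_config()] used (with derived seeds) for all fits.
#' @param collapse_map category collapse mapping passed to
#'   [collapse_categories()]; `NULL` skips collapsing (synthetic bundles are
#'   generated on the collapsed scale already).
#' @param run_checks run the assumption diagnostics and item selection
#'   (default `TRUE`). When disabled, all items are retained and diagnostics
#'   are `NULL`.
#' @param dependence_threshold residual-correlation flag threshold.
#' @param min_bin_size,monotonicity_tolerance rest-score binning controls.
#' @param dic_no_biological additionally fit step 2 without the biological
#'   control to complete the DIC triple (default `TRUE`).
#' @param keep_fits retain the full `mlirt_fit` objects in the result
#'   (memory-hungry; default `FALSE`).
#' @return A list of class `pipeline_result`.
#' @export
run_pipeline <- function(bundle, mcmc,
                         collapse_map = NULL,
                         run_checks = TRUE,
                         dependence_threshold = 0.25,
                         min_bin_size = 50L,
                         monotonicity_tolerance = 0.03,
                         dic_no_biological = TRUE,
                         keep_fits = FALSE) {
  stage <- "prepare"
  result <- list(seed = mcmc$seed)
  out <- tryCatch({
    bio <- bundle$bio
    lived <- bundle$lived_observed
    if (!is.null(collapse_map)) {
      stage <- "collapse"
      bio <- collapse_categories(bio, collapse_map)
      lived <- collapse_categories(lived, collapse_map)
    }

    stage <- "filter_respondents"
    kept <- filter_respondents(bio)
    bio <- subset_persons(bio, kept$kept)
    lived <- subset_persons(lived, kept$kept)
    result$n_kept <- kept$n_kept
    result$n_total <- kept$n_total

    stage <- "equate"
    lived <- equate_lived_with_biological(
      bio, lived, bundle$aid_use, item_map = bundle$item_map)

    dwellings <- bundle$dwellings

    stage <- "descriptives"
    if (!is.null(bundle$covariates_person)) {
      cp <- bundle$covariates_person
      cp <- cp[match(kept$kept, cp$person_id), , drop = FALSE]
      catcols <- names(cp)[vapply(cp, function(x)
        is.character(x) || is.factor(x) || length(unique(x)) <= 6,
        logical(1))]
      catcols <- setdiff(catcols, "person_id")
      wt <- bundle$weights[match(kept$kept, bundle$dwellings$person_id)]
      if (length(catcols)) {
        result$descriptives <- weighted_descriptives(cp[catcols], wt)
      }
    }

    seed_for <- function(offset) {
      cfg <- mcmc
      cfg$seed <- (mcmc$seed + offset) %% .Machine$integer.max
      cfg
    }

    retained_bio <- bio$bank$item_id
    retained_lived <- lived$bank$item_id
    if (run_checks) {
      stage <- "assumption_checks"
      diag_out <- list()
      for (side in c("bio", "lived")) {
        rmx <- if (side == "bio") bio else lived
        R <- polychoric_matrix(rmx)
        used <- setdiff(rmx$bank$item_id, attr(R, "excluded"))
        bf <- bifactor_check(R, rmx$bank$domain[match(used, rmx$bank$item_id)])
        ld <- local_dependence(R, threshold = dependence_threshold)
        mono <- monotonicity_check(rmx, min_bin_size = min_bin_size,
                                   tolerance = monotonicity_tolerance)
        disc <- provisional_discriminations(rmx)
        keep <- select_items(used, monotonicity = mono, dependence = ld,
                             bifactor = bf, discriminations = disc)
        diag_out[[side]] <- list(bifactor = bf, dependence = ld,
                                 monotonicity = mono, retained = keep)
      }
      result$diagnostics <- diag_out
      retained_bio <- diag_out$bio$retained
      retained_lived <- diag_out$lived$retained
      bio_sel <- select_item_columns(bio, retained_bio)
      lived_sel <- select_item_columns(lived, retained_lived)
    } else {
      bio_sel <- bio
      lived_sel <- lived
    }
    result$retained_items <- list(biological = retained_bio,
                                  lived = retained_lived)

    stage <- "step1_biological"
    step1 <- step1_biological(bio_sel, dwellings, seed_for(101L))
    result$step1 <- list(summary = step1$summary, scores = step1$scores,
                         dic = step1$fit$dic)

    if (run_checks &&
        length(retained_bio) < length(bio$bank$item_id)) {
      stage <- "robustness"
      full_fit <- step1_biological(bio, dwellings, seed_for(102L))
      result$robustness <- robustness_check(full_fit$scores, step1$scores)
    }

    stage <- "step2_lived"
    pers_cov <- pipeline_person_design(bundle, kept$kept)
    dw_cov <- pipeline_dwelling_design(bundle)
    step2 <- step2_lived(lived_sel, step1$scores, pers_cov, dwellings,
                         dw_cov, seed_for(103L))
    result$step2 <- list(summary = step2$summary, dic = step2$fit$dic)

    stage <- "empty_model"
    empty <- fit_empty_model(lived_sel, dwellings, seed_for(104L))
    result$empty <- list(summary = empty$summary, dic = empty$dic,
                         tau2 = empty$tau2, sigma2 = empty$sigma2)

    stage <- "dic_no_biological"
    if (dic_no_biological) {
      nobio <- step2_lived(lived_sel, step1$scores, pers_cov, dwellings,
                           dw_cov, seed_for(105L), include_biological = FALSE)
      result$dic <- list(empty = empty$dic$dic, full = step2$fit$dic$dic,
                         no_biological = nobio$fit$dic$dic)
    } else {
      result$dic <- list(empty = empty$dic$dic, full = step2$fit$dic$dic,
                         no_biological = NA_real_)
    }

    stage <- "variance_decomposition"
    result$icc <- icc(empty$tau2, empty$sigma2)
    result$variance_explained <- variance_explained(empty$fit, step2$fit)
    if (keep_fits) {
      result$fits <- list(step1 = step1$fit, step2 = step2$fit,
                          empty = empty$fit)
    }
    class(result) <- "pipeline_result"
    result
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  out
}

# quick provisional discriminations for item selection: corrected item-rest
# correlations mapped through a monotone transform, adequate for ranking
provisional_discriminations <- function(rm) {
  vals <- rm$values
  row_sum <- rowSums(vals, na.rm = TRUE)
  row_n <- rowSums(!is.na(vals))
  disc <- vapply(seq_len(ncol(vals)), function(k) {
    y <- vals[, k]
    obs <- !is.na(y) & (row_n - 1L) > 0L
    rest <- (row_sum[obs] - y[obs]) / (row_n[obs] - 1L)
    if (stats::sd(y[obs]) == 0 || stats::sd(rest) == 0) return(0)
    r <- stats::cor(y[obs], rest)
    r / sqrt(pmax(1 - r^2, 1e-6))
  }, numeric(1))
  stats::setNames(disc, colnames(vals))
}

select_item_columns <- function(rm, item_ids) {
  idx <- match(item_ids, rm$bank$item_id)
  bank <- rm$bank[idx, , drop = FALSE]
  class(bank) <- c("item_bank", "data.frame")
  response_matrix(rm$values[, idx, drop = FALSE], bank, rm$person_ids)
}

pipeline_person_design <- function(bundle, person_ids) {
  cp <- bundle$covariates_person
  if (is.null(cp)) return(NULL)
  cp <- cp[match(person_ids, cp$person_id), , drop = FALSE]
  num <- setdiff(names(cp)[vapply(cp, is.numeric, logical(1))],
                 c("person_id", "biological"))
  if (!length(num)) return(NULL)
  X <- as.matrix(cp[num])
  rownames(X) <- person_ids
  X
}

pipeline_dwelling_design <- function(bundle) {
  cd <- bundle$covariates_dwelling
  if (is.null(cd)) return(NULL)
  num <- names(cd)[vapply(cd, is.numeric, logical(1))]
  if (!length(num)) return(NULL)
  W <- as.matrix(cd[num])
  rownames(W) <- cd$dwelling_id
  W
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  persons kept: %d of %d\n", x$n_kept, x$n_total))
  cat(sprintf("  ICC: %.3f\n", x$icc))
  cat(sprintf("  variance explained: person %.3f, dwelling %.3f\n",
              x$variance_explained["person"], x$variance_explained["dwelling"]))
  cat(sprintf("  DIC: empty %.1f, full %.1f, no biological control %.1f\n",
              x$dic$empty, x$dic$full, x$dic$no_biological))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `report.json` (run metadata, ICC, variance explained, DIC triple,
#' retained items), `summary_step1.csv`, `summary_step2.csv`, `scores.csv`
#' and, when present, `diagnostics.json`.
#'
#' @param result a [run_pipeline()] output.
#' @param dir output directory.
#' @param extra named list merged into the report (e.g. config hash).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(result, dir, extra = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  report <- c(list(
    seed = result$seed,
    n_kept = result$n_kept, n_total = result$n_total,
    icc = result$icc,
    variance_explained = as.list(result$variance_explained),
    dic = result$dic,
    retained_items = result$retained_items
  ), extra)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(format_summary(result$step1$summary),
                   file.path(dir, "summary_step1.csv"), row.names = FALSE)
  utils::write.csv(format_summary(result$step2$summary),
                   file.path(dir, "summary_step2.csv"), row.names = FALSE)
  utils::write.csv(data.frame(person_id = names(result$step1$scores),
                              biological_score = unname(result$step1$scores)),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  if (!is.null(result$diagnostics)) {
    dj <- lapply(result$diagnostics, function(d) list(
      flagged_domains = d$bifactor$flagged_domains,
      dependent_pairs = d$dependence$flagged,
      monotonicity = as.list(d$monotonicity$verdicts),
      retained = as.character(d$retained)))
    jsonlite::write_json(dj, file.path(dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

# Table-style 3-decimal formatting of a posterior summary
format_summary <- function(s) {
  data.frame(parameter = s$parameter, block = s$block,
             mean = sprintf("%.3f", s$mean), sd = sprintf("%.3f", s$sd),
             hpd = sprintf("[%.3f, %.3f]", s$hpd_lower, s$hpd_upper),
             stringsAsFactors = FALSE)
}
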