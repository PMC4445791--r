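#' Construct a response matrix
#'
#' The observed data of the graded response model: a persons-by-items matrix
#' of 0-based ordinal codes with `NA` for missing responses. The orientation
#' is fixed so that a *higher* code means *more* difficulty, hence a higher
#' latent value means worse health.
#'
#' @param values integer matrix (persons x items); codes `0 .. C-1` or `NA`.
#' @param bank an [item_bank()] whose rows match the columns of `values`.
#' @param person_ids character vector of person identifiers (defaults to the
#'   rownames of `values`).
#'
#' @return An object of class `response_matrix`: a list with elements
#'   `values`, `bank`, `person_ids`.
#' @export
response_matrix <- function(values, bank, person_ids = rownames(values)) {
  assert_item_bank(bank)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (ncol(values) != nrow(bank)) {
    stop("number of columns must equal the number of items in the bank", call. = FALSE)
  }
  if (is.null(person_ids)) person_ids <- paste0("p", seq_len(nrow(values)))
  person_ids <- as.character(person_ids)
  if (anyDuplicated(person_ids)) stop("person_ids must be unique", call. = FALSE)
  colnames(values) <- bank$item_id
  rownames(values) <- person_ids
  for (k in seq_len(ncol(values))) {
    bad <- which(!is.na(values[, k]) &
                   (values[, k] < 0L | values[, k] >= bank$n_categories[k]))
    if (length(bad)) {
      stop(sprintf("out-of-range code for item '%s', person '%s'",
                   bank$item_id[k], person_ids[bad[1]]), call. = FALSE)
    }
  }
  structure(list(values = values, bank = bank, person_ids = person_ids),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items, %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Subset a response matrix by person
#'
#' @param rm a [response_matrix()].
#' @param person_ids identifiers to keep, in the requested order.
#' @return A `response_matrix` restricted to those persons.
#' @export
subset_persons <- function(rm, person_ids) {
  idx <- match(person_ids, rm$person_ids)
  if (anyNA(idx)) {
    stop("unknown person id(s): ", paste(person_ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  response_matrix(rm$values[idx, , drop = FALSE], rm$bank, person_ids)
}

#' Read survey responses from a delimited file
#'
#' Reads a CSV with one row per person: a `person_id` column followed by one
#' column per item, coded on the survey's 1-based ordinal scale (`1` = least
#' difficulty). Blank cells are missing. Codes are shifted to the package's
#' 0-based internal representation. Persons with all responses missing are
#' dropped with a warning.
#'
#' @param path path to the CSV file.
#' @param bank the [item_bank()] declaring the expected item columns.
#' @param drop_all_missing drop persons whose responses are all blank (with a
#'   warning). Set to `FALSE` for lived-health files, where non-aid users
#'   legitimately leave every question blank until equating fills them in.
#' @return A [response_matrix()].
#' @export
load_responses <- function(path, bank, drop_all_missing = TRUE) {
  assert_item_bank(bank)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"person_id" %in% names(raw)) stop("missing 'person_id' column", call. = FALSE)
  extra <- setdiff(names(raw), c("person_id", bank$item_id))
  if (length(extra)) {
    stop("unknown item column(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(bank$item_id, names(raw))
  if (length(missing_cols)) {
    stop("item column(s) absent from file: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  vals <- matrix(NA_integer_, nrow(raw), nrow(bank),
                 dimnames = list(raw$person_id, bank$item_id))
  for (k in seq_len(nrow(bank))) {
    col <- raw[[bank$item_id[k]]]
    nonblank <- !is.na(col) & nzchar(trimws(col))
    code <- suppressWarnings(as.integer(col[nonblank]))
    bad <- which(is.na(code) | code < 1L | code > bank$n_categories[k])
    if (length(bad)) {
      row_lab <- raw$person_id[which(nonblank)[bad[1]]]
      stop(sprintf("invalid code '%s' for item '%s' (person '%s'); expected 1..%d",
                   col[nonblank][bad[1]], bank$item_id[k], row_lab,
                   bank$n_categories[k]), call. = FALSE)
    }
    vals[nonblank, k] <- code - 1L
  }
  all_missing <- rowSums(!is.na(vals)) == 0L
  if (drop_all_missing && any(all_missing)) {
    warning(sprintf("dropping %d person(s) with all responses missing",
                    sum(all_missing)), call. = FALSE)
    vals <- vals[!all_missing, , drop = FALSE]
  }
  response_matrix(vals, bank)
}

#' Write survey responses to a delimited file
#'
#' Inverse of [load_responses()]: internal 0-based codes are written on the
#' survey's 1-based scale, missing cells as empty strings.
#'
#' @param rm a [response_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(rm, path) {
  out <- as.data.frame(rm$values + 1L)
  out[] <- lapply(out, function(x) ifelse(is.na(x), "", as.character(x)))
  out <- cbind(person_id = rm$person_ids, out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse ordinal response categories
#'
#' Merges response options with an order-preserving surjection of old codes
#' onto new codes, e.g. pooling "with moderate difficulty" and "with severe
#' difficulty" into a single middle option when their marginal frequencies are
#' low.
#'
#' @param rm a [response_matrix()].
#' @param mapping integer vector of length `C_old`; `mapping[c + 1]` is the new
#'   0-based code for old code `c`. Must be non-decreasing, start at 0, and
#'   increase in steps of at most 1.
#' @return A new [response_matrix()] with the reduced number of categories;
#'   missing cells are preserved.
#' @export
#' @examples
#' # pool codes 1 and 2 (moderate, severe) of a 4-category item into one
#' # collapse_categories(rm, c(0, 1, 1, 2))
collapse_categories <- function(rm, mapping) {
  mapping <- as.integer(mapping)
  if (length(unique(rm$bank$n_categories)) != 1L ||
      length(mapping) != rm$bank$n_categories[1]) {
    stop("mapping length must equal the common number of categories", call. = FALSE)
  }
  if (mapping[1] != 0L || any(diff(mapping) < 0L) || any(diff(mapping) > 1L)) {
    stop("mapping must be a non-decreasing surjection starting at 0", call. = FALSE)
  }
  new_c <- max(mapping) + 1L
  vals <- matrix(mapping[rm$values + 1L], nrow(rm$values), ncol(rm$values))
  bank <- rm$bank
  bank$n_categories <- new_c
  response_matrix(vals, bank, rm$person_ids)
}

#' Keep only respondents reporting some difficulty
#'
#' Retains persons with at least one non-missing response above the lowest
#' category of the biological-health items, the inclusion rule of the
#' analysis population ("had difficulty in at least one question").
#'
#' @param rm the biological-health [response_matrix()].
#' @return A list with `kept` (character vector of retained person ids),
#'   `n_kept`, and `n_total`.
#' @export
filter_respondents <- function(rm) {
  any_difficulty <- apply(rm$values, 1L, function(v) any(v > 0L, na.rm = TRUE))
  kept <- rm$person_ids[any_difficulty]
  if (!length(kept)) {
    stop("no person reports difficulty on any item; nothing to analyse",
         call. = FALSE)
  }
  list(kept = kept, n_kept = length(kept), n_total = length(rm$person_ids))
}

#' Equate lived-health responses with biological health for non-aid users
#'
#' Lived-health questions are answered only by people who use technical aids
#' and/or personal assistance in a domain. For everyone else, lived health in
#' that domain is defined to equal biological health: the corresponding
#' biological response is copied into the lived item.
#'
#' @param rm_bio biological-health [response_matrix()].
#' @param rm_lived lived-health [response_matrix()] over the same persons;
#'   cells of non-aid users are typically missing before equating.
#' @param aid_use logical matrix (persons x domains; dimnames required) —
#'   `TRUE` where the person uses aids/assistance in that domain.
#' @param item_map named character vector mapping each lived `item_id` to its
#'   matching biological `item_id`. If `NULL`, items are matched by domain,
#'   which must then be unambiguous (one biological item per lived item's
#'   domain).
#' @return The lived [response_matrix()] after equating.
#' @export
equate_lived_with_biological <- function(rm_bio, rm_lived, aid_use,
                                         item_map = NULL) {
  if (!identical(rm_bio$person_ids, rm_lived$person_ids)) {
    stop("biological and lived matrices must cover the same persons in order",
         call. = FALSE)
  }
  if (is.null(rownames(aid_use)) || is.null(colnames(aid_use))) {
    stop("aid_use needs person rownames and domain colnames", call. = FALSE)
  }
  aid_use <- aid_use[rm_bio$person_ids, , drop = FALSE]
  if (is.null(item_map)) {
    item_map <- vapply(seq_len(nrow(rm_lived$bank)), function(k) {
      dom <- rm_lived$bank$domain[k]
      cand <- rm_bio$bank$item_id[rm_bio$bank$domain == dom]
      if (length(cand) != 1L) NA_character_ else cand
    }, character(1))
    names(item_map) <- rm_lived$bank$item_id
  }
  vals <- rm_lived$values
  for (k in seq_len(ncol(vals))) {
    lived_id <- rm_lived$bank$item_id[k]
    dom <- rm_lived$bank$domain[k]
    if (!dom %in% colnames(aid_use)) {
      stop("aid_use has no column for domain '", dom, "'", call. = FALSE)
    }
    copy_rows <- which(!aid_use[, dom])
    if (!length(copy_rows)) next
    bio_id <- item_map[[lived_id]]
    if (is.null(bio_id) || is.na(bio_id) || !bio_id %in% rm_bio$bank$item_id) {
      stop("no matched biological item for lived item '", lived_id,
           "' but equating is required", call. = FALSE)
    }
    vals[copy_rows, k] <- rm_bio$values[copy_rows, bio_id]
  }
  response_matrix(vals, rm_lived$bank, rm_lived$person_ids)
}

#' Population-weighted descriptive table
#'
#' Weighted counts and percentages for categorical person characteristics,
#' the layout of a survey descriptives table. Percentages sum to 100 within
#' each variable.
#'
#' @param covariates data frame of factors/character columns, one row per
#'   person.
#' @param weights non-negative sampling weights, one per person; `NULL` means
#'   equal weights.
#' @return A data frame with columns `variable`, `category`, `n_weighted`,
#'   `pct`.
#' @export
weighted_descriptives <- function(covariates, weights = NULL) {
  covariates <- as.data.frame(covariates)
  n <- nrow(covariates)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights must align with persons", call. = FALSE)
  if (any(weights < 0)) stop("negative sampling weight", call. = FALSE)
  rows <- lapply(names(covariates), function(v) {
    f <- as.factor(covariates[[v]])
    wt <- vapply(levels(f), function(lv) sum(weights[f == lv]), numeric(1))
    data.frame(variable = v, category = levels(f),
               n_weighted = unname(wt),
               pct = unname(100 * wt / sum(wt)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a person-to-dwelling index
#'
#' @param person_id,dwelling_id equal-length vectors; each person must appear
#'   exactly once.
#' @return A data frame of class `dwelling_index`.
#' @export
dwelling_index <- function(person_id, dwelling_id) {
  person_id <- as.character(person_id)
  if (anyDuplicated(person_id)) {
    stop("each person must map to exactly one dwelling", call. = FALSE)
  }
  out <- data.frame(person_id = person_id,
                    dwelling_id = as.character(dwelling_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("dwelling_index", "data.frame")
  out
}
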