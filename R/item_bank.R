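#' Define an item bank
#'
#' An item bank describes the ordinal survey questions entering a graded
#' response model: their identifiers, the functioning domain each belongs to
#' (e.g. communication, mobility, self-care), whether the question measures
#' biological health (difficulty without aids or assistance) or lived health
#' (difficulty with any aids or assistance in place), and the number of
#' ordered response categories.
#'
#' Questions excluded from an analysis (for instance domains where the survey
#' did not separate aided from unaided performance) are simply left out of the
#' bank; no special-case handling exists downstream.
#'
#' @param item_id character vector of unique item identifiers.
#' @param domain character vector of functioning domains, recycled if scalar.
#' @param role `"biological"` or `"lived"`, recycled if scalar.
#' @param n_categories integer (>= 2) number of ordered response categories
#'   per item, recycled if scalar. After category collapsing all items in a
#'   fitted model must share one value.
#'
#' @return A data frame of class `item_bank` with columns `item_id`, `domain`,
#'   `role`, `n_categories`.
#' @export
#' @examples
#' item_bank(c("b1", "b2"), domain = "mobility", role = "biological", n_categories = 4)
item_bank <- function(item_id, domain, role = "biological", n_categories = 3L) {
  item_id <- as.character(item_id)
  if (anyDuplicated(item_id)) {
    stop("item_id values must be unique", call. = FALSE)
  }
  role <- match.arg(rep_len(as.character(role), length(item_id)),
                    c("biological", "lived"), several.ok = TRUE)
  n_categories <- as.integer(rep_len(n_categories, length(item_id)))
  if (any(n_categories < 2L)) {
    stop("each item needs at least 2 response categories", call. = FALSE)
  }
  bank <- data.frame(
    item_id = item_id,
    domain = rep_len(as.character(domain), length(item_id)),
    role = role,
    n_categories = n_categories,
    stringsAsFactors = FALSE
  )
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %d items (%s), %d domain(s)\n",
              nrow(x), paste(unique(x$role), collapse = "+"),
              length(unique(x$domain))))
  print.data.frame(x, ...)
  invisible(x)
}

assert_item_bank <- function(bank) {
  if (!inherits(bank, "item_bank")) stop("expected an 'item_bank'", call. = FALSE)
  invisible(bank)
}
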