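#' Define a fixed-length, sum-scored screening instrument
#'
#' An instrument is the scoring universe in which every stopping rule lives:
#' a fixed number of items, an integer score range per item, and an integer
#' cutoff on the total score at or above which a respondent screens positive
#' ("screened in"). Item ranges may differ across items; the canonical COMM
#' uses 17 items all scored 0--4 with cutoff 9 (see [comm_instrument()]).
#'
#' @param n_items Number of items (positive integer).
#' @param item_min Integer per-item score floor; a scalar is recycled to all
#'   items.
#' @param item_max Integer per-item score ceiling; a scalar is recycled.
#' @param cutoff Integer cutoff `T`: a total score `>= T` classifies positive.
#'   Must satisfy `sum(item_min) < cutoff <= sum(item_max)` so that both
#'   classifications are attainable.
#' @param item_labels Optional character vector of item labels.
#'
#' @return An object of class `"instrument"`: a list with elements `n_items`,
#'   `item_min`, `item_max`, `cutoff` and `item_labels`.
#' @examples
#' instrument(3, item_min = 0, item_max = 2, cutoff = 3)
#' @export
instrument <- function(n_items, item_min = 0L, item_max, cutoff,
                       item_labels = NULL) {
  if (length(n_items) != 1L || is.na(n_items) || n_items < 1 ||
      n_items != round(n_items)) {
    abort("`n_items` must be a single positive integer.")
  }
  n_items <- as.integer(n_items)
  item_min <- as_item_vector(item_min, n_items, "item_min")
  item_max <- as_item_vector(item_max, n_items, "item_max")
  if (any(item_min >= item_max)) {
    abort("`item_min` must be strictly below `item_max` for every item.")
  }
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff != round(cutoff)) {
    abort("`cutoff` must be a single integer.")
  }
  cutoff <- as.integer(cutoff)
  if (cutoff <= sum(item_min) || cutoff > sum(item_max)) {
    abort(paste0(
      "`cutoff` must satisfy sum(item_min) < cutoff <= sum(item_max) ",
      "so both classifications are attainable."
    ))
  }
  if (!is.null(item_labels) && length(item_labels) != n_items) {
    abort("`item_labels` must have one entry per item.")
  }
  structure(
    list(
      n_items = n_items, item_min = item_min, item_max = item_max,
      cutoff = cutoff, item_labels = item_labels
    ),
    class = "instrument"
  )
}

as_item_vector <- function(x, n_items, name) {
  if (anyNA(x) || any(x != round(x))) {
    abort(sprintf("`%s` must be integer-valued with no missing entries.", name))
  }
  x <- as.integer(x)
  if (length(x) == 1L) x <- rep(x, n_items)
  if (length(x) != n_items) {
    abort(sprintf("`%s` must have length 1 or `n_items`.", name))
  }
  x
}

#' The COMM instrument definition
#'
#' The Current Opioid Misuse Measure: 17 items scored 0 ("never") to 4
#' ("very often"), summed to a total in 0--68, with a total of 9 or more
#' taken as a positive screen.
#'
#' @return An [instrument()] object.
#' @examples
#' comm_instrument()
#' @export
comm_instrument <- function() {
  instrument(
    n_items = 17L, item_min = 0L, item_max = 4L, cutoff = 9L,
    item_labels = paste0("item_", 1:17)
  )
}

#' @export
print.instrument <- function(x, ...) {
  cat(sprintf(
    "<instrument> %d items, cutoff >= %d (totals %d..%d)\n",
    x$n_items, x$cutoff, sum(x$item_min), sum(x$item_max)
  ))
  rng <- paste0(x$item_min, "-", x$item_max)
  if (length(unique(rng)) == 1L) {
    cat(sprintf("  per-item score range: %s\n", rng[1]))
  } else {
    cat(sprintf("  per-item score ranges: %s\n", paste(rng, collapse = " ")))
  }
  invisible(x)
}

# attainable cumulative-score range after each stage
cum_min <- function(spec) cumsum(spec$item_min)
cum_max <- function(spec) cumsum(spec$item_max)

item_cols <- function(spec) paste0("item_", seq_len(spec$n_items))

is_instrument <- function(x) inherits(x, "instrument")

check_instrument <- function(spec) {
  if (!is_instrument(spec)) abort("`spec` must be an `instrument` object.")
  invisible(spec)
}

# Extract the n x n_items integer score matrix from a response data frame.
# Errors on a column-count mismatch (a configuration error, not a data error).
score_matrix <- function(data, spec, complete = TRUE) {
  check_instrument(spec)
  have <- grep("^item_[0-9]+$", names(data), value = TRUE)
  want <- item_cols(spec)
  if (!setequal(have, want)) {
    abort(sprintf(
      "response data has %d item columns but the instrument defines %d items.",
      length(have), spec$n_items
    ))
  }
  m <- as.matrix(data[want])
  if (!is.numeric(m)) abort("item columns must be numeric.")
  storage.mode(m) <- "double"
  if (complete && anyNA(m)) {
    abort(paste0(
      "response records contain missing item scores; ",
      "run `validate_responses()` first."
    ))
  }
  m
}
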