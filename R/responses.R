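#' Validate a response matrix and log exclusions
#'
#' Screens a raw respondent-by-item table against an instrument definition,
#' admitting only complete records whose scores lie inside the per-item
#' ranges. Mirrors the conservative handling of problem records in screening
#' studies: incomplete or out-of-range rows are excluded with a reason, never
#' clamped or imputed. Every input row ends up in exactly one of the two
#' returned tables.
#'
#' @param data A data frame with columns `item_1 .. item_n` (integer scores,
#'   `NA` for missing cells), optionally `respondent_id` and `gold` (binary
#'   external gold-standard label, 0/1).
#' @param spec An [instrument()].
#' @param require_gold If `TRUE`, rows with a missing `gold` label are also
#'   excluded (use when gold-standard metrics will be requested downstream).
#'   Requires a `gold` column.
#'
#' @return A list with elements
#'   * `admitted`: tibble of complete, in-range rows;
#'   * `excluded`: tibble with columns `respondent_id` and `reason`.
#' @examples
#' d <- tibble::tibble(item_1 = c(0, 5, NA), item_2 = c(1, 1, 1))
#' validate_responses(d, instrument(2, 0, 4, cutoff = 2))
#' @export
validate_responses <- function(data, spec, require_gold = FALSE) {
  check_instrument(spec)
  data <- as_tibble(data)
  if (!"respondent_id" %in% names(data)) {
    data$respondent_id <- sprintf("row_%d", seq_len(nrow(data)))
  }
  data$respondent_id <- as.character(data$respondent_id)
  if (require_gold && !"gold" %in% names(data)) {
    abort("`require_gold = TRUE` but the data has no `gold` column.")
  }

  m <- score_matrix(data, spec, complete = FALSE)
  miss <- is.na(m)
  nonint <- !miss & m != round(m)
  lo <- matrix(spec$item_min, nrow(m), spec$n_items, byrow = TRUE)
  hi <- matrix(spec$item_max, nrow(m), spec$n_items, byrow = TRUE)
  oor <- !miss & !nonint & (m < lo | m > hi)

  reasons <- character(nrow(data))
  add_reason <- function(reasons, flag, txt) {
    ifelse(flag, ifelse(reasons == "", txt, paste(reasons, txt, sep = "; ")),
           reasons)
  }
  reasons <- add_reason(reasons, rowSums(miss) > 0, "missing item score")
  reasons <- add_reason(reasons, rowSums(nonint) > 0, "non-integer item score")
  reasons <- add_reason(reasons, rowSums(oor) > 0, "item score out of range")
  if (require_gold) {
    gold_bad <- is.na(data$gold) |
      !(data$gold %in% c(0, 1, TRUE, FALSE))
    reasons <- add_reason(reasons, gold_bad, "missing gold label")
  }

  keep <- reasons == ""
  admitted <- data[keep, , drop = FALSE]
  # admitted scores are whole numbers: store them as integers
  for (col in item_cols(spec)) admitted[[col]] <- as.integer(admitted[[col]])
  list(
    admitted = admitted,
    excluded = tibble(
      respondent_id = data$respondent_id[!keep],
      reason = reasons[!keep]
    )
  )
}

#' Total score of each respondent
#'
#' Sums the item scores of complete response records. The total of a complete
#' record always lies in `[sum(item_min), sum(item_max)]`.
#'
#' @param data A data frame of complete responses (see [validate_responses()]).
#' @param spec An [instrument()].
#' @return An integer vector of totals, one per row of `data`.
#' @examples
#' total_score(tibble::tibble(item_1 = 2, item_2 = 3),
#'             instrument(2, 0, 4, cutoff = 5))
#' @export
total_score <- function(data, spec) {
  m <- score_matrix(data, spec)
  as.integer(rowSums(m))
}

#' Full-length classification of each respondent
#'
#' Classifies complete records by the instrument's cutoff: positive
#' ("screened in") iff the total score reaches the cutoff.
#'
#' @inheritParams total_score
#' @return A character vector, `"positive"` or `"negative"`, one per row.
#' @export
full_length_decision <- function(data, spec) {
  as_decision(total_score(data, spec) >= spec$cutoff)
}

as_decision <- function(positive) {
  ifelse(positive, "positive", "negative")
}

#' Per-item descriptive statistics
#'
#' Item-level mean, SD, median and inter-quartile range for a set of complete
#' response records, in the layout conventional for questionnaire descriptive
#' tables. SDs are sample SDs (denominator n - 1); the IQR is Q3 - Q1 using
#' type-7 quantiles (the [stats::quantile()] default).
#'
#' @inheritParams total_score
#' @param digits Optional number of decimals to round the statistics to for
#'   reporting (e.g. `1`); `NULL` (default) leaves them unrounded.
#' @return A tibble with columns `item`, `n`, `mean`, `sd`, `median`, `iqr`.
#' @export
describe_items <- function(data, spec, digits = NULL) {
  if (nrow(data) == 0L) abort("cannot describe an empty set of records.")
  m <- score_matrix(data, spec)
  out <- tibble(
    item = seq_len(spec$n_items),
    n = nrow(m),
    mean = unname(colMeans(m)),
    sd = unname(apply(m, 2, sd)),
    median = unname(apply(m, 2, median)),
    iqr = unname(apply(m, 2, function(x) {
      unname(diff(quantile(x, c(0.25, 0.75))))
    }))
  )
  if (!is.null(digits)) {
    out <- mutate(out, dplyr::across(c("mean", "sd", "median", "iqr"),
                                     ~ round(.x, digits)))
  }
  out
}
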