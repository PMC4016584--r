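#' Construct a stopping-boundary rule table
#'
#' A rule table holds, for each stage `k` (the point after the k-th
#' administered item), an optional negative stopping boundary `neg_max[k]`
#' (stop with a negative decision iff the cumulative score is `<= neg_max[k]`)
#' and an optional positive stopping boundary `pos_min[k]` (stop positive iff
#' the cumulative score is `>= pos_min[k]`). Absent boundaries are `NA` and
#' mean "never stop here for that decision" (the "N/A" cells of a printed
#' look-up table). The final stage must partition the attainable totals:
#' `neg_max[n] = cutoff - 1`, `pos_min[n] = cutoff`.
#'
#' @param stage Integer vector `1..n_items` (may be given in any order; the
#'   result is sorted).
#' @param neg_max,pos_min Integer vectors with `NA` for absent boundaries.
#' @param spec An [instrument()]; boundaries are validated against its
#'   attainable cumulative-score ranges.
#' @param method Label: `"curtailment"`, `"sc"` or `"full_length"`.
#' @param gamma Probability threshold used to derive the rule (1 for
#'   deterministic curtailment, `NA` for the full-length baseline).
#' @param constrained Whether the table is a monotone-constrained variant.
#'
#' @return A tibble of class `"curtail_rule"` with columns `stage`,
#'   `neg_max`, `pos_min` and metadata attributes (see [rule_meta()]).
#' @export
boundary_rule <- function(stage, neg_max, pos_min, spec,
                          method = "sc", gamma = NA_real_,
                          constrained = FALSE) {
  check_instrument(spec)
  n <- spec$n_items
  ord <- order(stage)
  stage <- as.integer(stage[ord])
  neg_max <- as.integer(neg_max[ord])
  pos_min <- as.integer(pos_min[ord])
  if (!identical(stage, seq_len(n))) {
    abort("`stage` must cover 1..n_items exactly once.")
  }
  cmin <- cum_min(spec)
  cmax <- cum_max(spec)
  if (is.na(neg_max[n]) || is.na(pos_min[n]) ||
      neg_max[n] != spec$cutoff - 1L || pos_min[n] != spec$cutoff) {
    abort(paste0(
      "malformed rule table: the final stage must partition the totals ",
      "(neg_max = cutoff - 1, pos_min = cutoff)."
    ))
  }
  bad_neg <- !is.na(neg_max) & (neg_max < cmin | neg_max >= cmax)
  bad_pos <- !is.na(pos_min) & (pos_min > cmax | pos_min <= cmin)
  # final stage is exempt from the strict-interior check on one side
  bad_neg[n] <- neg_max[n] < cmin[n] || neg_max[n] > cmax[n]
  bad_pos[n] <- pos_min[n] < cmin[n] || pos_min[n] > cmax[n]
  if (any(bad_neg) || any(bad_pos)) {
    abort(paste0(
      "boundaries outside the attainable cumulative-score range at stages: ",
      paste(which(bad_neg | bad_pos), collapse = ", "),
      " (store unattainable boundaries as NA)."
    ))
  }
  both <- !is.na(neg_max) & !is.na(pos_min)
  if (any(both & neg_max >= pos_min)) {
    abort("`neg_max` must be strictly below `pos_min` wherever both are present.")
  }
  out <- tibble(stage = stage, neg_max = neg_max, pos_min = pos_min)
  class(out) <- c("curtail_rule", class(out))
  attr(out, "method") <- method
  attr(out, "gamma") <- as.numeric(gamma)
  attr(out, "constrained") <- isTRUE(constrained)
  attr(out, "cutoff") <- spec$cutoff
  attr(out, "n_items") <- n
  out
}

#' Rule metadata
#'
#' @param rule A `"curtail_rule"` table.
#' @return A list with `method`, `gamma`, `constrained`, `cutoff`, `n_items`.
#' @export
rule_meta <- function(rule) {
  list(
    method = attr(rule, "method"),
    gamma = attr(rule, "gamma"),
    constrained = attr(rule, "constrained"),
    cutoff = attr(rule, "cutoff"),
    n_items = attr(rule, "n_items")
  )
}

#' Human-readable rule label
#'
#' `"full-length"`, `"curtailment"`, or `"SC-95"` style labels (with a
#' `"-constrained"` suffix for monotone-constrained variants).
#'
#' @param rule A `"curtail_rule"` table.
#' @return A string.
#' @export
rule_label <- function(rule) {
  meta <- rule_meta(rule)
  base <- switch(meta$method,
    full_length = "full-length",
    curtailment = "curtailment",
    sc = sprintf("SC-%g", round(100 * meta$gamma, 2)),
    meta$method
  )
  if (isTRUE(meta$constrained)) base <- paste0(base, "-constrained")
  base
}

#' @export
print.curtail_rule <- function(x, ...) {
  meta <- rule_meta(x)
  cat(sprintf(
    "<curtail_rule> %s (gamma = %s%s), %d items, cutoff >= %d\n",
    rule_label(x),
    ifelse(is.na(meta$gamma), "-", format(meta$gamma)),
    if (meta$constrained) ", constrained" else "",
    meta$n_items, meta$cutoff
  ))
  NextMethod()
}

#' Derive deterministic curtailment boundaries
#'
#' Curtailment stops as soon as the remaining items can no longer change the
#' final classification: positive once the cumulative score is guaranteed to
#' reach the cutoff whatever the remaining answers (for instruments with
#' all-zero item minima, once the score reaches the cutoff itself), negative
#' once the cutoff is unreachable even with maximal remaining scores. A rule
#' replayed through these boundaries always reproduces the full-length
#' classification exactly.
#'
#' @param spec An [instrument()].
#' @return A `"curtail_rule"` table with `gamma = 1`.
#' @examples
#' curtailment_boundaries(comm_instrument())
#' @export
curtailment_boundaries <- function(spec) {
  check_instrument(spec)
  n <- spec$n_items
  cmin <- cum_min(spec)
  cmax <- cum_max(spec)
  rest_min <- sum(spec$item_min) - cmin
  rest_max <- sum(spec$item_max) - cmax
  pos <- spec$cutoff - rest_min      # guaranteed positive from here
  neg <- spec$cutoff - 1L - rest_max # cutoff unreachable from here
  pos[pos > cmax] <- NA_integer_
  neg[neg < cmin] <- NA_integer_
  boundary_rule(seq_len(n), neg, pos, spec,
                method = "curtailment", gamma = 1)
}

#' The full-length (never-stop-early) baseline rule
#'
#' A degenerate rule table with no interim boundaries; every respondent takes
#' all items and is classified by the cutoff at the final stage. Used as the
#' comparison baseline in operating-characteristic reports.
#'
#' @param spec An [instrument()].
#' @return A `"curtail_rule"` table.
#' @export
full_length_rule <- function(spec) {
  check_instrument(spec)
  n <- spec$n_items
  neg <- rep(NA_integer_, n)
  pos <- rep(NA_integer_, n)
  neg[n] <- spec$cutoff - 1L
  pos[n] <- spec$cutoff
  boundary_rule(seq_len(n), neg, pos, spec,
                method = "full_length", gamma = NA_real_)
}

#' Replay complete response records through a stopping rule
#'
#' Simulates sequential administration post hoc: items are walked in the
#' instrument's fixed order, the cumulative score is accumulated, and the
#' test stops at the first stage whose negative (`score <= neg_max`) or
#' positive (`score >= pos_min`) boundary is hit; the final-stage partition
#' guarantees a decision by stage `n`. The full-length classification is
#' recorded alongside for concordance bookkeeping.
#'
#' @param data A data frame of complete responses (see
#'   [validate_responses()]); a `gold` column, if present, is carried
#'   through.
#' @param rule A `"curtail_rule"` table consistent with `spec`.
#' @param spec An [instrument()].
#' @return A tibble with one row per respondent: `respondent_id`,
#'   `stop_stage`, `items_administered`, `decision`,
#'   `full_length_decision`, and `gold` when present in `data`.
#' @examples
#' spec <- comm_instrument()
#' rec <- tibble::as_tibble(setNames(as.list(c(1, 0, 2, 2, 1, 0, 3,
#'                                             rep(0, 10))), paste0("item_", 1:17)))
#' apply_rule(rec, curtailment_boundaries(spec), spec)
#' @export
apply_rule <- function(data, rule, spec) {
  check_instrument(spec)
  meta <- rule_meta(rule)
  if (!inherits(rule, "curtail_rule")) abort("`rule` must be a `curtail_rule`.")
  if (meta$n_items != spec$n_items || meta$cutoff != spec$cutoff) {
    abort("rule table and instrument disagree on n_items or cutoff.")
  }
  n <- spec$n_items
  if (is.na(rule$neg_max[n]) || is.na(rule$pos_min[n]) ||
      rule$neg_max[n] != spec$cutoff - 1L || rule$pos_min[n] != spec$cutoff) {
    abort("malformed rule table: final stage is not a partition of the totals.")
  }
  m <- score_matrix(data, spec)
  cum <- m %*% upper.tri(diag(n), diag = TRUE)
  pos_b <- ifelse(is.na(rule$pos_min), Inf, rule$pos_min)
  neg_b <- ifelse(is.na(rule$neg_max), -Inf, rule$neg_max)
  pos_hit <- sweep(cum, 2, pos_b, ">=")
  neg_hit <- sweep(cum, 2, neg_b, "<=")
  hit <- pos_hit | neg_hit
  stopifnot(all(hit[, n]))
  ss <- max.col(hit, ties.method = "first")
  idx <- cbind(seq_len(nrow(m)), ss)
  out <- tibble(
    respondent_id = if ("respondent_id" %in% names(data)) {
      as.character(data$respondent_id)
    } else {
      sprintf("row_%d", seq_len(nrow(m)))
    },
    stop_stage = as.integer(ss),
    items_administered = as.integer(ss),
    decision = as_decision(pos_hit[idx]),
    full_length_decision = as_decision(cum[, n] >= spec$cutoff)
  )
  if ("gold" %in% names(data)) out$gold <- data$gold
  out
}

#' Render a rule table in look-up-table notation
#'
#' Formats each cell as `"N/A"`, `"Score <= x"`, `"Score >= x"`, or the
#' equality form `"Score = x"` when the boundary coincides with the
#' attainable extreme at that stage (e.g. a stage-1 positive boundary equal
#' to the maximum single-item score).
#'
#' @param rule A `"curtail_rule"` table.
#' @param spec The matching [instrument()].
#' @return A tibble with character columns `stage`, `negative_stopping`,
#'   `positive_stopping`.
#' @export
format_rule <- function(rule, spec) {
  check_instrument(spec)
  cmin <- cum_min(spec)
  cmax <- cum_max(spec)
  fmt <- function(bound, extreme, op) {
    ifelse(
      is.na(bound), "N/A",
      ifelse(bound == extreme, sprintf("Score = %d", bound),
             sprintf("Score %s %d", op, bound))
    )
  }
  tibble(
    stage = rule$stage,
    negative_stopping = fmt(rule$neg_max, cmin, "<="),
    positive_stopping = fmt(rule$pos_min, cmax, ">=")
  )
}
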