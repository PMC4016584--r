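#' Operating characteristics of a stopping rule on a test cohort
#'
#' Replays every complete record through the rule (via [apply_rule()]) and
#' summarises the replay the way screening shortening studies report it:
#' sensitivity and specificity of the shortened rule's decisions for
#' predicting the full-length classification, the same against an external
#' gold-standard label when one is supplied, the mean and SD of the number
#' of items administered, and the percentage of respondents whose tests
#' stopped before the last item. The reference classification is always the
#' row dimension: sensitivity is the fraction of reference-positive records
#' the rule also calls positive.
#'
#' A proportion whose reference class is empty is reported as `NA`, never
#' coerced to 0 or 1. The SD of test length is the sample SD.
#'
#' @param data A data frame of complete responses; include a complete
#'   `gold` column (0/1) to obtain gold-standard metrics.
#' @param rule A `"curtail_rule"` table.
#' @param spec An [instrument()].
#' @return A one-row tibble: `method`, `gamma`, `constrained`, `n`,
#'   `sens_full`, `spec_full`, `sens_gold`, `spec_gold`, `asn_mean`,
#'   `asn_sd`, `pct_early`, and a list-column `counts` holding the 2x2
#'   concordance cells for each comparison.
#' @export
evaluate_rule <- function(data, rule, spec) {
  out <- apply_rule(data, rule, spec)
  meta <- rule_meta(rule)
  dec <- out$decision == "positive"
  full <- out$full_length_decision == "positive"

  cells <- function(ref) {
    tibble(
      tp = sum(dec & ref), fn = sum(!dec & ref),
      fp = sum(dec & !ref), tn = sum(!dec & !ref)
    )
  }
  safe_prop <- function(num, den) if (den == 0) NA_real_ else num / den

  cf <- cells(full)
  counts <- mutate(cf, comparison = "full_length", .before = 1)
  sens_gold <- spec_gold <- NA_real_
  if ("gold" %in% names(data)) {
    g <- data$gold
    if (anyNA(g) || !all(g %in% c(0, 1, TRUE, FALSE))) {
      abort("`gold` must be a complete 0/1 column; validate with `require_gold = TRUE` or drop it.")
    }
    g <- as.logical(g)
    cg <- cells(g)
    counts <- bind_rows(counts, mutate(cg, comparison = "gold", .before = 1))
    sens_gold <- safe_prop(cg$tp, cg$tp + cg$fn)
    spec_gold <- safe_prop(cg$tn, cg$tn + cg$fp)
  }

  len <- out$items_administered
  tibble(
    method = rule_label(rule),
    gamma = meta$gamma,
    constrained = meta$constrained,
    n = nrow(out),
    sens_full = safe_prop(cf$tp, cf$tp + cf$fn),
    spec_full = safe_prop(cf$tn, cf$tn + cf$fp),
    sens_gold = sens_gold,
    spec_gold = spec_gold,
    asn_mean = mean(len),
    asn_sd = if (length(len) > 1) sd(len) else 0,
    pct_early = 100 * mean(out$stop_stage < meta$n_items),
    counts = list(counts)
  )
}

#' Compare stopping rules on one test cohort
#'
#' Evaluates each supplied rule plus (by default) the full-length baseline
#' on the same records, producing one report row per method in a fixed
#' order, suitable for rendering a sensitivity/specificity/test-length grid.
#'
#' @param data A data frame of complete responses.
#' @param rules A single `"curtail_rule"` or a list of them.
#' @param spec An [instrument()].
#' @param include_full_length Prepend the full-length baseline row.
#' @return A tibble with one row per method (see [evaluate_rule()]).
#' @export
compare_rules <- function(data, rules, spec, include_full_length = TRUE) {
  if (inherits(rules, "curtail_rule")) rules <- list(rules)
  if (include_full_length) {
    rules <- c(list(full_length_rule(spec)), rules)
  }
  purrr::map_dfr(rules, function(r) evaluate_rule(data, r, spec))
}
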