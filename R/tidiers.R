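#' Tidy per-stage probability models
#'
#' @param x A `"stage_models"` tibble from [fit_stage_models()].
#' @param ... Unused.
#' @return A long tibble with columns `stage`, `fit_method`, `separation`,
#'   `term`, `estimate` (estimates are `NA` for empirical-fallback stages,
#'   whose lookup lives in the model object itself).
#' @exportS3Method generics::tidy
tidy.stage_models <- function(x, ...) {
  tidyr::pivot_longer(
    select(as_tibble(x), "stage", "fit_method", "separation",
           "intercept", "slope"),
    c("intercept", "slope"),
    names_to = "term", values_to = "estimate"
  )
}

#' @rdname tidy.stage_models
#' @return `glance()` returns a one-row tibble with `n_train`, `n_stages`,
#'   `n_separated`, `positive_rate`, `cutoff`, `n_items`.
#' @exportS3Method generics::glance
glance.stage_models <- function(x, ...) {
  tibble(
    n_train = x$n_train[1],
    n_stages = nrow(x),
    n_separated = sum(x$separation),
    positive_rate = attr(x, "positive_rate"),
    cutoff = attr(x, "cutoff"),
    n_items = attr(x, "n_items")
  )
}

#' Tidy a stopping-rule table
#'
#' @param x A `"curtail_rule"` table.
#' @param ... Unused.
#' @return The boundary tibble with the rule metadata spread into columns
#'   `method`, `gamma`, `constrained`.
#' @exportS3Method generics::tidy
tidy.curtail_rule <- function(x, ...) {
  meta <- rule_meta(x)
  mutate(as_tibble(x),
         method = rule_label(x), gamma = meta$gamma,
         constrained = meta$constrained)
}

#' @rdname tidy.curtail_rule
#' @return `glance()` returns a one-row tibble with the metadata plus the
#'   number of stages carrying each boundary type.
#' @exportS3Method generics::glance
glance.curtail_rule <- function(x, ...) {
  meta <- rule_meta(x)
  tibble(
    method = rule_label(x),
    gamma = meta$gamma,
    constrained = meta$constrained,
    cutoff = meta$cutoff,
    n_items = meta$n_items,
    n_neg_stages = sum(!is.na(x$neg_max)),
    n_pos_stages = sum(!is.na(x$pos_min))
  )
}
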