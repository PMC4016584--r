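#' Fit per-stage probability models on a training cohort
#'
#' For each interim stage `k = 1..n_items - 1`, models the probability that
#' the full-length classification is positive given the cumulative score
#' after `k` items, by maximum-likelihood logistic regression on the training
#' records (intercept + slope on the cumulative score). Late stages of a
#' screener often exhibit (quasi-)separation: the cumulative score then
#' predicts the outcome perfectly and the logistic likelihood has no finite
#' maximizer. Such stages are flagged and carry an empirical fallback instead:
#' the observed conditional proportion positive at each cumulative score,
#' extended to unobserved scores by a left-continuous step function.
#'
#' The outcome modelled is the instrument's own full-length classification,
#' not any external gold standard: the stopping probabilities are defined
#' with respect to the "screened in"/"screened out" result the complete
#' questionnaire would give.
#'
#' @param data A data frame of complete training responses.
#' @param spec An [instrument()].
#' @param min_n Warn when fewer training records than this are supplied.
#' @param sep_threshold Absolute slope magnitude beyond which a fit is
#'   treated as separated (on the log-odds-per-point scale).
#' @return A tibble of class `"stage_models"` with columns `stage`,
#'   `intercept`, `slope`, `fit_method` (`"maximum-likelihood"` or
#'   `"empirical-fallback"`), `separation`, `n_train` and a list-column
#'   `empirical` (the score/probability lookup for fallback stages).
#' @export
fit_stage_models <- function(data, spec, min_n = 30L, sep_threshold = 10) {
  check_instrument(spec)
  m <- score_matrix(data, spec)
  n <- spec$n_items
  if (nrow(m) < 2L) abort("at least two training records are required.")
  cum <- m %*% upper.tri(diag(n), diag = TRUE)
  y <- cum[, n] >= spec$cutoff
  if (all(y) || !any(y)) {
    abort("training outcome has a single class; no stage model is identifiable.")
  }
  if (nrow(m) < min_n) {
    warn(sprintf("only %d training records (fewer than min_n = %d); stage models may be unstable.",
                 nrow(m), min_n))
  }
  rows <- purrr::map(seq_len(n - 1L), function(k) {
    x <- cum[, k]
    fit <- fit_logit_ml(x, y, sep_threshold)
    if (fit$separation) {
      tab <- tibble(
        score = sort(unique(x)),
        prob = vapply(sort(unique(x)), function(s) mean(y[x == s]), numeric(1))
      )
      tibble(
        stage = k, intercept = NA_real_, slope = NA_real_,
        fit_method = "empirical-fallback", separation = TRUE,
        n_train = nrow(m), empirical = list(tab)
      )
    } else {
      tibble(
        stage = k, intercept = fit$intercept, slope = fit$slope,
        fit_method = "maximum-likelihood", separation = FALSE,
        n_train = nrow(m), empirical = list(NULL)
      )
    }
  })
  out <- bind_rows(rows)
  class(out) <- c("stage_models", class(out))
  attr(out, "cutoff") <- spec$cutoff
  attr(out, "n_items") <- n
  attr(out, "positive_rate") <- mean(y)
  out
}

# ML logistic fit of P(y = 1 | x) with separation detection. Divergent or
# non-converged fits (infinite-likelihood configurations) are flagged so the
# caller can fall back to an empirical estimator.
fit_logit_ml <- function(x, y, sep_threshold = 10) {
  msgs <- character()
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  cf <- coef(fit)
  separation <- !isTRUE(fit$converged) || anyNA(cf) ||
    any(grepl("fitted probabilities numerically 0 or 1", msgs)) ||
    any(grepl("did not converge", msgs)) ||
    abs(cf[["x"]]) > sep_threshold
  list(
    intercept = unname(cf[1]), slope = unname(cf[2]),
    separation = separation
  )
}

#' Estimated probability of a positive full-length result
#'
#' Evaluates a stage model at one or more cumulative scores: the inverse
#' logit of `intercept + slope * score` for maximum-likelihood stages, or a
#' left-continuous step lookup of the empirical conditional proportions for
#' fallback stages. Scores outside the stage's attainable range (when `spec`
#' is given) are clamped to the range endpoints with a warning.
#'
#' @param models A `"stage_models"` tibble from [fit_stage_models()].
#' @param stage Interim stage number.
#' @param score Integer cumulative score(s) after `stage` items.
#' @param spec Optional [instrument()] used to clamp `score` to the
#'   attainable range.
#' @return A numeric vector of probabilities in `[0, 1]`.
#' @export
estimate_probability <- function(models, stage, score, spec = NULL) {
  row <- models[models$stage == stage, ]
  if (nrow(row) != 1L) abort(sprintf("no model for stage %s.", stage))
  if (!is.null(spec)) {
    check_instrument(spec)
    lo <- cum_min(spec)[stage]
    hi <- cum_max(spec)[stage]
    if (any(score < lo | score > hi)) {
      warn(sprintf("scores outside the attainable range [%d, %d] at stage %d were clamped.",
                   lo, hi, stage))
      score <- pmin(pmax(score, lo), hi)
    }
  }
  if (row$fit_method == "maximum-likelihood") {
    plogis(row$intercept + row$slope * score)
  } else {
    tab <- row$empirical[[1]]
    if (nrow(tab) == 1L) {
      rep(tab$prob, length(score))
    } else {
      approx(tab$score, tab$prob, xout = score,
             method = "constant", f = 0, rule = 2)$y
    }
  }
}

#' Derive stochastic-curtailment boundaries at a probability threshold
#'
#' Converts fitted stage models into an integer stopping-boundary look-up
#' table: at stage `k`, the positive boundary is the smallest attainable
#' cumulative score whose estimated positive probability reaches or exceeds
#' `gamma` (non-strict), and the negative boundary the largest attainable
#' score whose negative probability (one minus positive) reaches or exceeds
#' `gamma`; a boundary is absent when no attainable score qualifies. Each
#' stage is then unioned with the deterministic curtailment boundary, so
#' guaranteed outcomes always stop even where a finite-sample fit fails to
#' reflect them, and the final stage is fixed to the cutoff partition.
#'
#' @param models A `"stage_models"` tibble from [fit_stage_models()].
#' @param gamma Probability threshold in (0.5, 1), e.g. 0.90, 0.95, 0.99.
#' @param spec An [instrument()].
#' @param constrained If `TRUE`, apply [constrain_monotone()] to the result.
#' @return A `"curtail_rule"` table with `method = "sc"`.
#' @export
sc_boundaries <- function(models, gamma, spec, constrained = FALSE) {
  check_instrument(spec)
  if (length(gamma) != 1L || is.na(gamma) || gamma <= 0.5 || gamma >= 1) {
    abort("`gamma` must be a single probability in (0.5, 1); gamma = 1 is deterministic curtailment.")
  }
  n <- spec$n_items
  if (!identical(as.integer(models$stage), seq_len(n - 1L))) {
    abort("`models` must contain one model per interim stage 1..n_items-1.")
  }
  if (attr(models, "n_items") != n || attr(models, "cutoff") != spec$cutoff) {
    abort("stage models and instrument disagree on n_items or cutoff.")
  }
  cmin <- cum_min(spec)
  cmax <- cum_max(spec)
  curt <- curtailment_boundaries(spec)
  neg <- rep(NA_integer_, n)
  pos <- rep(NA_integer_, n)
  for (k in seq_len(n - 1L)) {
    s <- seq.int(cmin[k], cmax[k])
    p <- estimate_probability(models, k, s)
    pos_q <- s[p >= gamma]
    neg_q <- s[(1 - p) >= gamma]
    if (length(pos_q)) {
      pos[k] <- min(pos_q)
      if (!all(p[s >= pos[k]] >= gamma)) {
        warn(sprintf("non-monotone estimated probabilities at stage %d; positive boundary taken at the smallest qualifying score.", k))
      }
    }
    if (length(neg_q)) {
      neg[k] <- max(neg_q)
      if (!all((1 - p[s <= neg[k]]) >= gamma)) {
        warn(sprintf("non-monotone estimated probabilities at stage %d; negative boundary taken at the largest qualifying score.", k))
      }
    }
  }
  # union with deterministic curtailment: guaranteed outcomes always stop
  pos <- pmin(pos, curt$pos_min, na.rm = TRUE)
  neg <- pmax(neg, curt$neg_max, na.rm = TRUE)
  pos[n] <- spec$cutoff
  neg[n] <- spec$cutoff - 1L
  clash <- !is.na(neg) & !is.na(pos) & neg >= pos
  if (any(clash)) {
    warn(sprintf("overlapping stopping regions at stages %s; negative boundaries truncated below the positive ones.",
                 paste(which(clash), collapse = ", ")))
    neg[clash] <- pos[clash] - 1L
    neg[!is.na(neg) & neg < cmin] <- NA_integer_
  }
  rule <- boundary_rule(seq_len(n), neg, pos, spec,
                        method = "sc", gamma = gamma)
  if (constrained) constrain_monotone(rule, spec) else rule
}

#' Monotone-constrained variant of a stopping rule
#'
#' Stage-by-stage fitting does not force boundary sequences to be
#' nondecreasing across stages, and an occasional dip can result (a positive
#' requirement of 9 at one stage but 8 at the next). The constrained variant
#' adjusts conservatively: positive boundaries are raised to the forward
#' running maximum over the stages where they are present, and negative
#' boundaries lowered to the backward running minimum, so the constrained
#' rule never stops a respondent the unconstrained rule would continue. The
#' final-stage partition is untouched.
#'
#' @param rule A `"curtail_rule"` table.
#' @param spec The matching [instrument()].
#' @return A `"curtail_rule"` table with the `constrained` flag set.
#' @export
constrain_monotone <- function(rule, spec) {
  check_instrument(spec)
  meta <- rule_meta(rule)
  n <- meta$n_items
  pos <- rule$pos_min
  neg <- rule$neg_max
  idx <- seq_len(n - 1L)
  pres <- idx[!is.na(pos[idx])]
  pos[pres] <- cummax(pos[pres])
  pres <- idx[!is.na(neg[idx])]
  neg[pres] <- rev(cummin(rev(neg[pres])))
  boundary_rule(rule$stage, neg, pos, spec,
                method = meta$method, gamma = meta$gamma,
                constrained = TRUE)
}
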