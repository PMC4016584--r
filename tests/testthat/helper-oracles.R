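# shared fixtures and independent oracles for the test suite

comm_spec <- function() comm_instrument()

# one complete COMM record from a plain score vector
comm_record <- function(scores, id = "r1", gold = NULL) {
  stopifnot(length(scores) == 17)
  out <- tibble::as_tibble(setNames(as.list(as.integer(scores)),
                                    paste0("item_", 1:17)))
  out <- tibble::add_column(out, respondent_id = id, .before = 1)
  if (!is.null(gold)) out$gold <- gold
  out
}

# matrix of records -> response tibble
records_tibble <- function(m, gold = NULL) {
  out <- tibble::as_tibble(as.data.frame(m),
                           .name_repair = ~ paste0("item_", seq_along(.x)))
  out <- tibble::add_column(out,
                            respondent_id = sprintf("r%03d", seq_len(nrow(m))),
                            .before = 1)
  if (!is.null(gold)) out$gold <- gold
  out
}

# a small, quick generator config with a realistic class balance
helper_config <- function(n, seed = 1, missing_rate = 0,
                          gold_missing_rate = 0) {
  spec <- comm_spec()
  lambda <- 0.9
  s <- sqrt(1 + lambda^2)
  thresholds <- rep(list(s * c(0.5, 1.2, 1.9, 2.6)), 17)
  cohort_config(
    spec, n, loadings = lambda, thresholds = thresholds,
    gold_intercept = -0.7, gold_slope = 1.5,
    missing_rate = missing_rate, gold_missing_rate = gold_missing_rate,
    seed = seed
  )
}

# Brute-force stopping-boundary oracle: for each stage and attainable
# cumulative score, enumerate every completion of the remaining items and
# stop exactly when all completions share one classification. Independent of
# the analytic boundary algebra.
oracle_boundaries <- function(spec) {
  n <- spec$n_items
  neg <- rep(NA_integer_, n)
  pos <- rep(NA_integer_, n)
  cmin <- cumsum(spec$item_min)
  cmax <- cumsum(spec$item_max)
  for (k in seq_len(n)) {
    if (k < n) {
      rest <- expand.grid(lapply((k + 1):n, function(j) {
        spec$item_min[j]:spec$item_max[j]
      }))
      rest_sums <- rowSums(rest)
    } else {
      rest_sums <- 0L
    }
    neg_scores <- integer()
    pos_scores <- integer()
    for (s in cmin[k]:cmax[k]) {
      cls <- (s + rest_sums) >= spec$cutoff
      if (all(cls)) pos_scores <- c(pos_scores, s)
      if (!any(cls)) neg_scores <- c(neg_scores, s)
    }
    if (length(neg_scores)) neg[k] <- max(neg_scores)
    if (length(pos_scores)) pos[k] <- min(pos_scores)
  }
  list(neg_max = neg, pos_min = pos)
}

# Grid-search maximizer of the Bernoulli-logistic likelihood, independent of
# glm. Profiles the concave likelihood: a 1-d coarse-to-fine grid over the
# slope, maximizing over the intercept by a nested 1-d coarse-to-fine grid
# (safe for unimodal functions, unlike joint box refinement on a correlated
# ridge).
grid_ml_logit <- function(x, y, int_range = c(-30, 30), slope_range = c(-5, 5),
                          steps = 21, refinements = 5) {
  loglik <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta)))
  }
  refine1d <- function(f, range) {
    for (r in seq_len(refinements)) {
      g <- seq(range[1], range[2], length.out = steps)
      v <- vapply(g, f, numeric(1))
      j <- which.max(v)
      st <- g[2] - g[1]
      range <- c(g[j] - st, g[j] + st)
    }
    best <- mean(range)
    list(arg = best, value = f(best))
  }
  profile <- function(b) refine1d(function(a) loglik(a, b), int_range)
  slope <- refine1d(function(b) profile(b)$value, slope_range)$arg
  list(intercept = profile(slope)$arg, slope = slope)
}
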