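#' Configure a synthetic cohort generator
#'
#' The generator emulates a sum-score screener population with a
#' unidimensional latent-severity model: each respondent draws a latent
#' trait `z ~ N(0, 1)`; item `j`'s latent response is
#' `loading[j] * z + e`, `e ~ N(0, 1)`, categorised against the item's
#' ordered thresholds to give an ordinal score in `item_min..item_max`; and
#' the binary gold-standard label is drawn with probability
#' `plogis(gold_intercept + gold_slope * z)`. Because the gold label depends
#' on the trait rather than on the item responses, screen-versus-gold
#' discrimination is imperfect by construction, matching the moderate
#' (around 0.70) sensitivity/specificity regime of real screeners.
#'
#' @param spec An [instrument()].
#' @param n Number of respondents to generate.
#' @param loadings Nonnegative per-item association with the latent trait;
#'   a scalar is recycled.
#' @param thresholds A list with one numeric vector per item of
#'   `item_max - item_min` strictly increasing cut-points on the
#'   latent-response scale, or `NULL` for symmetric defaults.
#' @param gold_intercept,gold_slope Parameters of the gold-label model on
#'   the log-odds scale.
#' @param missing_rate Probability that an item cell is blanked (to exercise
#'   exclusion logic); 0 for complete data.
#' @param gold_missing_rate Probability that a gold label is blanked.
#' @param seed Integer seed; a fixed seed yields a byte-identical cohort.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(spec, n, loadings = 0.9, thresholds = NULL,
                          gold_intercept = -0.7, gold_slope = 1.5,
                          missing_rate = 0, gold_missing_rate = 0,
                          seed = 1L) {
  check_instrument(spec)
  if (length(n) != 1L || n < 1) abort("`n` must be a positive count.")
  loadings <- rep_len(as.numeric(loadings), spec$n_items)
  if (any(loadings < 0) || anyNA(loadings)) {
    abort("`loadings` must be nonnegative.")
  }
  k_cats <- spec$item_max - spec$item_min # number of cut-points per item
  if (is.null(thresholds)) {
    thresholds <- purrr::map2(loadings, k_cats, function(l, k) {
      s <- sqrt(1 + l^2)
      s * (seq_len(k) - (k + 1) / 2)
    })
  }
  if (length(thresholds) != spec$n_items) {
    abort("`thresholds` must have one vector per item.")
  }
  ok <- purrr::map2_lgl(thresholds, k_cats, function(tau, k) {
    length(tau) == k && !anyNA(tau) && all(diff(tau) > 0)
  })
  if (!all(ok)) {
    abort("each item needs `item_max - item_min` strictly increasing thresholds.")
  }
  structure(
    list(
      spec = spec, n = as.integer(n), loadings = loadings,
      thresholds = thresholds,
      gold_intercept = gold_intercept, gold_slope = gold_slope,
      missing_rate = missing_rate, gold_missing_rate = gold_missing_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n = %d respondents, %d items, seed = %d\n",
    x$n, x$spec$n_items, x$seed
  ))
  cat(sprintf(
    "  loadings %.2f..%.2f; gold model logit^-1(%.3f + %.3f z); missing rate %g\n",
    min(x$loadings), max(x$loadings), x$gold_intercept, x$gold_slope,
    x$missing_rate
  ))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws a complete respondent-by-item score table (plus gold label) from a
#' [cohort_config()]. Deterministic under the config's seed: the same
#' config always yields the identical tibble. The latent traits are attached
#' as the `"trait"` attribute for diagnostic use; the seed and a hash of the
#' config are attached for provenance and embedded by [write_responses()].
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `respondent_id`, `item_1..item_n`, `gold`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be a `cohort_config`.")
  }
  spec <- config$spec
  n <- config$n
  withr::with_seed(config$seed, {
    z <- rnorm(n)
    scores <- matrix(0L, n, spec$n_items)
    for (j in seq_len(spec$n_items)) {
      y <- config$loadings[j] * z + rnorm(n)
      scores[, j] <- spec$item_min[j] +
        findInterval(y, config$thresholds[[j]])
    }
    gold <- rbinom(n, 1L, plogis(config$gold_intercept +
                                   config$gold_slope * z))
    if (config$missing_rate > 0) {
      blank <- matrix(runif(n * spec$n_items) < config$missing_rate,
                      n, spec$n_items)
      scores[blank] <- NA_integer_
    }
    if (config$gold_missing_rate > 0) {
      gold[runif(n) < config$gold_missing_rate] <- NA_integer_
    }
  })
  out <- tibble(respondent_id = sprintf("r%05d", seq_len(n)))
  for (j in seq_len(spec$n_items)) out[[paste0("item_", j)]] <- scores[, j]
  out$gold <- gold
  attr(out, "seed") <- config$seed
  attr(out, "config_hash") <- hash(unclass(config))
  attr(out, "trait") <- z
  out
}

#' Published reference moments for the COMM validation samples
#'
#' Item-level means and SDs (plus medians and IQRs) reported for the COMM's
#' validation ("training", n = 214) and cross-validation ("test", n = 201)
#' samples, together with the sample-level targets a calibrated synthetic
#' cohort should reproduce: screen-positive prevalence at the >= 9 cutoff,
#' gold-standard-positive prevalence, the full-length screen's sensitivity
#' and specificity against the gold standard, and the total-score mean/SD.
#'
#' @param dataset `"training"` or `"test"`.
#' @return A tibble with columns `item`, `mean`, `sd`, `median`, `iqr` and a
#'   `"targets"` attribute (list with `screen_positive`, `gold_positive`,
#'   `sens_gold`, `spec_gold`, `total_mean`, `total_sd`).
#' @export
comm_reference_moments <- function(dataset = c("training", "test")) {
  dataset <- match.arg(dataset)
  if (dataset == "training") {
    out <- tibble(
      item = 1:17,
      mean = c(1.3, 0.8, 0.3, 0.6, 0.4, 1.0, 1.1, 0.7, 0.1, 0.5, 0.5, 0.2,
               1.2, 0.6, 0.1, 0.2, 0.4),
      sd = c(1.1, 1.1, 0.7, 0.9, 0.8, 1.0, 0.9, 0.8, 0.4, 0.9, 0.9, 0.5,
             0.8, 0.8, 0.5, 0.6, 0.7),
      median = c(1, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0),
      iqr = c(2, 1, 0, 1, 1, 1, 1, 1, 0, 1, 1, 0, 1, 1, 0, 0, 1)
    )
    targets <- list(
      screen_positive = 0.486, gold_positive = 0.341,
      sens_gold = 0.703, spec_gold = 0.701,
      total_mean = 10.1, total_sd = 7.5
    )
  } else {
    out <- tibble(
      item = 1:17,
      mean = c(1.5, 0.8, 0.2, 0.6, 0.2, 0.8, 1.1, 0.8, 0.0, 0.4, 0.3, 0.1,
               1.2, 0.5, 0.0, 0.2, 0.2),
      sd = c(1.2, 1.0, 0.6, 0.9, 0.6, 1.0, 1.0, 1.0, 0.2, 0.8, 0.7, 0.5,
             1.0, 0.8, 0.2, 0.6, 0.5),
      median = c(1, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0),
      iqr = c(2, 1, 0, 1, 0, 1, 2, 1, 0, 1, 0, 0, 2, 1, 0, 0, 0)
    )
    targets <- list(
      screen_positive = 0.428, gold_positive = 0.318,
      sens_gold = 0.703, spec_gold = 0.701,
      total_mean = 8.9, total_sd = 6.9
    )
  }
  attr(out, "targets") <- targets
  out
}

# --- closed-form machinery for calibration --------------------------------

# quadrature grid over the latent trait
trait_grid <- function(step = 0.01, span = 6) {
  z <- seq(-span, span, by = step)
  w <- dnorm(z)
  list(z = z, w = w / sum(w))
}

# marginal mean/SD of an ordinal item with cut-points tau on a latent
# response of SD s (normal-ogive closed form)
item_marginal_moments <- function(tau, s, item_min) {
  k <- length(tau)
  p_ge <- 1 - pnorm(tau / s)              # P(X0 >= c), c = 1..k
  m0 <- sum(p_ge)
  ex2 <- sum((2 * seq_len(k) - 1) * p_ge) # E[X0^2]
  list(mean = item_min + m0, sd = sqrt(max(ex2 - m0^2, 0)))
}

# solve equally-spaced cut-points (location, spread) for target mean/SD
calibrate_item_thresholds <- function(mean_t, sd_t, item_min, k, s) {
  m0_t <- min(max(mean_t - item_min, 1e-3), k - 1e-3)
  obj <- function(par) {
    tau <- par[1] + exp(par[2]) * (seq_len(k) - (k + 1) / 2)
    mm <- item_marginal_moments(tau, s, 0)
    (mm$mean - m0_t)^2 + (mm$sd - sd_t)^2
  }
  init <- c(s * qnorm(1 - m0_t / k), log(0.8 * s))
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 1000, reltol = 1e-10))
  fit$par[1] + exp(fit$par[2]) * (seq_len(k) - (k + 1) / 2)
}

# P(X0 >= c | z) for each z in grid: pnorm(lambda * z - tau_c)
item_conditional_pge <- function(tau, lambda, z) {
  vapply(tau, function(t) pnorm(lambda * z - t), numeric(length(z)))
}

# distribution of the total shifted score sum(X0_j) given z: matrix
# (length(z) x total_max + 1) of probabilities, by convolution over items
total_conditional_pmf <- function(thresholds, loadings, z) {
  total_k <- sum(lengths(thresholds))
  pmf <- matrix(0, length(z), total_k + 1L)
  pmf[, 1] <- 1
  width <- 0L
  for (j in seq_along(thresholds)) {
    pge <- item_conditional_pge(thresholds[[j]], loadings[j], z)
    k <- ncol(pge)
    cat_p <- cbind(1 - pge[, 1, drop = FALSE],
                   if (k > 1) pge[, -k, drop = FALSE] - pge[, -1, drop = FALSE],
                   pge[, k, drop = FALSE])
    new <- matrix(0, length(z), total_k + 1L)
    for (c in 0:k) {
      cols <- seq_len(width + 1L)
      new[, cols + c] <- new[, cols + c] + pmf[, cols] * cat_p[, c + 1L]
    }
    pmf <- new
    width <- width + k
  }
  pmf
}

#' Calibrate a cohort config to target moments
#'
#' Chooses generator parameters so that simulated cohorts reproduce a set of
#' published marginal moments: per-item thresholds are matched to each
#' item's target mean and SD through the normal-ogive closed form (equally
#' spaced cut-points, two free parameters per item); a single common loading
#' is tuned so the model-implied total-score SD matches its target (which
#' fixes the inter-item dependence a sum-score screener presumes); and the
#' gold-label intercept/slope are chosen by least squares against the target
#' gold prevalence and the screen-versus-gold sensitivity and specificity.
#' All matching uses quadrature over the latent trait, so calibration is
#' deterministic - no simulation is involved until [generate_cohort()].
#'
#' @param targets A tibble with columns `item`, `mean`, `sd` and optionally a
#'   `"targets"` attribute as returned by [comm_reference_moments()].
#' @param spec An [instrument()].
#' @param n Cohort size to store in the resulting config.
#' @param seed Seed to store in the resulting config.
#' @param loading Fix the common loading instead of tuning it (used when the
#'   targets carry no total-score SD).
#' @param loading_range Search interval for the common loading.
#' @return A [cohort_config()] whose `"achieved"` attribute reports the
#'   model-implied moments next to their targets: an `items` tibble and
#'   scalars `screen_positive`, `gold_positive`, `sens_gold`, `spec_gold`,
#'   `total_mean`, `total_sd`.
#' @export
calibrate_cohort <- function(targets, spec, n, seed = 1L, loading = NULL,
                             loading_range = c(0.3, 1.6)) {
  check_instrument(spec)
  targets <- as_tibble(targets)
  if (!all(c("item", "mean", "sd") %in% names(targets)) ||
      nrow(targets) != spec$n_items) {
    abort("`targets` needs columns item/mean/sd with one row per item.")
  }
  targets <- arrange(targets, .data$item)
  bad <- targets$mean < spec$item_min | targets$mean > spec$item_max |
    targets$sd < 0
  if (any(bad)) {
    abort(sprintf("unattainable targets for items: %s.",
                  paste(which(bad), collapse = ", ")))
  }
  extra <- attr(targets, "targets") %||% list()
  k_cats <- spec$item_max - spec$item_min
  grid <- trait_grid()

  solve_thresholds <- function(lambda) {
    s <- sqrt(1 + lambda^2)
    purrr::pmap(
      list(targets$mean, targets$sd, spec$item_min, k_cats),
      function(m, sd, lo, k) calibrate_item_thresholds(m, sd, lo, k, s)
    )
  }
  implied_total_sd <- function(lambda, thresholds) {
    lam <- rep(lambda, spec$n_items)
    mu_z <- rep(0, length(grid$z))
    ex2_z <- rep(0, length(grid$z))
    for (j in seq_len(spec$n_items)) {
      pge <- item_conditional_pge(thresholds[[j]], lam[j], grid$z)
      m_j <- rowSums(pge)
      e2_j <- as.vector(pge %*% (2 * seq_len(ncol(pge)) - 1))
      ex2_z <- ex2_z + (e2_j - m_j^2) # accumulate conditional variances
      mu_z <- mu_z + m_j
    }
    et <- sum(grid$w * mu_z)
    vt <- sum(grid$w * (ex2_z + mu_z^2)) - et^2
    list(mean = sum(spec$item_min) + et, sd = sqrt(vt))
  }

  if (is.null(loading)) {
    if (is.null(extra$total_sd)) {
      loading <- 0.9
    } else {
      loading <- optimize(function(l) {
        (implied_total_sd(l, solve_thresholds(l))$sd - extra$total_sd)^2
      }, loading_range, tol = 1e-3)$minimum
    }
  }
  thresholds <- solve_thresholds(loading)
  loadings <- rep(loading, spec$n_items)
  tot <- implied_total_sd(loading, thresholds)

  # screen-positive probability at each trait value
  pmf <- total_conditional_pmf(thresholds, loadings, grid$z)
  need <- spec$cutoff - sum(spec$item_min) # shifted-score cutoff
  s_z <- rowSums(pmf[, (need + 1L):ncol(pmf), drop = FALSE])
  screen_prev <- sum(grid$w * s_z)

  gold_int <- -0.7
  gold_slo <- 1.5
  achieved_gold <- list(prev = NA_real_, sens = NA_real_, spec = NA_real_)
  if (!is.null(extra$gold_positive)) {
    gold_ops <- function(a, b) {
      g <- plogis(a + b * grid$z)
      prev <- sum(grid$w * g)
      list(
        prev = prev,
        sens = sum(grid$w * g * s_z) / prev,
        spec = sum(grid$w * (1 - g) * (1 - s_z)) / (1 - prev)
      )
    }
    obj <- function(par) {
      o <- gold_ops(par[1], par[2])
      (o$prev - extra$gold_positive)^2 +
        (o$sens - (extra$sens_gold %||% o$sens))^2 +
        (o$spec - (extra$spec_gold %||% o$spec))^2
    }
    fit <- optim(c(qlogis(extra$gold_positive), 1.5), obj,
                 method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-10))
    gold_int <- fit$par[1]
    gold_slo <- fit$par[2]
    achieved_gold <- gold_ops(gold_int, gold_slo)
  }

  config <- cohort_config(
    spec, n, loadings = loadings, thresholds = thresholds,
    gold_intercept = gold_int, gold_slope = gold_slo, seed = seed
  )
  s <- sqrt(1 + loading^2)
  item_achieved <- purrr::map2_dfr(thresholds, seq_len(spec$n_items),
    function(tau, j) {
      mm <- item_marginal_moments(tau, s, spec$item_min[j])
      tibble(item = j, target_mean = targets$mean[j], achieved_mean = mm$mean,
             target_sd = targets$sd[j], achieved_sd = mm$sd)
    })
  attr(config, "achieved") <- list(
    items = item_achieved,
    loading = loading,
    screen_positive = screen_prev,
    gold_positive = achieved_gold$prev,
    sens_gold = achieved_gold$sens,
    spec_gold = achieved_gold$spec,
    total_mean = tot$mean,
    total_sd = tot$sd
  )
  config
}
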