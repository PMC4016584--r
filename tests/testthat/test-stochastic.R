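make_models <- function(spec, intercepts, slopes) {
  n <- spec$n_items
  out <- tibble::tibble(
    stage = seq_len(n - 1L),
    intercept = rep_len(intercepts, n - 1L),
    slope = rep_len(slopes, n - 1L),
    fit_method = "maximum-likelihood",
    separation = FALSE,
    n_train = 1000L,
    empirical = rep(list(NULL), n - 1L)
  )
  class(out) <- c("stage_models", class(out))
  attr(out, "cutoff") <- spec$cutoff
  attr(out, "n_items") <- n
  attr(out, "positive_rate") <- 0.5
  out
}

test_that("estimate_probability evaluates the inverse-logit closed form", {
  spec <- instrument(11, 0, 4, cutoff = 12)
  models <- make_models(spec, -6, 1)
  expect_equal(estimate_probability(models, 3, 6), 0.5)
  expect_equal(estimate_probability(models, 3, 9), plogis(3))
  # logistic symmetry about the logit zero
  expect_equal(estimate_probability(models, 3, 3),
               1 - estimate_probability(models, 3, 9))
  # out-of-range scores are clamped with a warning
  expect_warning(
    p <- estimate_probability(models, 2, 20, spec = spec),
    "clamped"
  )
  expect_equal(p, plogis(-6 + 1 * 8))
})

test_that("sc_boundaries inverts the probability threshold into integer boundaries", {
  # 11 items of 0-4 within 10 stages gives stage-3 attainable range 0..12;
  # use a wide instrument so the attainable range covers the closed form
  spec <- instrument(11, 0, 4, cutoff = 22)
  models <- make_models(spec, -6, 1)
  # the same toy model at every stage contradicts the cutoff arithmetic at
  # late stages, where the union rule truncates with a warning
  suppressWarnings(rule <- sc_boundaries(models, 0.95, spec))
  # smallest s with plogis(s - 6) >= 0.95 is ceil(6 + log(19)) = 9, reached
  # from stage 3 on (stage-2 max is 8)
  expect_equal(rule$pos_min[3], 9L)
  expect_equal(rule$pos_min[2], NA_integer_)
  # largest s with 1 - plogis(s - 6) >= 0.95 is 3
  expect_equal(rule$neg_max[3], 3L)
  expect_equal(rule_meta(rule)$method, "sc")
  expect_equal(rule_meta(rule)$gamma, 0.95)
})

test_that("a degenerate exact probability model reduces to curtailment via the union rule", {
  spec <- instrument(4, 0, 2, cutoff = 4)
  curt <- curtailment_boundaries(spec)
  cmin <- cumsum(spec$item_min)
  cmax <- cumsum(spec$item_max)
  # empirical models carrying the guaranteed probabilities: 1 in the
  # guaranteed-positive region, 0 in the guaranteed-negative, 0.5 between
  rows <- purrr::map(seq_len(spec$n_items - 1L), function(k) {
    s <- cmin[k]:cmax[k]
    p <- rep(0.5, length(s))
    if (!is.na(curt$pos_min[k])) p[s >= curt$pos_min[k]] <- 1
    if (!is.na(curt$neg_max[k])) p[s <= curt$neg_max[k]] <- 0
    tibble::tibble(stage = k, intercept = NA_real_, slope = NA_real_,
                   fit_method = "empirical-fallback", separation = TRUE,
                   n_train = 100L,
                   empirical = list(tibble::tibble(score = s, prob = p)))
  })
  models <- dplyr::bind_rows(rows)
  class(models) <- c("stage_models", class(models))
  attr(models, "cutoff") <- spec$cutoff
  attr(models, "n_items") <- spec$n_items
  rule <- sc_boundaries(models, 0.999, spec)
  expect_equal(rule$neg_max, curt$neg_max)
  expect_equal(rule$pos_min, curt$pos_min)
})

test_that("fitted stage models maximize the likelihood (grid-search oracle)", {
  spec <- comm_spec()
  train <- generate_cohort(helper_config(1500, seed = 21))
  models <- fit_stage_models(train, spec)
  ml <- models[models$fit_method == "maximum-likelihood", ]
  expect_gte(nrow(ml), 3)
  m <- as.matrix(train[paste0("item_", 1:17)])
  cum <- t(apply(m, 1, cumsum))
  y <- cum[, 17] >= 9
  for (k in utils::head(ml$stage, 3)) {
    orc <- grid_ml_logit(cum[, k], y)
    row <- ml[ml$stage == k, ]
    expect_equal(row$slope, orc$slope, tolerance = 0.02)
    expect_equal(row$intercept, orc$intercept, tolerance = 0.05)
  }
})

test_that("constructed separation triggers the empirical fallback", {
  # stage-1 score >= 6 perfectly predicts the full-length classification
  set.seed(3)
  item1 <- sample(0:10, 200, replace = TRUE)
  item2 <- ifelse(item1 >= 6, 9L, 0L)
  spec <- instrument(2, 0, 10, cutoff = 15)
  d <- records_tibble(cbind(item1, item2))
  models <- fit_stage_models(d, spec)
  expect_true(models$separation[1])
  expect_equal(models$fit_method[1], "empirical-fallback")
  tab <- models$empirical[[1]]
  expect_equal(tab$prob, as.numeric(sort(unique(item1)) >= 6))
})

test_that("empirical fallback equals hand-computed conditional proportions", {
  # 10-record hand dataset on a 2-item instrument; sep_threshold = 0 forces
  # the empirical estimator at every stage
  spec <- instrument(2, 0, 5, cutoff = 6)
  item1 <- c(0L, 0L, 2L, 2L, 2L, 4L, 4L, 5L, 5L, 5L)
  item2 <- c(0L, 5L, 0L, 5L, 5L, 0L, 5L, 0L, 5L, 5L)
  d <- records_tibble(cbind(item1, item2))
  models <- suppressWarnings(
    fit_stage_models(d, spec, min_n = 5, sep_threshold = 0)
  )
  expect_equal(models$fit_method[1], "empirical-fallback")
  tab <- models$empirical[[1]]
  # positive iff item1 + item2 >= 6: by hand, score 0 -> 0/2, 2 -> 2/3,
  # 4 -> 1/2, 5 -> 2/3
  expect_equal(tab$score, c(0L, 2L, 4L, 5L))
  expect_equal(tab$prob, c(0, 2 / 3, 1 / 2, 2 / 3))
  # step lookup carries the nearest observed score below; ends are clamped
  expect_equal(estimate_probability(models, 1, c(1, 3, 6)),
               c(0, 2 / 3, 2 / 3))
})

test_that("single-class training data is rejected", {
  spec <- instrument(2, 0, 4, cutoff = 8)
  d <- records_tibble(matrix(0L, 20, 2))
  expect_error(fit_stage_models(d, spec), "single class")
})

test_that("threshold nesting: stricter gamma gives smaller stopping regions", {
  spec <- comm_spec()
  train <- generate_cohort(helper_config(1200, seed = 8))
  models <- fit_stage_models(train, spec)
  curt <- curtailment_boundaries(spec)
  # empirical-fallback stages can be non-monotone in the score; the
  # extreme-qualifying-score convention warns on its own
  rules <- lapply(c(0.90, 0.95, 0.99), function(g) {
    suppressWarnings(sc_boundaries(models, g, spec))
  })
  # region(pos = a) subset of region(pos = b); likewise for negative regions
  subset_pos <- function(a, b) is.na(a) | (!is.na(b) & a >= b)
  subset_neg <- function(a, b) is.na(a) | (!is.na(b) & a <= b)
  for (i in 1:2) {
    strict <- rules[[i + 1]]
    loose <- rules[[i]]
    expect_true(all(subset_pos(strict$pos_min, loose$pos_min)))
    expect_true(all(subset_neg(strict$neg_max, loose$neg_max)))
  }
  # every SC region contains the deterministic curtailment region
  for (r in rules) {
    expect_true(all(subset_pos(curt$pos_min, r$pos_min)))
    expect_true(all(subset_neg(curt$neg_max, r$neg_max)))
  }
})

test_that("constrain_monotone adjusts dips conservatively", {
  spec <- comm_spec()
  # the published dip: positive boundary 9 at stage 3 but 8 at stages 4-5
  pos <- c(NA, NA, 9L, 8L, 8L, 9L, rep(9L, 10), 9L)
  neg <- c(rep(NA_integer_, 14), 0L, 4L, 8L)
  rule <- boundary_rule(1:17, neg, pos, spec, method = "sc", gamma = 0.99)
  con <- constrain_monotone(rule, spec)
  expect_equal(con$pos_min[3:6], rep(9L, 4))
  expect_true(rule_meta(con)$constrained)
  # the adjustment never enlarges a stopping region
  expect_true(all(is.na(rule$pos_min) == is.na(con$pos_min)))
  expect_true(all(con$pos_min >= rule$pos_min, na.rm = TRUE))

  # already-monotone boundaries are untouched
  ct <- curtailment_boundaries(spec)
  con2 <- constrain_monotone(ct, spec)
  expect_equal(con2$neg_max, ct$neg_max)
  expect_equal(con2$pos_min, ct$pos_min)

  # backward running minimum on the negative side, by hand: 2,4,3,5 -> 2,3,3,5
  spec5 <- instrument(5, 0, 4, cutoff = 12)
  neg5 <- c(2L, 4L, 3L, 5L, 11L)
  pos5 <- c(NA, NA, 12L, 12L, 12L)
  rule5 <- boundary_rule(1:5, neg5, pos5, spec5, method = "sc", gamma = 0.9)
  expect_equal(constrain_monotone(rule5, spec5)$neg_max,
               c(2L, 3L, 3L, 5L, 11L))
})

test_that("gamma outside (0.5, 1) is rejected", {
  spec <- comm_spec()
  models <- make_models(spec, -6, 1)
  expect_error(sc_boundaries(models, 1, spec), "gamma")
  expect_error(sc_boundaries(models, 0.5, spec), "gamma")
})
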