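test_that("COMM curtailment boundaries match the published look-up table", {
  spec <- comm_spec()
  ct <- curtailment_boundaries(spec)
  expect_equal(rule_meta(ct)$gamma, 1)
  expect_equal(ct$pos_min, c(NA, NA, rep(9L, 15)))
  expect_equal(ct$neg_max, c(rep(NA_integer_, 14), 0L, 4L, 8L))
})

test_that("degenerate and tiny instruments derive correct boundaries", {
  one <- instrument(1, 0, 4, cutoff = 1)
  ct1 <- curtailment_boundaries(one)
  expect_equal(ct1$neg_max, 0L)
  expect_equal(ct1$pos_min, 1L)

  spec3 <- instrument(3, 0, 2, cutoff = 3)
  ct3 <- curtailment_boundaries(spec3)
  orc <- oracle_boundaries(spec3)
  expect_equal(ct3$neg_max, orc$neg_max)
  expect_equal(ct3$pos_min, orc$pos_min)
})

test_that("curtailment boundaries equal the exhaustive-completion oracle on small instruments", {
  # every instrument with <= 3 items, score widths <= 3 and a nonzero-floor
  # variant, across all attainable cutoffs
  for (n in 1:3) {
    widths <- expand.grid(rep(list(1:3), n))
    for (w in seq_len(nrow(widths))) {
      item_max <- as.integer(widths[w, ])
      for (cutoff in 1:sum(item_max)) {
        spec <- instrument(n, 0, item_max, cutoff = cutoff)
        got <- curtailment_boundaries(spec)
        orc <- oracle_boundaries(spec)
        expect_equal(got$neg_max, orc$neg_max)
        expect_equal(got$pos_min, orc$pos_min)
      }
    }
  }
  # nonzero item minima shift the guaranteed-positive boundary
  spec <- instrument(3, item_min = c(1, 0, 2), item_max = c(3, 2, 4),
                     cutoff = 6)
  got <- curtailment_boundaries(spec)
  orc <- oracle_boundaries(spec)
  expect_equal(got$neg_max, orc$neg_max)
  expect_equal(got$pos_min, orc$pos_min)
})

test_that("curtailment boundaries are monotone where present", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(3:8, 1)
    spec <- instrument(n, 0, sample(2:4, n, replace = TRUE),
                       cutoff = sample(2:5, 1))
    ct <- curtailment_boundaries(spec)
    neg <- ct$neg_max[!is.na(ct$neg_max)]
    expect_true(all(diff(neg) >= 0))
    pos <- ct$pos_min[!is.na(ct$pos_min)]
    if (all(spec$item_min == 0)) {
      expect_true(all(pos == spec$cutoff))
    }
  }
})

test_that("apply_rule replays the worked examples", {
  spec <- comm_spec()
  ct <- curtailment_boundaries(spec)

  # score reaches the cutoff after item 7: stop positive there
  worked <- comm_record(c(1, 0, 2, 2, 1, 0, 3, rep(0, 10)))
  out <- apply_rule(worked, ct, spec)
  expect_equal(out$stop_stage, 7L)
  expect_equal(out$decision, "positive")
  expect_equal(out$items_administered, 7L)

  # the all-zero respondent cannot reach 9 once 15 items are answered
  out0 <- apply_rule(comm_record(rep(0, 17)), ct, spec)
  expect_equal(out0$stop_stage, 15L)
  expect_equal(out0$decision, "negative")

  # maximal scoring hits the cutoff at the first stage where 9 is attainable
  out4 <- apply_rule(comm_record(rep(4, 17)), ct, spec)
  expect_equal(out4$stop_stage, 3L)
  expect_equal(out4$decision, "positive")

  # boundary hits are non-strict: a score equal to pos_min stops
  eq <- comm_record(c(4, 4, 1, rep(0, 14)))
  expect_equal(apply_rule(eq, ct, spec)$stop_stage, 3L)
})

test_that("apply_rule rejects malformed tables and mismatched instruments", {
  spec <- comm_spec()
  ct <- curtailment_boundaries(spec)
  bad <- ct
  bad$pos_min[17] <- 10L
  expect_error(apply_rule(comm_record(rep(0, 17)), bad, spec), "partition")
  spec4 <- instrument(4, 0, 4, cutoff = 9)
  expect_error(apply_rule(comm_record(rep(0, 17)),
                          curtailment_boundaries(spec4), spec), "disagree")
})

test_that("curtailment decisions always equal the full-length classification", {
  spec <- comm_spec()
  ct <- curtailment_boundaries(spec)
  coh <- generate_cohort(helper_config(400, seed = 5))
  out <- apply_rule(coh, ct, spec)
  expect_equal(out$decision, out$full_length_decision)
  expect_equal(out$full_length_decision, full_length_decision(coh, spec))
  expect_lte(mean(out$items_administered), spec$n_items)
  expect_true(any(out$stop_stage < spec$n_items))
})

test_that("boundary_rule validates ranges, ordering and the final partition", {
  spec <- instrument(3, 0, 2, cutoff = 3)
  expect_error(
    boundary_rule(1:3, c(NA, NA, 2L), c(NA, NA, 4L), spec),
    "partition"
  )
  expect_error(
    boundary_rule(1:3, c(3L, NA, 2L), c(NA, NA, 3L), spec),
    "attainable"
  )
  expect_error(
    boundary_rule(1:3, c(NA, 2L, 2L), c(NA, 2L, 3L), spec),
    "strictly below"
  )
})

test_that("format_rule renders N/A and the equality forms", {
  spec <- comm_spec()
  fmt <- format_rule(curtailment_boundaries(spec), spec)
  expect_equal(fmt$negative_stopping[1], "N/A")
  expect_equal(fmt$negative_stopping[15], "Score = 0")   # attainable minimum
  expect_equal(fmt$negative_stopping[16], "Score <= 4")
  expect_equal(fmt$positive_stopping[3], "Score >= 9")
  # a positive boundary at the stage maximum renders as equality
  r <- boundary_rule(1:17, c(rep(NA, 16), 8L), c(4L, rep(NA, 15), 9L), spec)
  expect_equal(format_rule(r, spec)$positive_stopping[1], "Score = 4")
})
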