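test_that("instrument construction validates its invariants", {
  spec <- instrument(3, item_min = c(0, 1, 0), item_max = c(2, 3, 2),
                     cutoff = 4)
  expect_s3_class(spec, "instrument")
  expect_equal(spec$item_min, c(0L, 1L, 0L))
  expect_equal(cumsum(spec$item_max), c(2L, 5L, 7L))

  # scalar ranges broadcast
  expect_equal(instrument(4, 0, 4, cutoff = 5)$item_max, rep(4L, 4))
  # degenerate or unattainable configurations are rejected
  expect_error(instrument(2, 0, 0, cutoff = 1), "strictly below")
  expect_error(instrument(2, 0, 4, cutoff = 0), "attainable")
  expect_error(instrument(2, 0, 4, cutoff = 9), "attainable")
  expect_error(instrument(2, 1, 4, cutoff = 2), "attainable")
})

test_that("the COMM instrument spans totals 0 to 68 with cutoff 9", {
  spec <- comm_instrument()
  expect_equal(spec$n_items, 17L)
  expect_equal(sum(spec$item_min), 0L)
  expect_equal(sum(spec$item_max), 68L)
  expect_equal(spec$cutoff, 9L)
})

test_that("validate_responses partitions rows into admitted and excluded", {
  spec <- comm_spec()
  m <- matrix(1L, 5, 17)
  d <- records_tibble(m, gold = c(1, 0, 1, 0, 1))
  d$item_9[3] <- NA            # incomplete questionnaire
  d$gold[5] <- NA              # missing gold classification
  res <- validate_responses(d, spec, require_gold = TRUE)
  expect_equal(nrow(res$admitted), 3L)
  expect_equal(nrow(res$excluded), 2L)
  expect_setequal(res$excluded$reason,
                  c("missing item score", "missing gold label"))
  expect_equal(nrow(res$admitted) + nrow(res$excluded), nrow(d))

  # complete matrix: everything admitted, empty log
  res2 <- validate_responses(records_tibble(matrix(2L, 4, 17)), spec)
  expect_equal(nrow(res2$admitted), 4L)
  expect_equal(nrow(res2$excluded), 0L)

  # out-of-range score on a 0-4 item is an exclusion, not a crash or a clamp
  d3 <- records_tibble(matrix(0L, 2, 17))
  d3$item_1[2] <- 5L
  res3 <- validate_responses(d3, spec)
  expect_equal(res3$excluded$reason, "item score out of range")
  expect_equal(res3$admitted$respondent_id, "r001")

  # non-integer scores are excluded with their own reason
  d4 <- records_tibble(matrix(0L, 1, 17))
  d4$item_2 <- 1.5
  expect_equal(validate_responses(d4, spec)$excluded$reason,
               "non-integer item score")

  # wrong item-column count is a configuration error
  expect_error(validate_responses(d[-2], spec), "item columns")
})

test_that("total_score and full_length_decision follow the cutoff rule", {
  spec <- comm_spec()
  worked <- comm_record(c(1, 0, 2, 2, 1, 0, 3, rep(0, 10)))
  expect_equal(total_score(worked, spec), 9L)
  expect_equal(full_length_decision(worked, spec), "positive")

  expect_equal(total_score(comm_record(rep(0, 17)), spec), 0L)
  expect_equal(total_score(comm_record(rep(4, 17)), spec), 68L)
  expect_equal(full_length_decision(comm_record(rep(0, 17)), spec),
               "negative")
  # boundary: total 8 misses a >= 9 cutoff
  expect_equal(full_length_decision(comm_record(c(rep(1, 8), rep(0, 9))),
                                    spec), "negative")

  # totals are permutation-invariant over items
  set.seed(11)
  v <- sample(0:4, 17, replace = TRUE)
  expect_equal(total_score(comm_record(v), spec),
               total_score(comm_record(sample(v)), spec))

  # incomplete records must not be silently scored
  d <- comm_record(rep(1, 17))
  d$item_3 <- NA_integer_
  expect_error(total_score(d, spec), "missing")
})

test_that("describe_items matches a naive reimplementation", {
  spec <- instrument(2, 0, 4, cutoff = 5)
  d <- tibble::tibble(item_1 = c(0L, 1L, 1L, 2L, 4L),
                      item_2 = rep(2L, 5))
  out <- describe_items(d, spec)

  # independent hand computation for (0,1,1,2,4)
  expect_equal(out$mean[1], 1.6)
  expect_equal(out$sd[1], sqrt(sum((c(0, 1, 1, 2, 4) - 1.6)^2) / 4))
  expect_equal(out$median[1], 1)
  # constant column: all spread statistics vanish
  expect_equal(out$mean[2], 2)
  expect_equal(out$sd[2], 0)
  expect_equal(out$iqr[2], 0)

  naive <- function(x) {
    c(mean = sum(x) / length(x),
      sd = sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1)),
      median = median(x),
      iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)))
  }
  for (j in 1:2) {
    x <- d[[paste0("item_", j)]]
    expect_equal(unname(unlist(out[j, c("mean", "sd", "median", "iqr")])),
                 unname(naive(x)))
  }

  expect_equal(describe_items(d, spec, digits = 1)$sd[1],
               round(out$sd[1], 1))
  expect_error(describe_items(d[0, ], spec), "empty")
})
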