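test_that("normalized weights follow the three-step matrix normalization", {
  # 2x2 hand example: s = 10, column shares (0.8, 0.2)
  sv <- data.frame(a = c(5, 3), b = c(1, 1))
  pm <- suppressMessages(
    build_preference_matrix(sv, criterion_set(c("a", "b"))))
  w <- normalized_raw_weights(pm)
  expect_equal(w$s, 10)
  expect_equal(unname(w$raw_fractions), c(0.8, 0.2))
  expect_equal(sum(w$percentages), 100L)

  # identical columns -> uniform fractions
  pm2 <- pm_from_matrix(matrix(3L, 4, 5))
  expect_equal(unname(normalized_raw_weights(pm2)$raw_fractions), rep(0.2, 5))

  # single respondent, constant row
  pm3 <- pm_from_matrix(matrix(3L, 1, 5))
  expect_equal(unname(normalized_raw_weights(pm3)$raw_fractions), rep(0.2, 5))
})

test_that("normalized fractions agree with a brute-force double loop", {
  set.seed(7)
  for (rep_i in 1:10) {
    P <- sample(1:6, 1); Q <- sample(2:4, 1)
    A <- matrix(sample(1:5, P * Q, TRUE), P, Q)
    pm <- suppressMessages(build_preference_matrix(
      setNames(as.data.frame(A), letters[1:Q]),
      criterion_set(letters[1:Q])))
    expect_equal(unname(normalized_raw_weights(pm)$raw_fractions),
                 brute_force_normalized(A), tolerance = 1e-12)
  }
})

test_that("normalized weights are invariant to stacking respondent copies", {
  set.seed(3)
  A <- matrix(sample(1:5, 30, TRUE), 6, 5)
  w1 <- normalized_raw_weights(pm_from_matrix(A))
  w3 <- normalized_raw_weights(pm_from_matrix(rbind(A, A, A)))
  expect_equal(w1$raw_fractions, w3$raw_fractions)
  expect_equal(w1$percentages, w3$percentages)
})

test_that("criteria rank by descending median, mean as tie-break", {
  # medians (5,4,4,3,2); the two median-4 criteria split on means 4.4 vs 4.1
  A <- rbind(c(5, 5, 4, 3, 2),
             c(5, 4, 4, 3, 2),
             c(5, 5, 4, 3, 2),
             c(5, 4, 4, 3, 2),
             c(5, 4, 5, 3, 2),
             c(5, 4, 4, 3, 2),
             c(5, 5, 4, 3, 2),
             c(5, 4, 4, 3, 2),
             c(5, 5, 5, 3, 2),
             c(5, 4, 4, 3, 2))
  # col2 mean 4.4? col2: mean of (5,4,5,4,4,4,5,4,5,4) = 4.4; col3 mean 4.2
  pm <- pm_from_matrix(A)
  r <- rank_criteria(pm)
  expect_equal(r$order[1:3], c("Scale", "HFE", "CE"))
  expect_equal(r$rank_keys$median[1], 5)

  # total tie -> declaration order, flagged
  pm_tie <- pm_from_matrix(matrix(4L, 3, 5))
  r_tie <- suppressMessages(rank_criteria(pm_tie))
  expect_equal(r_tie$order, criterion_set()$labels)
  expect_true(r_tie$tied)

  # the study-profile matrix reproduces its intended ordering
  r_prof <- rank_criteria(profiled_pm())
  expect_equal(r_prof$order,
               c("Scale", "HFE", "Multimorbidity", "Equity", "CE"))
})

test_that("ROC weights match the centroid formula and round to 46/26/15/9/4", {
  w5 <- roc_raw_weights(5)
  expect_equal(unname(w5$raw_fractions),
               c(0.456667, 0.256667, 0.156667, 0.09, 0.04),
               tolerance = 1e-5)
  expect_equal(unname(w5$percentages), c(46L, 26L, 15L, 9L, 4L))
  # closed-form checks: last rank = 1/n^2, strict decrease, exact unit sum
  expect_equal(unname(w5$raw_fractions)[5], 1 / 25)
  expect_true(all(diff(unname(w5$raw_fractions)) < 0))
  expect_equal(sum(w5$raw_fractions), 1)

  expect_equal(unname(roc_raw_weights(1)$raw_fractions), 1)
  expect_equal(unname(roc_raw_weights(2)$raw_fractions), c(0.75, 0.25))

  # via a survey: fractions attach to criteria in rank order
  r <- rank_criteria(profiled_pm())
  w <- roc_raw_weights(r)
  expect_equal(unname(w$percentages[r$order]), c(46L, 26L, 15L, 9L, 4L))
  expect_equal(unname(w$percentages["CE"]), 4L)
})

test_that("Hare-Niemeyer rounding: floors plus largest remainders", {
  expect_equal(hare_niemeyer_round(c(0.5, 0.5)), c(50L, 50L))
  expect_equal(hare_niemeyer_round(rep(1, 3) / 3), c(34L, 33L, 33L))
  expect_equal(hare_niemeyer_round(c(0.456667, 0.256667, 0.156667, 0.09, 0.04)),
               c(46L, 26L, 15L, 9L, 4L))
  # tie order redirects the remainder seat
  expect_equal(hare_niemeyer_round(rep(1, 3) / 3, tie_order = c(3, 2, 1)),
               c(33L, 33L, 34L))
  expect_error(hare_niemeyer_round(c(0.5, 0.4)), "sum to 1")
})

test_that("rounded percentages sum to 100 and sit within 1 of their quota", {
  set.seed(99)
  for (i in 1:200) {
    q <- sample(2:8, 1)
    fr <- as.numeric(rmultinom(1, 1000, runif(q))) / 1000
    pct <- hare_niemeyer_round(fr)
    expect_identical(sum(pct), 100L)
    expect_true(all(abs(pct - 100 * fr) < 1))
  }
})

test_that("compute_weights orchestrates methods and stratification", {
  pm_u <- pm_from_matrix(matrix(4L, 6, 5))
  w_norm <- suppressMessages(compute_weights(pm_u, "normalized"))
  expect_equal(unname(w_norm$pooled$percentages), rep(20L, 5))
  w_eq <- suppressMessages(compute_weights(pm_u, "equal"))
  expect_equal(unname(w_eq$pooled$percentages), rep(20L, 5))
  w_roc <- suppressMessages(compute_weights(profiled_pm(), "roc"))
  expect_setequal(unname(w_roc$pooled$percentages), c(46L, 26L, 15L, 9L, 4L))

  # stratification: group b's Equity shifted far below group a's
  A <- rbind(matrix(5L, 10, 5),
             cbind(matrix(5L, 10, 4), matrix(2L, 10, 1)))
  eth <- rep(c("a", "b"), each = 10)
  ws <- suppressMessages(compute_weights(pm_from_matrix(A, ethnicity = eth),
                                         "normalized", by = eth))
  expect_true(attr(ws, "stratified"))
  expect_setequal(names(ws), c("a", "b"))
  expect_equal(unname(ws$a$percentages), rep(20L, 5))

  # identical groups pool
  wp <- suppressMessages(compute_weights(pm_from_matrix(rbind(A, A)),
                                         "normalized",
                                         by = rep(c("x", "y"), 20)))
  expect_false(attr(wp, "stratified"))
  expect_named(wp, "pooled")
})
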