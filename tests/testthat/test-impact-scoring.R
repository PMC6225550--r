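test_that("DALY banding is closed on the left (>= / <)", {
  expect_equal(daly_level(5.0), 5L)
  expect_equal(daly_level(3.0), 4L)
  expect_equal(daly_level(2.999), 3L)
  expect_equal(daly_level(0), 1L)
  expect_equal(daly_level(c(0.99, 1, 1.99, 2, 4.99)), c(1L, 2L, 2L, 3L, 4L))
  expect_error(daly_level(-0.1), "0, 100")
})

test_that("HFE banding is open on the left, closed on the right (> / <=)", {
  expect_equal(hfe_level(5092), 5L)
  expect_equal(hfe_level(5091), 4L)
  expect_equal(hfe_level(1735), 2L)
  expect_equal(hfe_level(1736), 3L)
  expect_equal(hfe_level(c(0, 750, 751, 2789, 2790)), c(1L, 1L, 2L, 3L, 4L))
  expect_error(hfe_level(-1), "non-negative")
})

test_that("CE banding decreases in ICER", {
  expect_equal(ce_level(5000), 5L)
  expect_equal(ce_level(10000), 4L)
  expect_equal(ce_level(25001), 1L)
  expect_equal(ce_level(c(1, 5001, 20000, 20001, 25000)),
               c(5L, 4L, 3L, 2L, 2L))
  expect_error(ce_level(0), "positive")
  expect_error(ce_level(-100), "positive")
})

test_that("rate-ratio banding shared by ethnicity, gender, multimorbidity", {
  expect_equal(ratio_level(2.01), 5L)
  expect_equal(ratio_level(2.00), 4L)
  expect_equal(ratio_level(1.50), 3L)
  expect_equal(ratio_level(1.11), 1L)
  expect_equal(ratio_level(c(0.5, 1.12, 1.26, 1.27, 1.51, 1.52)),
               c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_error(ratio_level(0), "positive")
})

test_that("level maps are exhaustive and monotone across their breakpoints", {
  eps <- c(-1e-6, 0, 1e-6)
  scan <- function(f, breaks, lo, hi) {
    xs <- sort(unique(pmax(lo, pmin(hi, c(outer(breaks, eps, `+`),
                                          seq(lo, hi, length.out = 200))))))
    lv <- f(xs)
    expect_true(all(lv %in% 1:5))            # exhaustive, no gaps
    lv
  }
  expect_true(all(diff(scan(daly_level, c(1, 2, 3, 5), 0, 8)) >= 0))
  expect_true(all(diff(scan(hfe_level, c(750, 1735, 2789, 5091), 0, 8000)) >= 0))
  expect_true(all(diff(scan(ce_level, c(5000, 10000, 20000, 25000),
                            1, 40000)) <= 0))
  expect_true(all(diff(scan(ratio_level, c(1.11, 1.26, 1.51, 2), 0.01, 3)) >= 0))
})

test_that("equity score weights ethnicity 2:1 over gender", {
  expect_equal(equity_score(5, 2), 4)
  expect_equal(equity_score(3, 3), 3)
  expect_equal(equity_score(1, 5), 7 / 3)
  # linear, bounded, fixed point on the diagonal
  for (e in 1:5) for (g in 1:5) {
    s <- equity_score(e, g)
    expect_true(s >= 1 && s <= 5)
    if (e == g) expect_equal(s, e)
  }
  expect_error(equity_score(0, 3), "1..5")
  expect_error(equity_score(3, 5.5), "1..5")
})

test_that("multimorbidity HR is a prevalence-weighted geometric aggregate", {
  expect_equal(multimorbidity_hr(1.8, 0.37), 1.8)
  expect_equal(multimorbidity_hr(c(2, 0.5), c(0.5, 0.5)), 1)
  expect_equal(multimorbidity_hr(c(4, 1), c(1, 1)), 2)
  # scale invariance in the weights; equal weights = geometric mean
  set.seed(5)
  hr <- runif(4, 0.5, 3); w <- runif(4, 0.1, 2)
  expect_equal(multimorbidity_hr(hr, w), multimorbidity_hr(hr, 7.3 * w))
  expect_equal(multimorbidity_hr(hr, rep(1, 4)), exp(mean(log(hr))))
  expect_error(multimorbidity_hr(numeric(0), numeric(0)), "at least one")
  expect_error(multimorbidity_hr(c(1, -2), c(1, 1)), "positive")
})

test_that("impact matrix assembly composes the five maps, with overrides", {
  ind <- data.frame(condition = "c1", daly_share = 5.5,
                    income_loss_nzd = 6000, icer_nzd_per_qaly = 4000,
                    ethnicity_ratio = 2.1, gender_ratio = 1.0,
                    multimorbidity_hr = 1.9)
  im <- build_impact_matrix(ind)
  expect_equal(unname(im$levels["c1", ]),
               c(5, 5, 5, (2 / 3) * 5 + (1 / 3) * 1, 4))

  # minimal bands everywhere
  ind_min <- data.frame(condition = "low", daly_share = 0.2,
                        income_loss_nzd = 100, icer_nzd_per_qaly = 30000,
                        ethnicity_ratio = 1.0, gender_ratio = 1.0,
                        multimorbidity_hr = 1.0)
  expect_equal(unname(build_impact_matrix(ind_min)$levels["low", ]),
               rep(1, 5))

  # overrides win and are flagged; missing cells without override reject
  ind_gap <- data.frame(condition = "g", daly_share = 2.5,
                        income_loss_nzd = 800, icer_nzd_per_qaly = 12000,
                        multimorbidity_hr = 1.3)
  expect_error(build_impact_matrix(ind_gap), "g/Equity")
  im_o <- build_impact_matrix(
    ind_gap, overrides = data.frame(condition = "g", criterion = "Equity",
                                    level = 5))
  expect_equal(unname(im_o$levels["g", "Equity"]), 5)
  expect_equal(unname(im_o$provenance["g", "Equity"]), "user")

  # comorbidity terms aggregate when no direct HR is given
  ind_cm <- data.frame(condition = "cm", daly_share = 1.5,
                       income_loss_nzd = 2000, icer_nzd_per_qaly = 8000,
                       ethnicity_ratio = 1.4, gender_ratio = 1.2)
  cm <- data.frame(condition = "cm", comorbidity = c("x", "y"),
                   hazard_ratio = c(4, 1), prevalence_weight = c(1, 1))
  im_cm <- build_impact_matrix(ind_cm, comorbidities = cm)
  expect_equal(unname(im_cm$levels["cm", "Multimorbidity"]),
               as.numeric(ratio_level(2)))
})
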