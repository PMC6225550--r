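test_that("Porter stemmer reproduces known reference stems", {
  pairs <- c(hypertension = "hypertens", hypertensive = "hypertens",
             disease = "diseas", diseases = "diseas", diabetes = "diabet",
             cancers = "cancer", cancer = "cancer", caresses = "caress",
             ponies = "poni", cats = "cat", motoring = "motor",
             hopping = "hop", hoping = "hope", happy = "happi", sky = "sky",
             relational = "relat", agreed = "agre", feed = "feed",
             controlling = "control", conditional = "condit",
             troubled = "troubl", sized = "size", filing = "file")
  expect_equal(porter_stem(names(pairs)), unname(pairs))
  # short words pass through
  expect_equal(porter_stem(c("a", "is", "flu")), c("a", "is", "flu"))
})

test_that("stemming is idempotent on its own output for the test vocabulary", {
  words <- c("cancers", "asthmatic", "strokes", "worried", "smoking",
             "hearts", "mental", "motoring", "diabetes", "happy")
  s1 <- porter_stem(words)
  expect_equal(porter_stem(s1), s1)
})

test_that("text preprocessing lowercases, strips punctuation, drops stopwords", {
  expect_equal(preprocess_text("hypertension and hypertensive disease")[[1]],
               c("hypertens", "hypertens", "diseas"))
  expect_equal(preprocess_text("the a and")[[1]], character(0))
  expect_equal(preprocess_text("")[[1]], character(0))
  expect_equal(preprocess_text(NA)[[1]], character(0))
  # hyphens separate; punctuation vanishes
  expect_equal(preprocess_text("Heart-disease, cancer!")[[1]],
               c("heart", "diseas", "cancer"))
})

test_that("term-document matrix is binary with per-respondent dedup", {
  td <- build_tdm(c("heart attack, heart disease", "diabetes", ""))
  expect_true(all(td$incidence %in% 0:1))
  expect_equal(unname(td$row_sums["heart"]), 1L)     # repeated word, one count
  expect_equal(sum(td$incidence[, 3]), 0L)           # empty text, zero column
  expect_equal(td$n_respondents, 3L)

  td2 <- build_tdm(c("diabetes", "diabetic diet"))
  expect_equal(unname(td2$row_sums["diabet"]), 2L)   # independent columns

  # row sums equal row totals, bounded by respondent count
  expect_equal(unname(td$row_sums), unname(rowSums(td$incidence)))
  expect_true(all(td$row_sums <= td$n_respondents))
  expect_equal(sum(td$incidence), sum(td$row_sums))
})

test_that("top concerns sort by count then alphabetically, truncate to k", {
  td <- build_tdm(c("heart cancer pain", "heart cancer", "heart pain",
                    "heart", "cancer"))
  top2 <- top_concerns(td, 2)
  expect_equal(top2$stem, c("heart", "cancer"))
  expect_equal(top2$count, c(4L, 3L))
  # tie at count: alphabetical
  td_tie <- build_tdm(c("zebra apple", "zebra apple"))
  expect_equal(top_concerns(td_tie, 2)$stem[1], "appl")
  expect_message(full <- top_concerns(td_tie, 50), "vocabulary")
  expect_equal(nrow(full), 2L)
})

test_that("known generating frequencies are recovered from a synthetic corpus", {
  spec <- survey_generator_spec(
    n_respondents = 500,
    concern_probs = c("heart disease" = 0.5, "cancer" = 0.3,
                      "diabetes" = 0.2),
    concerns_per_respondent = 1L, seed = 404L)
  sv <- generate_survey(spec)
  td <- build_tdm(sv$free_text)
  tc <- top_concerns(td, nrow(td$incidence))
  counts <- setNames(tc$count, tc$stem)[c("heart", "cancer", "diabet")]
  # empirical frequency order matches the generating probability order
  expect_true(all(diff(counts) < 0))
  expect_equal(unname(counts["heart"]) / 500, 0.5, tolerance = 0.15)
})

test_that("ranking comparison counts respondents per condition stem set", {
  lex <- list("Heart disease" = c("heart", "cardiac"),
              "Diabetes" = "diabetes",
              "COPD" = "copd")
  L <- rbind(c(5, 5, 5, 5, 5), c(3, 3, 3, 3, 3), c(1, 1, 1, 1, 1))
  crit <- criterion_set()
  dimnames(L) <- list(c("Heart disease", "Diabetes", "COPD"), crit$labels)
  im <- structure(list(conditions = rownames(L), levels = L,
                       provenance = matrix("user", 3, 5, dimnames = dimnames(L)),
                       criteria = crit), class = "impact_matrix")
  cr <- rank_conditions(im, weight_vector(crit, rep(0.2, 5)))
  td <- build_tdm(c("heart heart cardiac", "diabetes", "heart", "diabetes",
                    "diabetes pain"))
  cmp <- compare_rankings(cr, td, lex)
  expect_equal(cmp$freetext_count[cmp$condition == "Heart disease"], 2L)
  expect_equal(cmp$freetext_count[cmp$condition == "Diabetes"], 3L)
  # never-mentioned condition: no rank, flagged
  copd <- cmp[cmp$condition == "COPD", ]
  expect_true(is.na(copd$freetext_rank))
  expect_false(copd$mentioned)
  expect_error(compare_rankings(cr, td, list()), "empty")

  # single condition / single respondent: rank 1 on both sides
  im1 <- structure(list(conditions = "Diabetes",
                        levels = L["Diabetes", , drop = FALSE],
                        provenance = matrix("user", 1, 5),
                        criteria = crit), class = "impact_matrix")
  cr1 <- rank_conditions(im1, weight_vector(crit, rep(0.2, 5)))
  cmp1 <- compare_rankings(cr1, build_tdm("diabetes runs in my family"), lex)
  expect_equal(cmp1$algorithm_rank, 1L)
  expect_equal(cmp1$freetext_rank, 1L)
})

test_that("an adversarial corpus yields rank correlation -1", {
  conds <- c("Alpha", "Bravo", "Charlie", "Delta", "Echo")
  lex <- setNames(as.list(c("alphaterm", "bravoterm", "charlieterm",
                            "deltaterm", "echoterm")), conds)
  L <- cbind(5:1, 5:1, 5:1, 5:1, 5:1)  # algorithm order Alpha > ... > Echo
  crit <- criterion_set()
  dimnames(L) <- list(conds, crit$labels)
  im <- structure(list(conditions = conds, levels = L,
                       provenance = matrix("user", 5, 5, dimnames = dimnames(L)),
                       criteria = crit), class = "impact_matrix")
  cr <- rank_conditions(im, weight_vector(crit, rep(0.2, 5)))
  # mention frequency reversed: Echo most often, Alpha once
  texts <- unlist(lapply(1:5, function(i)
    rep(c("alphaterm", "bravoterm", "charlieterm", "deltaterm",
          "echoterm")[i], i)))
  cmp <- compare_rankings(cr, build_tdm(texts), lex)
  expect_equal(attr(cmp, "rank_correlation"), -1)
  # repeating a word within one respondent does not change counts
  texts2 <- c(texts, "echoterm echoterm echoterm")
  cmp2 <- compare_rankings(cr, build_tdm(texts2), lex)
  expect_equal(cmp2$freetext_count[cmp2$condition == "Echo"],
               cmp$freetext_count[cmp$condition == "Echo"] + 1L)
})
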