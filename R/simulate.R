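#' Categorical score distribution with a target mean
#'
#' Builds a probability vector over scores 1..5 with expectation exactly
#' `mean`: mass is split between the two scores adjacent to the target, with
#' an optional uniform tail (default 5 percent) spread over all five levels
#' to give realistic dispersion; the adjacent-point mass is re-solved so the
#' overall mean is preserved. Targets too close to the ends of the scale fall
#' back to the pure two-point form.
#'
#' @param mean target mean in [1, 5].
#' @param tail fraction of mass spread uniformly over the five levels.
#' @return Numeric vector of 5 probabilities summing to 1.
#' @export
#' @examples
#' sum(score_distribution(4.6) * (1:5))  # 4.6
score_distribution <- function(mean, tail = 0.05) {
  stopifnot(mean >= 1, mean <= 5, tail >= 0, tail < 1)
  two_point <- function(m) {
    lo <- min(floor(m), 4); hi <- lo + 1
    p <- numeric(5); p[hi] <- m - lo; p[lo] <- 1 - (m - lo)
    p
  }
  m_adj <- (mean - 3 * tail) / (1 - tail)
  if (tail > 0 && m_adj >= 1 && m_adj <= 5)
    (1 - tail) * two_point(m_adj) + tail * rep(0.2, 5)
  else two_point(mean)
}

.default_score_means <- function() {
  # per-subgroup target means on the 1-5 importance scale; the Maori profile
  # sits uniformly higher, most markedly for Equity (4.6 vs 4.2) and CE
  list(
    "non-Maori" = c(Scale = 4.6, HFE = 4.6, CE = 3.6, Equity = 4.2,
                    Multimorbidity = 4.5),
    "Maori" = c(Scale = 4.7, HFE = 4.7, CE = 3.8, Equity = 4.6,
                Multimorbidity = 4.6)
  )
}

.default_concern_probs <- function() {
  c("heart disease" = 0.30, "cancer" = 0.24, "diabetes" = 0.14,
    "mental health" = 0.08, "stroke" = 0.07, "asthma" = 0.06,
    "obesity" = 0.05, "arthritis" = 0.04, "hypertension" = 0.02)
}

#' Specify a synthetic ordered-choice survey
#'
#' Declares the generating conditions of a synthetic survey: respondent
#' count, subgroup mix, per-subgroup per-criterion score distributions over
#' 1..5, free-text concern probabilities, and the root seed. Defaults emulate
#' the observed study conditions: a two-level ethnicity mix (83.3 percent /
#' 16.7 percent), subgroup preference shifts concentrated on Equity
#' (means 4.6 vs 4.2) and CE, and a concern vocabulary led by heart disease,
#' cancer, and diabetes.
#'
#' @param n_respondents number of respondents, >= 1.
#' @param subgroup_fractions named fractions over subgroup labels, sum 1.
#' @param score_means named list: subgroup -> named numeric vector of target
#'   means per criterion (converted via [score_distribution()]), or
#' @param score_dists named list: subgroup -> criterion -> 5-probability
#'   vector, overriding `score_means` when supplied.
#' @param concern_probs named probabilities over concern phrases, sum 1.
#' @param concerns_per_respondent how many distinct concerns each respondent
#'   lists (default 3).
#' @param criteria a [criterion_set()].
#' @param seed integer root seed.
#' @return `survey_generator_spec` object.
#' @export
survey_generator_spec <- function(n_respondents = 800,
                                  subgroup_fractions = c("non-Maori" = 0.833,
                                                         "Maori" = 0.167),
                                  score_means = .default_score_means(),
                                  score_dists = NULL,
                                  concern_probs = .default_concern_probs(),
                                  concerns_per_respondent = 3L,
                                  criteria = criterion_set(),
                                  seed = 1L) {
  stopifnot(n_respondents >= 1)
  if (abs(sum(subgroup_fractions) - 1) > 1e-9)
    stop("subgroup_fractions must sum to 1", call. = FALSE)
  if (abs(sum(concern_probs) - 1) > 1e-9)
    stop("concern_probs must sum to 1", call. = FALSE)
  if (is.null(score_dists)) {
    score_dists <- lapply(score_means, function(mv) {
      lapply(setNames(criteria$labels, criteria$labels), function(cl) {
        if (!cl %in% names(mv))
          stop("score_means lacks criterion ", cl, call. = FALSE)
        score_distribution(mv[[cl]])
      })
    })
  }
  for (grp in names(score_dists)) for (cl in names(score_dists[[grp]])) {
    p <- score_dists[[grp]][[cl]]
    if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("score distribution for ", grp, "/", cl,
           " is not a 5-point probability vector", call. = FALSE)
  }
  if (!setequal(names(score_dists), names(subgroup_fractions)))
    stop("score distributions must cover exactly the subgroups", call. = FALSE)
  structure(list(n_respondents = as.integer(n_respondents),
                 subgroup_fractions = subgroup_fractions,
                 score_dists = score_dists,
                 concern_probs = concern_probs,
                 concerns_per_respondent = as.integer(concerns_per_respondent),
                 criteria = criteria, seed = as.integer(seed)),
            class = "survey_generator_spec")
}

# filler vocabulary; includes stopwords so tokenizer paths are exercised
.noise_words <- c("i", "am", "worried", "about", "my", "family", "getting",
                  "older", "and", "the", "health", "of", "people")

#' Generate a synthetic survey
#'
#' Draws a survey table from a [survey_generator_spec()]: subgroup membership
#' multinomial around the requested fractions, answers i.i.d. from the
#' subgroup's per-criterion distribution, and free text assembled from
#' sampled concern phrases plus filler words. Fully deterministic given the
#' spec's seed.
#'
#' @param spec a [survey_generator_spec()].
#' @return data.frame in the survey CSV schema (`respondent_id`, `gender`,
#'   `age_band`, `education`, `ethnicity`, one lowercase answer column per
#'   criterion, `free_text`), with the generating subgroup recorded in
#'   `ethnicity`.
#' @export
generate_survey <- function(spec) {
  stopifnot(inherits(spec, "survey_generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_respondents
  groups <- sample(names(spec$subgroup_fractions), n, replace = TRUE,
                   prob = spec$subgroup_fractions)
  A <- matrix(NA_integer_, n, spec$criteria$Q,
              dimnames = list(NULL, tolower(spec$criteria$labels)))
  for (grp in names(spec$score_dists)) {
    rows <- which(groups == grp)
    if (!length(rows)) next
    for (j in seq_len(spec$criteria$Q)) {
      p <- spec$score_dists[[grp]][[spec$criteria$labels[j]]]
      A[rows, j] <- sample.int(5L, length(rows), replace = TRUE, prob = p)
    }
  }
  free_text <- vapply(seq_len(n), function(i) {
    k <- min(spec$concerns_per_respondent, length(spec$concern_probs))
    concerns <- sample(names(spec$concern_probs), k, replace = FALSE,
                       prob = spec$concern_probs)
    noise <- sample(.noise_words, 3L, replace = TRUE)
    paste(c(paste(noise, collapse = " "),
            paste(concerns, collapse = ", ")), collapse = " ")
  }, character(1))
  out <- data.frame(
    respondent_id = sprintf("R%04d", seq_len(n)),
    gender = sample(c("Female", "Male", "Other/declined"), n, replace = TRUE,
                    prob = c(0.643, 0.351, 0.006)),
    age_band = sample(c("18-29", "30-49", "50-69", "70+"), n, replace = TRUE,
                      prob = c(0.072, 0.208, 0.450, 0.270)),
    education = sample(c("Secondary school", "Vocational school",
                         "College/university or higher"), n, replace = TRUE,
                       prob = c(0.34, 0.10, 0.56)),
    ethnicity = groups,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(A))
  out$free_text <- free_text
  out
}

#' Specify a synthetic indicator table
#'
#' Declares sampling ranges for each burden indicator such that every 1-5
#' level band can be hit, plus the root seed.
#'
#' @param n_conditions number of conditions to generate.
#' @param seed integer root seed.
#' @return `indicator_generator_spec` object.
#' @export
indicator_generator_spec <- function(n_conditions = 25L, seed = 1L) {
  stopifnot(n_conditions >= 1)
  structure(list(n_conditions = as.integer(n_conditions),
                 seed = as.integer(seed)),
            class = "indicator_generator_spec")
}

# sampling ranges per level band, strictly interior to each band so the
# mapped level is unambiguous under either boundary dialect
.band_ranges <- list(
  daly = rbind(c(0.05, 0.95), c(1.05, 1.95), c(2.05, 2.95),
               c(3.05, 4.95), c(5.05, 8.00)),
  hfe = rbind(c(10, 740), c(760, 1725), c(1745, 2779),
              c(2799, 5081), c(5101, 9000)),
  ce = rbind(c(25100, 40000), c(20100, 24900), c(10100, 19900),
             c(5100, 9900), c(100, 4900)),
  ratio = rbind(c(0.30, 1.10), c(1.12, 1.25), c(1.27, 1.50),
                c(1.52, 1.99), c(2.01, 3.00))
)

#' Generate synthetic condition indicators with known ground-truth levels
#'
#' For each condition and indicator, samples a target level uniformly from
#' 1..5 and then a raw indicator value strictly inside that level's band, so
#' the mapped level is known by construction. Deterministic given the seed.
#'
#' @param spec an [indicator_generator_spec()].
#' @return List with `indicators` (data.frame in the indicator CSV schema)
#'   and `truth` (data.frame of the generating levels per criterion,
#'   including the combined fractional Equity score).
#' @export
generate_indicators <- function(spec) {
  stopifnot(inherits(spec, "indicator_generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_conditions
  conds <- sprintf("condition_%02d", seq_len(n))
  draw <- function(kind) {
    lv <- sample.int(5L, n, replace = TRUE)
    val <- vapply(lv, function(l) {
      r <- .band_ranges[[kind]][l, ]
      stats::runif(1, r[1], r[2])
    }, numeric(1))
    list(level = lv, value = val)
  }
  daly <- draw("daly"); hfe <- draw("hfe"); ce <- draw("ce")
  eth <- draw("ratio"); gen <- draw("ratio"); mm <- draw("ratio")
  indicators <- data.frame(
    condition = conds,
    daly_share = daly$value,
    income_loss_nzd = hfe$value,
    icer_nzd_per_qaly = ce$value,
    ethnicity_ratio = eth$value,
    gender_ratio = gen$value,
    multimorbidity_hr = mm$value,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    condition = conds,
    Scale = daly$level, HFE = hfe$level, CE = ce$level,
    ethnicity_level = eth$level, gender_level = gen$level,
    Equity = equity_score(eth$level, gen$level),
    Multimorbidity = mm$level,
    stringsAsFactors = FALSE
  )
  list(indicators = indicators, truth = truth)
}
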