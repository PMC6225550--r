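#' Map DALY share to the scale-of-disease impact level
#'
#' Bands a condition's share of total national DALYs (percent) into levels
#' 1-5, closed on the left: >= 5 -> 5, [3, 5) -> 4, [2, 3) -> 3, [1, 2) -> 2,
#' [0, 1) -> 1.
#'
#' @param daly_share numeric percent in [0, 100].
#' @return Integer level(s) 1-5.
#' @export
#' @examples
#' daly_level(c(0.4, 2.999, 3, 5))
daly_level <- function(daly_share) {
  x <- as.numeric(daly_share)
  if (any(!is.na(x) & (x < 0 | x > 100)))
    stop("daly_share must lie in [0, 100] percent", call. = FALSE)
  ifelse(x >= 5, 5L, ifelse(x >= 3, 4L, ifelse(x >= 2, 3L,
         ifelse(x >= 1, 2L, 1L))))
}

#' Map diminished annual income to the household-financial-effect level
#'
#' Bands the decrease in annual personal income (NZD/year, median earner)
#' into levels 1-5, open on the left and closed on the right:
#' > 5091 -> 5, (2789, 5091] -> 4, (1735, 2789] -> 3, (750, 1735] -> 2,
#' [0, 750] -> 1.
#'
#' @param income_loss numeric NZD per year, >= 0.
#' @return Integer level(s) 1-5.
#' @export
hfe_level <- function(income_loss) {
  x <- as.numeric(income_loss)
  if (any(!is.na(x) & x < 0))
    stop("income_loss must be non-negative", call. = FALSE)
  ifelse(x > 5091, 5L, ifelse(x > 2789, 4L, ifelse(x > 1735, 3L,
         ifelse(x > 750, 2L, 1L))))
}

#' Map ICER (cost per QALY) to the cost-effectiveness level
#'
#' Bands the incremental cost-effectiveness ratio (NZD per QALY, vs no
#' treatment) into levels 1-5, decreasing in cost: (0, 5000] -> 5,
#' (5000, 10000] -> 4, (10000, 20000] -> 3, (20000, 25000] -> 2,
#' > 25000 -> 1. More cost-effective interventions score higher.
#'
#' @param icer numeric NZD/QALY, strictly positive (enter dominant
#'   interventions as a small positive cost).
#' @return Integer level(s) 1-5.
#' @export
ce_level <- function(icer) {
  x <- as.numeric(icer)
  if (any(!is.na(x) & x <= 0))
    stop("icer must be positive; enter cost-saving (dominant) interventions ",
         "as a small positive value", call. = FALSE)
  ifelse(x <= 5000, 5L, ifelse(x <= 10000, 4L, ifelse(x <= 20000, 3L,
         ifelse(x <= 25000, 2L, 1L))))
}

#' Map a rate ratio or hazard ratio to an impact level
#'
#' Shared banding for ethnicity rate ratios, gender rate ratios, and
#' multimorbidity mortality hazard ratios: > 2.00 -> 5, (1.51, 2.00] -> 4,
#' (1.26, 1.51] -> 3, (1.11, 1.26] -> 2, (0, 1.11] -> 1.
#'
#' @param ratio positive dimensionless ratio(s).
#' @return Integer level(s) 1-5.
#' @export
ratio_level <- function(ratio) {
  x <- as.numeric(ratio)
  if (any(!is.na(x) & x <= 0))
    stop("ratio must be positive", call. = FALSE)
  ifelse(x > 2, 5L, ifelse(x > 1.51, 4L, ifelse(x > 1.26, 3L,
         ifelse(x > 1.11, 2L, 1L))))
}

#' Combine ethnicity and gender levels into the equity impact score
#'
#' Weights the ethnicity burden-of-disease level twice as heavily as the
#' gender level: `score = (2/3) * ethnicity + (1/3) * gender`. The result may
#' be fractional (thirds) and is not re-rounded.
#'
#' @param ethnicity_level,gender_level integer levels in 1..5.
#' @return Numeric score(s) in [1, 5].
#' @export
#' @examples
#' equity_score(5, 2)  # 4
equity_score <- function(ethnicity_level, gender_level) {
  e <- as.numeric(ethnicity_level); g <- as.numeric(gender_level)
  ok <- function(v) all(is.na(v) | (v %in% 1:5))
  if (!ok(e) || !ok(g))
    stop("equity sub-criterion levels must be integers in 1..5", call. = FALSE)
  (2 / 3) * e + (1 / 3) * g
}

#' Aggregate comorbidity hazard ratios into one multimorbidity HR
#'
#' Prevalence-weighted geometric aggregation of per-comorbidity 1-year
#' mortality hazard ratios: weights are renormalized to sum to 1 and the HR is
#' `exp(sum(w * log(HR)))`. With equal weights this is the geometric mean;
#' multiplying all weights by a constant leaves the result unchanged.
#'
#' @param hazard_ratio positive numeric vector of comorbidity HRs.
#' @param prevalence_weight positive numeric weights, same length.
#' @return A single positive hazard ratio.
#' @export
#' @examples
#' multimorbidity_hr(c(4, 1), c(1, 1))  # 2
multimorbidity_hr <- function(hazard_ratio, prevalence_weight) {
  hr <- as.numeric(hazard_ratio); w <- as.numeric(prevalence_weight)
  if (length(hr) == 0L) stop("need at least one comorbidity term", call. = FALSE)
  if (length(hr) != length(w))
    stop("hazard_ratio and prevalence_weight must align", call. = FALSE)
  if (any(hr <= 0) || any(w <= 0))
    stop("hazard ratios and prevalence weights must be positive", call. = FALSE)
  exp(sum(w / sum(w) * log(hr)))
}

#' Assemble the conditions x criteria impact matrix
#'
#' Maps raw indicators to levels per criterion: Scale from DALY share, HFE
#' from income loss, CE from ICER, Equity from the 2:1 ethnicity/gender rate
#' ratio combination, and Multimorbidity from the (possibly aggregated)
#' mortality hazard ratio. User-supplied overrides win over mapped values and
#' are flagged in the provenance matrix.
#'
#' @param indicators data.frame with columns `condition` and any of
#'   `daly_share`, `income_loss_nzd`, `icer_nzd_per_qaly`, `ethnicity_ratio`,
#'   `gender_ratio`, `multimorbidity_hr` (NA = not supplied).
#' @param comorbidities optional long data.frame `condition`, `comorbidity`,
#'   `hazard_ratio`, `prevalence_weight`; aggregated via
#'   [multimorbidity_hr()] for conditions whose direct `multimorbidity_hr`
#'   is missing.
#' @param overrides optional data.frame `condition`, `criterion`, `level`
#'   supplying cells directly (levels in [1, 5]).
#' @param criteria a [criterion_set()] (the default five).
#' @return `impact_matrix` object: `conditions`, `levels` (numeric matrix,
#'   integer-valued except the Equity column), `provenance` (character matrix,
#'   "indicator" or "user").
#' @export
build_impact_matrix <- function(indicators, comorbidities = NULL,
                                overrides = NULL,
                                criteria = criterion_set()) {
  stopifnot(is.data.frame(indicators), "condition" %in% names(indicators))
  conds <- as.character(indicators$condition)
  if (anyDuplicated(conds)) stop("duplicate condition names", call. = FALSE)
  n <- length(conds)
  getcol <- function(nm) if (nm %in% names(indicators))
    as.numeric(indicators[[nm]]) else rep(NA_real_, n)

  mm_hr <- getcol("multimorbidity_hr")
  if (!is.null(comorbidities)) {
    stopifnot(all(c("condition", "hazard_ratio", "prevalence_weight") %in%
                    names(comorbidities)))
    for (i in which(is.na(mm_hr))) {
      terms <- comorbidities[comorbidities$condition == conds[i], , drop = FALSE]
      if (nrow(terms) > 0)
        mm_hr[i] <- multimorbidity_hr(terms$hazard_ratio,
                                      terms$prevalence_weight)
    }
  }
  eth <- getcol("ethnicity_ratio"); gen <- getcol("gender_ratio")
  cell <- function(x, f) ifelse(is.na(x), NA_real_, f(x))

  L <- matrix(NA_real_, n, criteria$Q,
              dimnames = list(conds, criteria$labels))
  fill <- function(lab, v) if (lab %in% criteria$labels) L[, lab] <<- v
  fill("Scale", cell(getcol("daly_share"), daly_level))
  fill("HFE", cell(getcol("income_loss_nzd"), hfe_level))
  fill("CE", cell(getcol("icer_nzd_per_qaly"), ce_level))
  eq <- ifelse(is.na(eth) | is.na(gen), NA_real_,
               equity_score(ifelse(is.na(eth), 1, ratio_level(eth)),
                            ifelse(is.na(gen), 1, ratio_level(gen))))
  fill("Equity", eq)
  fill("Multimorbidity", cell(mm_hr, ratio_level))

  prov <- matrix("indicator", n, criteria$Q,
                 dimnames = dimnames(L))
  if (!is.null(overrides)) {
    stopifnot(all(c("condition", "criterion", "level") %in% names(overrides)))
    for (k in seq_len(nrow(overrides))) {
      ci <- match(as.character(overrides$condition[k]), conds)
      cj <- match(as.character(overrides$criterion[k]), criteria$labels)
      if (is.na(ci) || is.na(cj))
        stop("override ", k, " names unknown condition or criterion",
             call. = FALSE)
      lv <- as.numeric(overrides$level[k])
      if (is.na(lv) || lv < 1 || lv > 5)
        stop("override level must lie in [1, 5]", call. = FALSE)
      L[ci, cj] <- lv
      prov[ci, cj] <- "user"
    }
  }
  if (anyNA(L)) {
    gaps <- which(is.na(L), arr.ind = TRUE)
    stop("missing indicator or override for: ",
         paste(unique(paste0(rownames(L)[gaps[, 1]], "/",
                             colnames(L)[gaps[, 2]])), collapse = ", "),
         call. = FALSE)
  }
  structure(list(conditions = conds, levels = L, provenance = prov,
                 criteria = criteria),
            class = "impact_matrix")
}

#' @export
print.impact_matrix <- function(x, ...) {
  cat("Impact matrix:", length(x$conditions), "conditions x",
      x$criteria$Q, "criteria\n")
  print(round(x$levels, 2))
  invisible(x)
}
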