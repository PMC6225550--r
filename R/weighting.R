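#' Construct a weight vector object
#'
#' Container pairing per-criterion raw fractions (summing to 1) with their
#' Hare-Niemeyer integer percentages (summing to exactly 100).
#'
#' @param criteria a [criterion_set()].
#' @param raw_fractions numeric, one per criterion, summing to 1.
#' @param method one of `"normalized"`, `"roc"`, `"equal"`, `"user"`.
#' @param s optional total preference mass (the normalizing scalar of the
#'   normalized method).
#' @param group optional subgroup tag.
#' @param tie_order integer permutation giving priority for remainder seats
#'   in the rounding step (defaults to declaration order).
#' @return `weight_vector` object with fields `criteria`, `raw_fractions`
#'   (named), `percentages` (named integers), `method`, `s`, `group`.
#' @export
weight_vector <- function(criteria, raw_fractions,
                          method = c("user", "normalized", "roc", "equal"),
                          s = NULL, group = NULL,
                          tie_order = seq_along(raw_fractions)) {
  method <- match.arg(method)
  stopifnot(inherits(criteria, "criterion_set"),
            length(raw_fractions) == criteria$Q)
  raw_fractions <- setNames(as.numeric(raw_fractions), criteria$labels)
  pct <- hare_niemeyer_round(raw_fractions, tie_order = tie_order)
  structure(list(criteria = criteria, raw_fractions = raw_fractions,
                 percentages = setNames(pct, criteria$labels),
                 method = method, s = s, group = group),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("Criterion weights (", x$method,
      if (!is.null(x$group)) paste0(", group: ", x$group), ")\n", sep = "")
  df <- data.frame(criterion = x$criteria$labels,
                   raw_fraction = round(unname(x$raw_fractions), 6),
                   percentage = unname(x$percentages))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Normalized-sum criterion weights from a preference matrix
#'
#' Sums all preference values to the scalar s, divides every entry by s, and
#' sums the normalized entries column-wise, giving each criterion the share of
#' total expressed preference mass it received.
#'
#' @param pm a preference matrix.
#' @param group optional subgroup tag carried into the result.
#' @return A [weight_vector()] with `method = "normalized"` and the scalar
#'   `s` stored.
#' @export
#' @examples
#' pm <- build_preference_matrix(
#'   data.frame(scale = c(5, 3), hfe = c(1, 1), ce = c(3, 3),
#'              equity = c(4, 4), multimorbidity = c(2, 2)))
#' normalized_raw_weights(pm)
normalized_raw_weights <- function(pm, group = NULL) {
  stopifnot(inherits(pm, "preference_matrix"))
  s <- sum(pm$values)
  fr <- colSums(pm$values) / s
  weight_vector(pm$criteria, fr, method = "normalized", s = s, group = group)
}

#' Rank criteria by importance from a preference matrix
#'
#' Criteria are ordered by descending median preference value; ties are broken
#' by descending mean, and residual exact ties by declaration order (flagged).
#' Medians of even-count columns use the midpoint convention.
#'
#' @param pm a preference matrix.
#' @return `criterion_ranking` object: `order` (labels, rank 1 first),
#'   `rank_keys` (data.frame of medians/means in rank order), `perm`
#'   (integer permutation of declaration positions), `tied` (logical).
#' @export
rank_criteria <- function(pm) {
  stopifnot(inherits(pm, "preference_matrix"))
  med <- apply(pm$values, 2, median)
  mn <- colMeans(pm$values)
  perm <- order(-med, -mn, seq_along(med))
  tied <- anyDuplicated(paste(med, mn)) > 0
  if (tied) message("exact median+mean tie between criteria; ",
                    "declaration order used")
  structure(list(order = pm$criteria$labels[perm],
                 rank_keys = data.frame(criterion = pm$criteria$labels[perm],
                                        median = med[perm], mean = mn[perm],
                                        row.names = NULL),
                 perm = perm, tied = tied, criteria = pm$criteria),
            class = "criterion_ranking")
}

#' @export
print.criterion_ranking <- function(x, ...) {
  cat("Criterion importance ranking:",
      paste(x$order, collapse = " > "), "\n")
  invisible(x)
}

#' Rank-order-centroid (SMARTER) weights
#'
#' Surrogate weights that depend only on the ordinal importance ranking of the
#' n criteria: the criterion at rank i receives
#' `(1/n) * sum(1/j for j = i..n)`, the i-th coordinate of the centroid of the
#' rank-constrained weight simplex.
#'
#' @param ranking a [rank_criteria()] result, or an integer n (criteria then
#'   labelled by rank).
#' @param group optional subgroup tag.
#' @return A [weight_vector()] with `method = "roc"`. Fractions are stored in
#'   criterion declaration order; remainder seats in the rounding step go to
#'   higher-ranked criteria.
#' @export
#' @examples
#' roc_raw_weights(5)$percentages
roc_raw_weights <- function(ranking, group = NULL) {
  if (is.numeric(ranking) && length(ranking) == 1L) {
    n <- as.integer(ranking)
    stopifnot(n >= 1L)
    if (n == 1L) {
      # degenerate single-criterion case handled without criterion_set's Q>=2
      return(structure(list(
        criteria = structure(list(labels = "rank1", Q = 1L),
                             class = "criterion_set"),
        raw_fractions = c(rank1 = 1), percentages = c(rank1 = 100L),
        method = "roc", s = NULL, group = group), class = "weight_vector"))
    }
    crit <- criterion_set(paste0("rank", seq_len(n)))
    perm <- seq_len(n)
  } else {
    stopifnot(inherits(ranking, "criterion_ranking"))
    crit <- ranking$criteria
    n <- crit$Q
    perm <- ranking$perm
  }
  w_by_rank <- vapply(seq_len(n), function(i) sum(1 / (i:n)) / n, numeric(1))
  fr <- numeric(n)
  fr[perm] <- w_by_rank           # back to declaration order
  tie_order <- order(perm)        # seat priority: rank position of each criterion
  wv <- weight_vector(crit, fr, method = "roc", group = group,
                      tie_order = tie_order)
  wv
}

#' Hare-Niemeyer (largest-remainder) rounding to integer percentages
#'
#' Rounds a fraction vector summing to 1 to non-negative integers summing to
#' exactly 100: each criterion gets `floor(100 * fraction)`, and the leftover
#' seats go to the largest fractional remainders. Equal remainders (compared
#' after rounding to 9 decimals to absorb float noise in analytically exact
#' ties) are resolved in favour of the earlier `tie_order` position.
#'
#' @param raw_fractions non-negative numeric summing to 1 (tolerance 1e-6).
#' @param tie_order integer vector; lower values win remainder ties. Defaults
#'   to input position.
#' @return Integer vector summing to 100; each element differs from
#'   `100 * raw_fractions` by strictly less than 1.
#' @export
#' @examples
#' hare_niemeyer_round(c(1, 1, 1) / 3)
hare_niemeyer_round <- function(raw_fractions,
                                tie_order = seq_along(raw_fractions)) {
  fr <- as.numeric(raw_fractions)
  if (any(fr < -1e-12)) stop("fractions must be non-negative", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-6)
    stop("fractions must sum to 1 (got ", format(sum(fr)), ")", call. = FALSE)
  quota <- 100 * fr
  fl <- floor(quota + 1e-9)       # guard against 0.199999... quotas
  r <- as.integer(round(100 - sum(fl)))
  rem <- round(quota - fl, 9)
  seat <- integer(length(fr))
  if (r > 0) {
    pick <- order(-rem, tie_order)[seq_len(r)]
    seat[pick] <- 1L
  }
  out <- as.integer(fl) + seat
  stopifnot(sum(out) == 100L)
  out
}

#' Compute aggregate criterion weights, optionally stratified by subgroup
#'
#' Orchestrates the weighting pipeline: normalized-sum, rank-order-centroid,
#' or equal weights, each finished by Hare-Niemeyer integer rounding. When a
#' two-level grouping is supplied, the per-criterion mean differences are
#' tested against the stratification threshold; if any exceeds it, one weight
#' vector per subgroup is returned, otherwise a single pooled vector.
#'
#' @param pm a preference matrix.
#' @param method `"normalized"`, `"roc"`, or `"equal"`.
#' @param by optional factor of length P with two used levels (see
#'   [subgroup_difference()]).
#' @param threshold percent threshold for the stratification rule (default 5).
#' @return A named list of [weight_vector()]s: `pooled`, or one entry per
#'   subgroup level when stratification triggers. The stratification decision
#'   is attached as attribute `stratified`.
#' @export
compute_weights <- function(pm, method = c("normalized", "roc", "equal"),
                            by = NULL, threshold = 5.0) {
  method <- match.arg(method)
  one <- function(p, group) {
    switch(method,
           normalized = normalized_raw_weights(p, group = group),
           roc = roc_raw_weights(rank_criteria(p), group = group),
           equal = weight_vector(p$criteria, rep(1 / p$criteria$Q, p$criteria$Q),
                                 method = "equal", group = group))
  }
  stratified <- FALSE
  if (!is.null(by)) {
    diffs <- subgroup_difference(pm, by)
    stratified <- isTRUE(as.logical(stratification_decision(diffs, threshold)))
  }
  if (stratified) {
    g <- as.factor(by)
    out <- lapply(levels(droplevels(g[!is.na(g)])), function(lv) {
      keep <- !is.na(g) & g == lv
      sub <- structure(list(values = pm$values[keep, , drop = FALSE],
                            respondents = pm$respondents[keep, , drop = FALSE],
                            criteria = pm$criteria, n_dropped = 0L),
                       class = "preference_matrix")
      one(sub, group = lv)
    })
    names(out) <- levels(droplevels(g[!is.na(g)]))
  } else {
    out <- list(pooled = one(pm, group = NULL))
  }
  attr(out, "stratified") <- stratified
  out
}
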