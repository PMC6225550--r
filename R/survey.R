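#' The five canonical ordered-choice scale labels
#'
#' Verbal anchors of the 5-point importance scale, in ascending order of the
#' integer score they encode (1 through 5).
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' scale_labels()
scale_labels <- function() {
  c("Not at all important", "A little important", "Important",
    "Very important", "Extremely important")
}

.normalize_label <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Encode verbal scale points as integer scores 1-5
#'
#' Bijective mapping from the five canonical verbal labels to integer scores:
#' "Not at all important" -> 1 up to "Extremely important" -> 5. Matching is
#' case- and whitespace-insensitive. Unknown labels are an error naming the
#' offending string and its position.
#'
#' @param label character vector of verbal scale points.
#' @return Integer vector of scores in 1..5 (NA maps to NA).
#' @seealso [decode_scale_point()] for the inverse.
#' @export
#' @examples
#' encode_scale_point(c("Extremely important", "important"))
encode_scale_point <- function(label) {
  canon <- .normalize_label(scale_labels())
  idx <- match(.normalize_label(as.character(label)), canon)
  bad <- which(is.na(idx) & !is.na(label))
  if (length(bad)) {
    stop("unknown scale label ", dQuote(label[bad[1]]), " at position ",
         bad[1], "; expected one of: ", paste(scale_labels(), collapse = ", "),
         call. = FALSE)
  }
  as.integer(idx)
}

#' Decode integer scores 1-5 back to verbal scale labels
#'
#' @param score integer vector with values in 1..5.
#' @return Character vector of canonical labels.
#' @export
decode_scale_point <- function(score) {
  score <- as.integer(score)
  if (any(!is.na(score) & (score < 1L | score > 5L)))
    stop("scores must lie in 1..5", call. = FALSE)
  scale_labels()[score]
}

#' Define the set of decision criteria
#'
#' Holds the ordered criterion labels used as columns of the preference and
#' impact matrices. Defaults to the five health preference criteria: scale of
#' disease (Scale), household financial effect (HFE), cost-effectiveness (CE),
#' health equity (Equity), and multimorbidity (Multimorbidity).
#'
#' @param labels character vector of unique criterion names, length >= 2.
#' @return An object of class `criterion_set` with fields `labels` and `Q`.
#' @export
#' @examples
#' criterion_set()
criterion_set <- function(labels = c("Scale", "HFE", "CE", "Equity",
                                     "Multimorbidity")) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("criterion labels must be unique", call. = FALSE)
  if (length(labels) < 2L) stop("need at least 2 criteria", call. = FALSE)
  structure(list(labels = labels, Q = length(labels)), class = "criterion_set")
}

#' @export
print.criterion_set <- function(x, ...) {
  cat("Criterion set (Q =", x$Q, "):", paste(x$labels, collapse = " > "), "\n")
  invisible(x)
}

.answer_columns <- function(survey, criteria) {
  cols <- match(tolower(criteria$labels), tolower(names(survey)))
  if (anyNA(cols)) {
    stop("survey table lacks answer column(s): ",
         paste(criteria$labels[is.na(cols)], collapse = ", "), call. = FALSE)
  }
  names(survey)[cols]
}

# Coerce one answer column to integer scores; accepts integers 1-5 or the
# verbal labels, but not a mixture within the column.
.coerce_answers <- function(x, column) {
  x <- as.character(x)
  x[!nzchar(trimws(ifelse(is.na(x), "", x)))] <- NA
  numeric_like <- grepl("^\\s*[0-9]+\\s*$", x)
  present <- !is.na(x)
  if (any(numeric_like & present) && any(!numeric_like & present))
    stop("column ", dQuote(column),
         " mixes integer and verbal answer encodings", call. = FALSE)
  if (all(numeric_like[present])) {
    v <- as.integer(x)
    if (any(present & (v < 1L | v > 5L)))
      stop("column ", dQuote(column), " has scores outside 1..5", call. = FALSE)
    v
  } else {
    encode_scale_point(x)
  }
}

#' Build the respondent-by-criterion preference matrix
#'
#' Encodes the ordered-choice answers of a survey table into the P x Q integer
#' preference matrix A with entries a_ij in 1..5: one row per retained
#' respondent, one column per criterion in declaration order.
#'
#' @param survey data.frame with one row per respondent. Must contain one
#'   answer column per criterion label (matched case-insensitively); answers
#'   may be integers 1-5 or the verbal labels. Demographic columns
#'   (`respondent_id`, `gender`, `age_band`, `education`, `ethnicity`,
#'   `free_text`) are carried along as row metadata when present.
#' @param criteria a [criterion_set()].
#' @param missing_policy `"drop_respondent"` (default) excludes any respondent
#'   with a missing answer, reporting the count via a message;
#'   `"error"` aborts naming the first offending respondent.
#' @return An object of class `preference_matrix`: list with `values`
#'   (integer matrix), `respondents` (metadata data.frame), `criteria`, and
#'   `n_dropped`.
#' @export
#' @examples
#' sv <- data.frame(scale = c(5, 4), hfe = c(4, 4), ce = c(3, 2),
#'                  equity = c(5, 5), multimorbidity = c(4, 3))
#' build_preference_matrix(sv)
build_preference_matrix <- function(survey, criteria = criterion_set(),
                                    missing_policy = c("drop_respondent", "error")) {
  missing_policy <- match.arg(missing_policy)
  if (!is.data.frame(survey) || nrow(survey) == 0L)
    stop("survey must be a non-empty data.frame", call. = FALSE)
  cols <- .answer_columns(survey, criteria)
  A <- vapply(cols, function(cn) .coerce_answers(survey[[cn]], cn),
              integer(nrow(survey)))
  A <- matrix(as.integer(A), nrow = nrow(survey),
              dimnames = list(NULL, criteria$labels))
  incomplete <- rowSums(is.na(A)) > 0L
  if (any(incomplete)) {
    if (missing_policy == "error") {
      who <- if ("respondent_id" %in% names(survey))
        survey$respondent_id[which(incomplete)[1]] else which(incomplete)[1]
      stop("respondent ", dQuote(who), " has missing answer(s)", call. = FALSE)
    }
    message(sum(incomplete), " respondent(s) dropped for missing answers")
  }
  keep <- !incomplete
  if (!any(keep)) stop("no respondents retained after applying missing policy",
                       call. = FALSE)
  meta_cols <- intersect(c("respondent_id", "gender", "age_band", "education",
                           "ethnicity", "free_text"), names(survey))
  structure(list(
    values = A[keep, , drop = FALSE],
    respondents = survey[keep, meta_cols, drop = FALSE],
    criteria = criteria,
    n_dropped = sum(incomplete)
  ), class = "preference_matrix")
}

#' @export
print.preference_matrix <- function(x, ...) {
  cat("Preference matrix: P =", nrow(x$values), "respondents, Q =",
      x$criteria$Q, "criteria\n")
  if (x$n_dropped > 0) cat("  (", x$n_dropped, "respondent(s) dropped )\n")
  print(head(x$values, 5))
  if (nrow(x$values) > 5) cat("  ...\n")
  invisible(x)
}

#' Summarize the preference profile of a survey (or a subset)
#'
#' Column-wise means, medians, and the proportion of respondents at each of
#' the five scale levels. For even respondent counts the median is the
#' midpoint of the two central order statistics.
#'
#' @param pm a [build_preference_matrix()] result.
#' @param subset optional logical or integer vector selecting respondents
#'   (rows); must retain at least one.
#' @return data.frame with one row per criterion: `criterion`, `mean`,
#'   `median`, and `p1`..`p5` (level proportions, each summing to 1).
#' @export
summarize_profile <- function(pm, subset = NULL) {
  stopifnot(inherits(pm, "preference_matrix"))
  A <- pm$values
  if (!is.null(subset)) A <- A[subset, , drop = FALSE]
  if (nrow(A) == 0L) stop("subset retains no respondents", call. = FALSE)
  props <- t(apply(A, 2, function(col) tabulate(col, nbins = 5) / length(col)))
  out <- data.frame(
    criterion = colnames(A),
    mean = colMeans(A),
    median = apply(A, 2, median),
    props,
    row.names = NULL
  )
  names(out)[4:8] <- paste0("p", 1:5)
  out
}

#' Compare preference profiles between two respondent groups
#'
#' Per criterion: group means, the percentage difference of means, and the
#' unequal-variance (Welch) two-sample t-test, two-sided. The percentage
#' difference is `100 * (mean_g1 - mean_g2) / mean_g2` computed on unrounded
#' means (the denominator group is configurable).
#'
#' @param pm a preference matrix.
#' @param groups factor (or coercible) of length P with exactly two used
#'   levels; rows with NA are excluded. The first level is g1.
#' @param denominator which group's mean divides the difference: `"g2"`
#'   (default) or `"g1"`.
#' @return data.frame per criterion: `criterion`, `mean_g1`, `mean_g2`,
#'   `percent_difference`, `t_statistic`, `df`, `p_value`. Group labels and
#'   sizes are attached as attributes `g1`, `g2`, `n_g1`, `n_g2`.
#' @export
subgroup_difference <- function(pm, groups, denominator = c("g2", "g1")) {
  stopifnot(inherits(pm, "preference_matrix"))
  denominator <- match.arg(denominator)
  g_vec <- as.factor(groups)
  if (length(g_vec) != nrow(pm$values))
    stop("groups must align with respondents (length P)", call. = FALSE)
  A <- pm$values
  keep <- !is.na(g_vec)
  A <- A[keep, , drop = FALSE]
  g_vec <- droplevels(g_vec[keep])
  if (nlevels(g_vec) != 2L)
    stop("groups must define exactly two non-missing levels", call. = FALSE)
  n1 <- sum(g_vec == levels(g_vec)[1]); n2 <- sum(g_vec == levels(g_vec)[2])
  if (min(n1, n2) < 2L)
    stop("each group needs at least 2 respondents", call. = FALSE)
  res <- lapply(colnames(A), function(cn) {
    x1 <- A[g_vec == levels(g_vec)[1], cn]
    x2 <- A[g_vec == levels(g_vec)[2], cn]
    m1 <- mean(x1); m2 <- mean(x2)
    if (stats::var(x1) + stats::var(x2) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = n1 + n2 - 2),
                 p.value = 1)
    } else {
      tt <- t.test(x1, x2, var.equal = FALSE)
    }
    den <- if (denominator == "g2") m2 else m1
    data.frame(criterion = cn, mean_g1 = m1, mean_g2 = m2,
               percent_difference = 100 * (m1 - m2) / den,
               t_statistic = unname(tt$statistic),
               df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, res)
  attr(out, "g1") <- levels(g_vec)[1]; attr(out, "g2") <- levels(g_vec)[2]
  attr(out, "n_g1") <- n1; attr(out, "n_g2") <- n2
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decide whether to stratify weights by a grouping
#'
#' True iff any criterion's absolute percentage mean difference exceeds the
#' threshold (default 5 percent). The triggering criteria are attached and
#' reported via a message so the decision is auditable.
#'
#' @param differences result of [subgroup_difference()], or a numeric vector
#'   of per-criterion percent differences.
#' @param threshold percent threshold, default 5.
#' @return logical scalar with attribute `triggering` (character vector of
#'   criterion names, possibly empty).
#' @export
stratification_decision <- function(differences, threshold = 5.0) {
  if (is.data.frame(differences)) {
    pd <- differences$percent_difference
    labs <- differences$criterion
  } else {
    pd <- as.numeric(differences)
    labs <- names(differences) %||% paste0("criterion_", seq_along(pd))
  }
  hit <- abs(pd) > threshold
  decision <- any(hit)
  message("stratification decision: ", if (decision) "stratify" else "pool",
          if (decision) paste0(" (|diff| > ", threshold, "% for ",
                               paste(labs[hit], collapse = ", "), ")") else "")
  structure(decision, triggering = labs[hit])
}
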