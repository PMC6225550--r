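# Flat-file interchange. CSV throughout (UTF-8, quoted free text); numbers
# are written at full precision and rounded only for display.

.survey_columns <- c("respondent_id", "gender", "age_band", "education",
                     "ethnicity", "scale", "hfe", "ce", "equity",
                     "multimorbidity", "free_text")

.check_header <- function(df, required, path) {
  miss <- setdiff(required, tolower(names(df)))
  if (length(miss))
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Read a survey CSV
#'
#' Expects the schema `respondent_id,gender,age_band,education,ethnicity,
#' scale,hfe,ce,equity,multimorbidity,free_text`. Answer cells may hold the
#' verbal scale labels or integers 1-5; the encoding is auto-detected per
#' column and mixed columns are rejected downstream.
#'
#' @param path CSV file path.
#' @return data.frame with character columns.
#' @export
read_survey_csv <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  .check_header(df, .survey_columns, path)
  if (nrow(df) == 0L) stop("survey file ", path, " has no rows", call. = FALSE)
  df
}

#' Write a survey data.frame to CSV
#' @param survey data.frame in the survey schema.
#' @param path output path.
#' @export
write_survey_csv <- function(survey, path) {
  write.csv(survey, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a condition indicator CSV
#'
#' Schema: `condition,daly_share,income_loss_nzd,icer_nzd_per_qaly,
#' ethnicity_ratio,gender_ratio,multimorbidity_hr`; empty cells are NA
#' (indicator not supplied). Non-numeric cells are rejected naming the column
#' and line.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_indicator_csv <- function(path) {
  df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  .check_header(df, "condition", path)
  for (cn in setdiff(names(df), "condition")) {
    x <- trimws(df[[cn]])
    x[!nzchar(x)] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      stop("file ", path, ", column ", dQuote(cn), ", line ", bad[1] + 1L,
           ": cannot parse ", dQuote(x[bad[1]]), " as a number",
           call. = FALSE)
    df[[cn]] <- v
  }
  df
}

#' Read a long-format comorbidity CSV
#'
#' Schema: `condition,comorbidity,hazard_ratio,prevalence_weight`, one row
#' per comorbidity term.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_comorbidity_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  .check_header(df, c("condition", "comorbidity", "hazard_ratio",
                      "prevalence_weight"), path)
  df
}

#' Read an impact matrix from CSV
#'
#' Schema: `condition,scale,hfe,ce,equity,multimorbidity`. All cells must lie
#' in [1, 5]; non-Equity cells must be integer-valued. Cells are marked
#' provenance "user".
#'
#' @param path CSV file path.
#' @param criteria a [criterion_set()] (the default five).
#' @return `impact_matrix` object.
#' @export
read_impact_csv <- function(path, criteria = criterion_set()) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  .check_header(df, c("condition", tolower(criteria$labels)), path)
  conds <- as.character(df$condition)
  L <- as.matrix(df[, tolower(criteria$labels), drop = FALSE])
  dimnames(L) <- list(conds, criteria$labels)
  if (any(is.na(L)) || any(L < 1) || any(L > 5))
    stop("impact levels must lie in [1, 5]", call. = FALSE)
  integer_cols <- setdiff(criteria$labels, "Equity")
  off <- abs(L[, integer_cols, drop = FALSE] -
               round(L[, integer_cols, drop = FALSE]))
  if (any(off > 1e-9))
    stop("non-Equity impact levels must be integers", call. = FALSE)
  structure(list(conditions = conds, levels = L,
                 provenance = matrix("user", nrow(L), ncol(L),
                                     dimnames = dimnames(L)),
                 criteria = criteria),
            class = "impact_matrix")
}

#' Write an impact matrix to CSV
#' @param impact an `impact_matrix`.
#' @param path output path.
#' @export
write_impact_csv <- function(impact, path) {
  stopifnot(inherits(impact, "impact_matrix"))
  df <- data.frame(condition = impact$conditions,
                   impact$levels, check.names = FALSE, row.names = NULL)
  names(df) <- c("condition", tolower(impact$criteria$labels))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write one or more weight vectors to CSV
#'
#' Long format: `group,criterion,raw_fraction,percentage,method`.
#'
#' @param weights a [weight_vector()] or list of them (as from
#'   [compute_weights()]).
#' @param path output path.
#' @export
write_weights_csv <- function(weights, path) {
  if (inherits(weights, "weight_vector")) weights <- list(weights)
  rows <- lapply(seq_along(weights), function(i) {
    w <- weights[[i]]
    data.frame(group = w$group %||% names(weights)[i] %||% "pooled",
               criterion = w$criteria$labels,
               raw_fraction = unname(w$raw_fractions),
               percentage = unname(w$percentages),
               method = w$method)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a weight vector from a weights CSV
#'
#' Inverse of [write_weights_csv()] for a single group.
#'
#' @param path CSV path.
#' @param group which group to read (default: the first in the file).
#' @return A `weight_vector`.
#' @export
read_weights_csv <- function(path, group = NULL) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  .check_header(df, c("group", "criterion", "raw_fraction", "percentage",
                      "method"), path)
  if (is.null(group)) group <- df$group[1]
  df <- df[df$group == group, , drop = FALSE]
  if (nrow(df) == 0L) stop("group ", dQuote(group), " not in ", path,
                           call. = FALSE)
  crit <- criterion_set(df$criterion)
  wv <- weight_vector(crit, df$raw_fraction, method = "user", group = group)
  if (!identical(unname(wv$percentages), as.integer(df$percentage)))
    wv$percentages <- setNames(as.integer(df$percentage), crit$labels)
  wv$method <- df$method[1]
  wv
}

#' Write a composite ranking to CSV
#'
#' Schema `rank,condition,a_score`, scores at full precision.
#'
#' @param ranking a `composite_ranking`.
#' @param path output path.
#' @export
write_ranking_csv <- function(ranking, path) {
  stopifnot(inherits(ranking, "composite_ranking"))
  write.csv(ranking$entries[, c("rank", "condition", "a_score")], path,
            row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
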