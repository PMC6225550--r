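#' Assemble a pipeline run configuration
#'
#' Collects the inputs and choices of an end-to-end run. Either `survey` (path
#' or data.frame) is required; the impact side takes `impact` (pre-built
#' matrix CSV/object) or `indicators` (+ optional `comorbidities`).
#'
#' @param survey survey CSV path or data.frame.
#' @param indicators indicator CSV path or data.frame, or NULL.
#' @param comorbidities comorbidity CSV path or data.frame, or NULL.
#' @param impact impact-matrix CSV path or `impact_matrix`, or NULL.
#' @param lexicon lexicon YAML path or named list; NULL disables the
#'   free-text comparison, `"default"` uses the shipped lexicon.
#' @param method weighting method: `"normalized"`, `"roc"`, or `"equal"`.
#' @param by demographic column for the stratification test (e.g.
#'   `"ethnicity"`), or NULL to pool.
#' @param threshold stratification threshold in percent.
#' @param missing_policy passed to [build_preference_matrix()].
#' @param criteria a [criterion_set()].
#' @param out_dir output directory for CSVs and the decision log, or NULL.
#' @return `run_config` list.
#' @export
run_config <- function(survey, indicators = NULL, comorbidities = NULL,
                       impact = NULL, lexicon = "default",
                       method = c("normalized", "roc", "equal"),
                       by = NULL, threshold = 5.0,
                       missing_policy = "drop_respondent",
                       criteria = criterion_set(), out_dir = NULL) {
  method <- match.arg(method)
  if (is.null(impact) && is.null(indicators))
    stop("supply either indicators or a pre-built impact matrix",
         call. = FALSE)
  structure(list(survey = survey, indicators = indicators,
                 comorbidities = comorbidities, impact = impact,
                 lexicon = lexicon, method = method, by = by,
                 threshold = threshold, missing_policy = missing_policy,
                 criteria = criteria, out_dir = out_dir),
            class = "run_config")
}

#' Run the full priority-setting pipeline
#'
#' Survey -> preference matrix -> (stratified) criterion weights -> impact
#' matrix -> composite ranking(s) -> free-text comparison. Every branch taken
#' (dropped respondents, the stratification outcome, ranking ties) is
#' recorded in the decision log; when `out_dir` is set, all intermediates are
#' written as CSV plus `decision_log.txt`.
#'
#' @param config a [run_config()].
#' @return `run_report` object: `preference_matrix`, `weights` (list),
#'   `impact`, `rankings` (list parallel to weights), `tdm`, `top_concerns`,
#'   `comparison`, `decision_log` (character vector).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  survey <- if (is.character(config$survey)) read_survey_csv(config$survey)
            else config$survey
  pm <- suppressMessages(
    build_preference_matrix(survey, config$criteria, config$missing_policy))
  note("survey: ", nrow(pm$values), " respondents retained, ",
       pm$n_dropped, " dropped (missing answers)")

  by_vec <- NULL
  if (!is.null(config$by)) {
    if (!config$by %in% names(pm$respondents))
      stop("grouping column ", dQuote(config$by), " not in survey",
           call. = FALSE)
    by_vec <- pm$respondents[[config$by]]
  }
  weights <- suppressMessages(
    compute_weights(pm, config$method, by = by_vec,
                    threshold = config$threshold))
  note("weighting: method = ", config$method,
       if (!is.null(config$by)) paste0(", stratification by ", config$by,
                                       " (threshold ", config$threshold,
                                       "%): ",
                                       if (attr(weights, "stratified"))
                                         "stratified" else "pooled"))

  impact <- if (!is.null(config$impact)) {
    if (is.character(config$impact)) read_impact_csv(config$impact,
                                                     config$criteria)
    else config$impact
  } else {
    ind <- if (is.character(config$indicators))
      read_indicator_csv(config$indicators) else config$indicators
    com <- if (is.character(config$comorbidities))
      read_comorbidity_csv(config$comorbidities) else config$comorbidities
    build_impact_matrix(ind, comorbidities = com,
                        criteria = config$criteria)
  }
  note("impact: ", length(impact$conditions), " conditions, ",
       sum(impact$provenance == "user"), " user-supplied cell(s)")

  rankings <- lapply(weights, function(w) rank_conditions(impact, w))
  names(rankings) <- names(weights)
  for (nm in names(rankings)) {
    nt <- sum(rankings[[nm]]$entries$tie)
    if (nt > 0) note("ranking (", nm, "): ", nt,
                     " tied entries broken alphabetically")
  }

  tdm <- top <- comparison <- NULL
  lex <- config$lexicon
  if (!is.null(lex) && "free_text" %in% names(pm$respondents)) {
    if (identical(lex, "default")) lex <- load_lexicon()
    else if (is.character(lex)) lex <- load_lexicon(lex)
    tdm <- build_tdm(pm$respondents$free_text,
                     ids = pm$respondents$respondent_id %||% NULL)
    top <- suppressMessages(
      top_concerns(tdm, k = min(100L, nrow(tdm$incidence))))
    comparison <- suppressMessages(
      compare_rankings(rankings[[1]], tdm, lex))
    note("freetext: ", nrow(tdm$incidence), " stems; ",
         sum(!comparison$mentioned),
         " condition(s) not mentioned with appreciable frequency")
  }

  report <- structure(list(preference_matrix = pm, weights = weights,
                           impact = impact, rankings = rankings,
                           tdm = tdm, top_concerns = top,
                           comparison = comparison, decision_log = log,
                           config = config),
                      class = "run_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_weights_csv(report$weights, fp("weights.csv"))
  write_impact_csv(report$impact, fp("impact_matrix.csv"))
  for (nm in names(report$rankings))
    write_ranking_csv(report$rankings[[nm]],
                      fp(paste0("ranking_", gsub("[^A-Za-z0-9]+", "_", nm),
                                ".csv")))
  if (!is.null(report$top_concerns))
    write.csv(report$top_concerns, fp("concern_frequencies.csv"),
              row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(report$comparison))
    write.csv(report$comparison, fp("ranking_comparison.csv"),
              row.names = FALSE, fileEncoding = "UTF-8")
  writeLines(report$decision_log, fp("decision_log.txt"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Priority-setting run report\n")
  cat("---------------------------\n")
  for (line in x$decision_log) cat("*", line, "\n")
  cat("\n")
  for (w in x$weights) print(w)
  cat("\n")
  print(x$rankings[[1]])
  invisible(x)
}
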