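#' Frozen English stopword list
#'
#' Returns the stopword list shipped with the package (a standard English
#' list frozen under `inst/extdata/` so results are reproducible across
#' environments).
#'
#' @return Character vector of lowercase stopwords.
#' @export
healthrank_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "healthrank",
                      mustWork = TRUE)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Tokenize, filter, and stem free-text responses
#'
#' Lowercases, strips punctuation (hyphens act as separators), splits on
#' whitespace, removes stopwords, and Porter-stems the remaining tokens.
#' Duplicate stems within one text are retained here; de-duplication happens
#' per respondent in [build_tdm()].
#'
#' @param text character vector of free-text responses (NA treated as empty).
#' @param stopwords character vector, default [healthrank_stopwords()].
#' @param stemmer stemming function, default [porter_stem()] (pluggable).
#' @return A list, one character vector of stems per input element (possibly
#'   empty).
#' @export
#' @examples
#' preprocess_text("hypertension and hypertensive disease")[[1]]
preprocess_text <- function(text, stopwords = healthrank_stopwords(),
                            stemmer = porter_stem) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  cleaned <- gsub("[^a-z0-9]+", " ", tolower(text))
  toks <- strsplit(trimws(cleaned), "[[:space:]]+")
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    tk <- tk[!tk %in% stopwords]
    if (!length(tk)) character(0) else stemmer(tk)
  })
}

#' Build the binary term-document (stem x respondent) matrix
#'
#' One row per processed stem, one column per respondent; an entry is 1 iff
#' the respondent mentioned the stem at least once (a stem repeated within a
#' single response counts once). Row sums give the number of respondents
#' mentioning each concern.
#'
#' @param texts character vector of free-text responses, or a list of
#'   pre-processed stem vectors (as from [preprocess_text()]).
#' @param ids optional respondent identifiers (column names).
#' @param ... passed to [preprocess_text()] when `texts` is character.
#' @return `tdm` object: `incidence` (integer 0/1 matrix, rows = sorted
#'   vocabulary), `row_sums` (named integer vector), `n_respondents`.
#' @export
build_tdm <- function(texts, ids = NULL, ...) {
  stems <- if (is.list(texts)) texts else preprocess_text(texts, ...)
  n <- length(stems)
  if (n == 0L) stop("need at least one respondent", call. = FALSE)
  stems <- lapply(stems, unique)
  vocab <- sort(unique(unlist(stems)))
  inc <- matrix(0L, nrow = length(vocab), ncol = n,
                dimnames = list(vocab,
                                ids %||% paste0("r", seq_len(n))))
  for (j in seq_len(n)) inc[match(stems[[j]], vocab), j] <- 1L
  structure(list(incidence = inc,
                 row_sums = setNames(as.integer(rowSums(inc)), vocab),
                 n_respondents = n),
            class = "tdm")
}

#' @export
print.tdm <- function(x, ...) {
  cat("Term-document matrix:", nrow(x$incidence), "stems x",
      x$n_respondents, "respondents\n")
  tc <- top_concerns(x, k = min(10L, max(1L, nrow(x$incidence))))
  print(tc, row.names = FALSE)
  invisible(x)
}

#' Most frequent health concerns
#'
#' Stems ranked by descending respondent count (row sums of the term-document
#' matrix); count ties are ordered alphabetically. If `k` exceeds the
#' vocabulary the full list is returned with a note.
#'
#' @param tdm a [build_tdm()] result.
#' @param k number of stems to return, >= 1.
#' @return data.frame `stem`, `count`, at most `k` rows.
#' @export
top_concerns <- function(tdm, k) {
  stopifnot(inherits(tdm, "tdm"), k >= 1)
  cnt <- tdm$row_sums
  if (k > length(cnt)) {
    message("k = ", k, " exceeds vocabulary size (", length(cnt),
            "); returning full list")
    k <- length(cnt)
  }
  ord <- order(-cnt, names(cnt))
  data.frame(stem = names(cnt)[ord], count = unname(cnt[ord]),
             row.names = NULL)[seq_len(k), , drop = FALSE]
}

#' Load a condition -> search-term lexicon from YAML
#'
#' The YAML maps each condition name to a vector of plain-language search
#' terms; terms are stemmed at comparison time, so raw words are fine. A
#' default lexicon for 25 dominant health conditions ships with the package
#' (`system.file("extdata", "condition_lexicon.yaml", package = "healthrank")`).
#'
#' @param path YAML file path.
#' @return Named list of character vectors.
#' @export
load_lexicon <- function(path = system.file("extdata",
                                            "condition_lexicon.yaml",
                                            package = "healthrank",
                                            mustWork = TRUE)) {
  lex <- yaml::read_yaml(path)
  lapply(lex, as.character)
}

#' Compare the algorithm ranking with the free-text concern ranking
#'
#' Each condition's free-text count is the number of respondents mentioning
#' any stem in its lexicon set (stems repeated within a respondent count
#' once). Conditions are ranked by descending count, count ties broken
#' alphabetically; conditions never mentioned get no free-text rank and are
#' flagged. A Spearman rank correlation over the matched pairs is attached.
#'
#' @param algorithm a [rank_conditions()] result.
#' @param tdm a [build_tdm()] result over the same survey.
#' @param lexicon named list: condition -> character vector of terms (stemmed
#'   internally). Conditions absent from the lexicon are reported and left
#'   unmatched.
#' @return data.frame `condition`, `algorithm_rank`, `freetext_count`,
#'   `freetext_rank`, `mentioned`; attribute `rank_correlation` (Spearman
#'   over matched pairs, NA if fewer than 2 matches).
#' @export
compare_rankings <- function(algorithm, tdm, lexicon = load_lexicon()) {
  stopifnot(inherits(algorithm, "composite_ranking"), inherits(tdm, "tdm"))
  if (length(lexicon) == 0L) stop("lexicon is empty", call. = FALSE)
  conds <- algorithm$entries$condition
  unmapped <- setdiff(conds, names(lexicon))
  if (length(unmapped))
    message("condition(s) not covered by lexicon: ",
            paste(unmapped, collapse = ", "))
  counts <- vapply(conds, function(cd) {
    if (!cd %in% names(lexicon)) return(NA_integer_)
    stems <- unique(porter_stem(tolower(lexicon[[cd]])))
    stems <- intersect(stems, rownames(tdm$incidence))
    if (!length(stems)) return(0L)
    as.integer(sum(colSums(tdm$incidence[stems, , drop = FALSE]) > 0L))
  }, integer(1))
  mentioned <- !is.na(counts) & counts > 0L
  ft_rank <- rep(NA_integer_, length(conds))
  if (any(mentioned)) {
    ord <- order(-counts[mentioned], conds[mentioned])
    ft_rank[which(mentioned)[ord]] <- seq_len(sum(mentioned))
  }
  out <- data.frame(condition = conds,
                    algorithm_rank = algorithm$entries$rank,
                    freetext_count = counts,
                    freetext_rank = ft_rank,
                    mentioned = mentioned,
                    row.names = NULL)
  matched <- !is.na(out$freetext_rank)
  attr(out, "rank_correlation") <- if (sum(matched) >= 2L)
    stats::cor(out$algorithm_rank[matched], out$freetext_rank[matched],
               method = "spearman")
  else NA_real_
  out
}
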