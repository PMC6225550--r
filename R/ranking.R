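#' Weighted additive composite score of one condition
#'
#' `A_score = sum(percentage_j * level_j) / 100` over the criteria, using the
#' integer Hare-Niemeyer percentages by default (matching the published
#' sequencing: weights are rounded first, then combined). Set
#' `use_raw_fractions = TRUE` for a sensitivity variant using the unrounded
#' fractions.
#'
#' @param levels named numeric vector of impact levels (names = criteria), or
#'   unnamed in the weight vector's criterion order.
#' @param weights a [weight_vector()].
#' @param use_raw_fractions logical, default FALSE.
#' @return Numeric composite score, bounded by the range of `levels` when the
#'   percentages sum to 100.
#' @export
#' @examples
#' w <- roc_raw_weights(5)
#' composite_score(c(rank1 = 5, rank2 = 4, rank3 = 3, rank4 = 2, rank5 = 1), w)
composite_score <- function(levels, weights, use_raw_fractions = FALSE) {
  stopifnot(inherits(weights, "weight_vector"))
  labs <- weights$criteria$labels
  if (!is.null(names(levels))) {
    if (!setequal(names(levels), labs))
      stop("impact levels and weights name different criteria", call. = FALSE)
    levels <- levels[labs]
  } else if (length(levels) != length(labs)) {
    stop("impact levels and weights have different lengths", call. = FALSE)
  }
  if (use_raw_fractions)
    sum(weights$raw_fractions * as.numeric(levels))
  else
    sum(weights$percentages * as.numeric(levels)) / 100
}

#' Rank conditions by descending composite score
#'
#' Scores every row of the impact matrix with [composite_score()] and orders
#' conditions by descending score. Exact ties share the score, are ordered
#' alphabetically by condition name, and flagged. Scores are kept at full
#' precision; round only for display.
#'
#' @param impact an [build_impact_matrix()] result.
#' @param weights a [weight_vector()] over the same criteria.
#' @param use_raw_fractions passed to [composite_score()].
#' @return `composite_ranking` object whose `entries` data.frame has columns
#'   `rank`, `condition`, `a_score`, `tie`.
#' @export
rank_conditions <- function(impact, weights, use_raw_fractions = FALSE) {
  stopifnot(inherits(impact, "impact_matrix"),
            inherits(weights, "weight_vector"))
  if (!setequal(impact$criteria$labels, weights$criteria$labels))
    stop("impact matrix and weights use different criterion sets",
         call. = FALSE)
  if (length(impact$conditions) == 0L)
    stop("impact matrix is empty", call. = FALSE)
  sc <- apply(impact$levels, 1, composite_score, weights = weights,
              use_raw_fractions = use_raw_fractions)
  ord <- order(-sc, impact$conditions)
  entries <- data.frame(rank = seq_along(ord),
                        condition = impact$conditions[ord],
                        a_score = unname(sc[ord]),
                        row.names = NULL)
  entries$tie <- duplicated(entries$a_score) |
    duplicated(entries$a_score, fromLast = TRUE)
  structure(list(entries = entries, weights_used = weights,
                 note = paste("composite scores are ordinal; relative",
                              "magnitudes are not meaningful multiplicatively")),
            class = "composite_ranking")
}

#' @export
print.composite_ranking <- function(x, ...) {
  cat("Priority ranking (", x$weights_used$method, " weights",
      if (!is.null(x$weights_used$group))
        paste0(", group: ", x$weights_used$group), ")\n", sep = "")
  df <- x$entries
  df$a_score <- sprintf("%.2f", df$a_score)
  print(df, row.names = FALSE)
  cat("note:", x$note, "\n")
  invisible(x)
}
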