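# Small in-code fixtures shared across tests.

# survey data.frame from an integer answer matrix
survey_from_matrix <- function(A, ethnicity = NULL, free_text = NULL) {
  A <- as.matrix(A)
  colnames(A) <- c("scale", "hfe", "ce", "equity", "multimorbidity")[
    seq_len(ncol(A))]
  df <- data.frame(respondent_id = sprintf("R%03d", seq_len(nrow(A))), A)
  if (!is.null(ethnicity)) df$ethnicity <- ethnicity
  if (!is.null(free_text)) df$free_text <- free_text
  df
}

pm_from_matrix <- function(A, ...) {
  suppressMessages(build_preference_matrix(survey_from_matrix(A, ...)))
}

# a 5-criterion matrix whose medians/means order the criteria
# Scale > HFE > Multimorbidity > Equity > CE
profiled_pm <- function() {
  A <- rbind(c(5, 5, 3, 4, 5),
             c(5, 5, 3, 4, 5),
             c(5, 4, 3, 4, 4),
             c(5, 5, 2, 3, 4),
             c(4, 4, 3, 4, 5),
             c(5, 5, 3, 5, 5))
  pm_from_matrix(A)
}

# brute-force composite scorer: independent of composite_score()
brute_force_scores <- function(levels_matrix, percentages) {
  out <- numeric(nrow(levels_matrix))
  for (i in seq_len(nrow(levels_matrix))) {
    acc <- 0
    for (j in seq_len(ncol(levels_matrix)))
      acc <- acc + percentages[[colnames(levels_matrix)[j]]] *
        levels_matrix[i, j]
    out[i] <- acc / 100
  }
  out
}

# brute-force normalized fractions by explicit double loop
brute_force_normalized <- function(A) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) s <- s + A[i, j]
  fr <- numeric(ncol(A))
  for (j in seq_len(ncol(A))) {
    for (i in seq_len(nrow(A))) fr[j] <- fr[j] + A[i, j] / s
  }
  fr
}
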