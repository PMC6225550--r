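# Porter stemming algorithm (Porter 1980), implemented from the original
# rule tables. Within each step the longest matching suffix fires; if its
# m-condition fails, the word passes through unchanged (no backtracking to
# shorter suffixes).

.pstem_vowels <- c("a", "e", "i", "o", "u")

# TRUE per character iff consonant; y is a consonant only at position 1 or
# after a vowel... (classically: y is a vowel when preceded by a consonant)
.cons_pattern <- function(word) {
  chs <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(chs)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chs[i]
    cons[i] <- if (ch %in% .pstem_vowels) FALSE
    else if (ch == "y") (if (i == 1L) TRUE else !cons[i - 1L])
    else TRUE
  }
  cons
}

# m = number of VC sequences in the [C](VC)^m[V] decomposition
.measure <- function(word) {
  if (!nzchar(word)) return(0L)
  runs <- rle(.cons_pattern(word))$values
  if (length(runs) < 2L) return(0L)
  sum(!runs[-length(runs)] & runs[-1L])
}

.has_vowel <- function(word) nzchar(word) && any(!.cons_pattern(word))

.double_cons <- function(word) {
  n <- nchar(word)
  n >= 2L &&
    substr(word, n, n) == substr(word, n - 1L, n - 1L) &&
    .cons_pattern(word)[n]
}

# consonant-vowel-consonant ending where the final consonant is not w, x, y
.cvc_end <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cons <- .cons_pattern(word)
  cons[n - 2L] && !cons[n - 1L] && cons[n] &&
    !(substr(word, n, n) %in% c("w", "x", "y"))
}

.ends <- function(word, suf) {
  n <- nchar(word); k <- nchar(suf)
  n > k && substr(word, n - k + 1L, n) == suf
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# Apply the longest matching rule from a named replacement table, guarded by
# a condition on the stem. cond(stem) -> logical.
.rule_table <- function(word, table, cond) {
  sufs <- names(table)
  hits <- sufs[vapply(sufs, .ends, logical(1), word = word)]
  if (!length(hits)) return(word)
  suf <- hits[which.max(nchar(hits))]
  stem <- .chop(word, nchar(suf))
  if (cond(stem, suf)) paste0(stem, table[[suf]]) else word
}

.porter_one <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # step 1a: plurals
  if (.ends(word, "sses")) word <- .chop(word, 2L)
  else if (.ends(word, "ies")) word <- paste0(.chop(word, 3L), "i")
  else if (!.ends(word, "ss") && .ends(word, "s")) word <- .chop(word, 1L)

  # step 1b: -ed / -ing
  fire_1b2 <- FALSE
  if (.ends(word, "eed")) {
    if (.measure(.chop(word, 3L)) > 0L) word <- .chop(word, 1L)
  } else if (.ends(word, "ed") && .has_vowel(.chop(word, 2L))) {
    word <- .chop(word, 2L); fire_1b2 <- TRUE
  } else if (.ends(word, "ing") && .has_vowel(.chop(word, 3L))) {
    word <- .chop(word, 3L); fire_1b2 <- TRUE
  }
  if (fire_1b2) {
    if (.ends(word, "at") || .ends(word, "bl") || .ends(word, "iz"))
      word <- paste0(word, "e")
    else if (.double_cons(word) &&
             !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z")))
      word <- .chop(word, 1L)
    else if (.measure(word) == 1L && .cvc_end(word))
      word <- paste0(word, "e")
  }

  # step 1c: terminal y -> i after a vowel-bearing stem
  if (.ends(word, "y") && .has_vowel(.chop(word, 1L)))
    word <- paste0(.chop(word, 1L), "i")

  # step 2 (m > 0)
  word <- .rule_table(word, list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), function(stem, suf) .measure(stem) > 0L)

  # step 3 (m > 0)
  word <- .rule_table(word, list(
    icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
    ful = "", ness = ""
  ), function(stem, suf) .measure(stem) > 0L)

  # step 4 (m > 1); -ion additionally needs the stem to end in s or t
  word <- .rule_table(word, list(
    al = "", ance = "", ence = "", er = "", ic = "", able = "", ible = "",
    ant = "", ement = "", ment = "", ent = "", ion = "", ou = "", ism = "",
    ate = "", iti = "", ous = "", ive = "", ize = ""
  ), function(stem, suf) {
    .measure(stem) > 1L &&
      (suf != "ion" ||
         substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))
  })

  # step 5a: drop terminal e
  if (.ends(word, "e")) {
    stem <- .chop(word, 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.cvc_end(stem))) word <- stem
  }
  # step 5b: -ll -> -l for m > 1
  if (.measure(word) > 1L && .double_cons(word) &&
      substr(word, nchar(word), nchar(word)) == "l")
    word <- .chop(word, 1L)

  word
}

#' Porter-stem a vector of lowercase words
#'
#' Reduces English words to their root stems by the classic Porter suffix-
#' stripping algorithm, e.g. "hypertension" and "hypertensive" both stem to
#' "hypertens". Words of one or two characters pass through unchanged. Input
#' is expected lowercase (the tokenizer in [preprocess_text()] lowercases).
#'
#' @param words character vector.
#' @return Character vector of stems, same length.
#' @export
#' @examples
#' porter_stem(c("hypertension", "hypertensive", "diseases"))
porter_stem <- function(words) {
  vapply(as.character(words), .porter_one, character(1), USE.NAMES = FALSE)
}
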