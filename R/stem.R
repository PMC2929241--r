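# Morphological processor: maps each word form to a canonical lexeme key so
# that inflectional (and a few derivational) variants pool their counts.
# Rules, applied in order on words longer than three characters:
#   plural   -ies -> -y; -es after s/x/z/ch/sh; otherwise -s (not -ss/-us/-is)
#   -ion     stripped only when the remainder ends in a double s
#            (repression -> repress; segmentation is left alone)
#   -ed/-ing stripped, with final-consonant undoubling (not ss/ll)
#   -or/-er  agentive, stripped when the remainder keeps >= 4 characters
#   final -e stripped from stems of >= 5 characters, so that e.g. "kinase"
#            and "kinases" share one key
# Keys are canonical strings, not necessarily words; display code maps a
# key back to its most frequent surface form.

#' Canonical lexeme key of word forms
#'
#' Deterministic, dictionary-free suffix stripping that groups words with
#' the same stem into one lexeme. For example "repression", "repress",
#' "repressed", "repressing", "represses", "repressor" and "repressors"
#' all map to the same key, while "segmentation" maps to itself.
#'
#' @param words Character vector of lowercase tokens.
#' @return Character vector of lexeme keys, same length as `words`.
#' @examples
#' lexeme_of(c("repressed", "repressors", "kinases", "segmentation"))
#' @export
lexeme_of <- function(words) {
  vapply(as.character(words), stem_one, "", USE.NAMES = FALSE)
}

stem_one <- function(w) {
  n <- nchar(w)
  if (is.na(w) || n <= 3L || grepl("^[0-9]", w) || grepl("-", w, fixed = TRUE)) {
    return(w)
  }
  # plural
  if (endsWith(w, "ies") && n > 4L) {
    w <- paste0(substr(w, 1L, n - 3L), "y")
  } else if (n > 4L && (endsWith(w, "ses") || endsWith(w, "xes") ||
                        endsWith(w, "zes") || endsWith(w, "ches") ||
                        endsWith(w, "shes"))) {
    w <- substr(w, 1L, n - 2L)
  } else if (endsWith(w, "s") && !endsWith(w, "ss") &&
             !endsWith(w, "us") && !endsWith(w, "is")) {
    w <- substr(w, 1L, n - 1L)
  }
  n <- nchar(w)
  if (endsWith(w, "ion") && n >= 7L && substr(w, n - 4L, n - 3L) == "ss") {
    w <- substr(w, 1L, n - 3L)
  } else if (endsWith(w, "ed") && n >= 5L) {
    w <- undouble(substr(w, 1L, n - 2L))
  } else if (endsWith(w, "ing") && n >= 6L) {
    w <- undouble(substr(w, 1L, n - 3L))
  }
  n <- nchar(w)
  if ((endsWith(w, "or") || endsWith(w, "er")) && n >= 6L) {
    w <- substr(w, 1L, n - 2L)
  }
  n <- nchar(w)
  if (endsWith(w, "e") && n >= 5L) w <- substr(w, 1L, n - 1L)
  w
}

# drop a doubled final consonant left by -ed/-ing stripping (stopped ->
# stop), but keep ss/ll, which commonly end real stems (repress, cell)
undouble <- function(w) {
  n <- nchar(w)
  if (n < 4L) return(w)
  a <- substr(w, n - 1L, n - 1L)
  b <- substr(w, n, n)
  if (a == b && !b %in% c("s", "l", "a", "e", "i", "o", "u")) {
    return(substr(w, 1L, n - 1L))
  }
  w
}
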