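# Abbreviation-expansion pair detection from parenthetical patterns,
# following the classic character-alignment approach: every alphanumeric
# character of the short form must match, in order, inside the long form,
# and the first character of the short form must start a long-form word.
# Both "long form (SF)" and "SF (long form)" orientations are handled.

# Best long form for a short form inside a candidate string, or NULL.
# Scans the short form right to left, consuming candidate characters; the
# match of the first short-form character must be word-initial.
find_best_long_form <- function(sf, candidate) {
  s <- strsplit(tolower(sf), "")[[1L]]
  l <- strsplit(tolower(candidate), "")[[1L]]
  si <- length(s); li <- length(l)
  is_alnum <- function(ch) grepl("[a-z0-9]", ch)
  while (si >= 1L) {
    ch <- s[si]
    if (!is_alnum(ch)) { si <- si - 1L; next }
    while (li >= 1L &&
           (l[li] != ch ||
            (si == 1L && li > 1L && is_alnum(l[li - 1L])))) {
      li <- li - 1L
    }
    if (li < 1L) return(NULL)
    si <- si - 1L; li <- li - 1L
  }
  substr(candidate, li + 1L, nchar(candidate))
}

# Validity of a parenthesized string as a short form.
valid_short_form <- function(sf) {
  sf <- trimws(sf)
  n <- nchar(sf)
  if (n < 2L || n > 10L) return(FALSE)
  if (length(strsplit(sf, "\\s+")[[1L]]) > 2L) return(FALSE)
  if (!grepl("[A-Za-z]", sf)) return(FALSE)
  grepl("^[A-Za-z0-9]", sf)
}

# Word-count cap on long forms, as in the original algorithm.
valid_long_form <- function(sf, lf) {
  if (is.null(lf) || !nzchar(trimws(lf))) return(FALSE)
  n_sf <- nchar(gsub("[^A-Za-z0-9]", "", sf))
  words <- strsplit(trimws(lf), "\\s+")[[1L]]
  if (length(words) > min(n_sf + 5L, n_sf * 2L)) return(FALSE)
  if (nchar(lf) <= nchar(sf)) return(FALSE)
  TRUE
}

#' Detect abbreviation-expansion pairs in a document
#'
#' Scans the title and each body sentence for parenthetical patterns
#' `long form (SF)` and `SF (long form)` and validates each candidate with
#' the character-alignment conditions: short-form alphanumerics must match
#' in order inside the long form and the first must start a long-form word.
#' Deterministic; returns lowercase forms.
#'
#' @param record A tokenized document entry (see [corpus_tokens()]) or a
#'   one-row `abstract_corpus`.
#' @return A tibble with columns `short_form`, `long_form`, `doc_id` and
#'   `where` (`"title"` or the sentence index as a string).
#' @examples
#' cc <- corpus("d1", "A study", "Dentin phosphoprotein (DPP) is cleaved.")
#' detect_abbreviations(cc)
#' @export
detect_abbreviations <- function(record) {
  entry <- as_token_entry(record)
  pieces <- c(title = entry$title,
              stats::setNames(entry$sentences, seq_along(entry$sentences)))
  out_sf <- character(0); out_lf <- character(0); out_where <- character(0)
  for (w in seq_along(pieces)) {
    text <- pieces[[w]]
    if (is.na(text) || !nzchar(text)) next
    m <- gregexpr("\\(([^()]+)\\)", text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      inner <- substr(text, m[i] + 1L, m[i] + lens[i] - 2L)
      before <- trimws(substr(text, 1L, m[i] - 1L))
      if (!nzchar(before)) next
      if (valid_short_form(inner)) {
        # long (short): candidate long form = trailing words before the paren
        sf <- trimws(inner)
        n_sf <- nchar(gsub("[^A-Za-z0-9]", "", sf))
        words <- strsplit(before, "\\s+")[[1L]]
        take <- min(length(words), min(n_sf + 5L, n_sf * 2L))
        cand <- paste(utils::tail(words, take), collapse = " ")
        lf <- find_best_long_form(sf, cand)
        if (valid_long_form(sf, lf)) {
          out_sf <- c(out_sf, tolower(sf))
          out_lf <- c(out_lf, tolower(trimws(lf)))
          out_where <- c(out_where, names(pieces)[w])
          next
        }
      }
      # short (long): token before the paren is the short form
      words <- strsplit(before, "\\s+")[[1L]]
      sf2 <- gsub("^[^A-Za-z0-9]+|[^A-Za-z0-9-]+$", "", utils::tail(words, 1L))
      if (valid_short_form(sf2) && !valid_short_form(inner)) {
        lf2 <- find_best_long_form(sf2, trimws(inner))
        # require the aligned long form to be (essentially) the whole inner text
        if (valid_long_form(sf2, lf2) &&
            nchar(lf2) >= 0.8 * nchar(trimws(inner))) {
          out_sf <- c(out_sf, tolower(sf2))
          out_lf <- c(out_lf, tolower(trimws(lf2)))
          out_where <- c(out_where, names(pieces)[w])
        }
      }
    }
  }
  tibble::tibble(short_form = out_sf, long_form = out_lf,
                 doc_id = rep(entry$doc_id %||% NA_character_, length(out_sf)),
                 where = out_where)
}
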