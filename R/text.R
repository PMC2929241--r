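# Tokenization and sentence segmentation.
#
# Tokens are lowercase runs of Unicode letters/digits with internal hyphens
# preserved; everything else is a separator. The sentence splitter is
# rule-based (no model download) and deterministic.

#' Tokenize text
#'
#' Lowercases and splits text into tokens. Letters, digits and internal
#' hyphens are token characters; all other characters separate tokens, so
#' punctuation is stripped while names such as `"JAM-1"` survive as
#' `"jam-1"`. Pure function: the same input always gives the same output.
#'
#' @param text A character scalar. `NA` or `""` give an empty token vector.
#' @return Character vector of lowercase tokens.
#' @examples
#' tokenize("WD40 domain.")
#' tokenize("JAM-1 mediates tight-junction assembly.")
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("`text` must be a single string", call. = FALSE)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  m <- gregexpr("[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*", x, perl = TRUE)
  regmatches(x, m)[[1L]]
}

# Words that commonly precede a period without ending a sentence.
.sentence_abbrevs <- c(
  "e.g", "i.e", "cf", "al", "fig", "figs", "vs", "ca", "approx",
  "dr", "mr", "mrs", "ms", "st", "sp", "spp", "resp", "no"
)

#' Split an abstract into title and body sentences
#'
#' The body is split on `.`, `?` or `!` followed by whitespace and a capital
#' letter or digit, with an exception list for common abbreviations
#' ("e.g.", "et al.", "Fig.", ...). The title is kept separate from the body
#' sentences so that positional rules (title / first / last sentence) can be
#' applied downstream.
#'
#' @param title Title text (may be `NA` or empty).
#' @param body Abstract body text.
#' @return A list with elements `title` (string) and `sentences`
#'   (character vector, possibly empty).
#' @examples
#' split_sentences("A title", "First sentence. Second sentence.")
#' @export
split_sentences <- function(title, body) {
  list(
    title = if (is.null(title) || length(title) == 0L || is.na(title)) "" else title,
    sentences = split_sentence_text(body)
  )
}

# Body-only splitter; returns a character vector of sentences.
split_sentence_text <- function(body) {
  if (is.null(body) || length(body) == 0L || is.na(body)) return(character(0))
  body <- trimws(body)
  if (!nzchar(body)) return(character(0))
  cand <- gregexpr("[.?!]+(?=[\")\\]']*\\s+[\"(\\[']*[A-Z0-9])", body, perl = TRUE)[[1L]]
  if (cand[1L] == -1L) return(body)
  lens <- attr(cand, "match.length")
  ends <- integer(0)
  for (i in seq_along(cand)) {
    pre <- substr(body, max(1L, cand[i] - 15L), cand[i] - 1L)
    word <- regmatches(pre, regexpr("\\S+$", pre))
    if (length(word) == 1L && tolower(word) %in% .sentence_abbrevs) next
    ends <- c(ends, cand[i] + lens[i] - 1L)
  }
  if (length(ends) == 0L) return(body)
  starts <- c(1L, ends + 1L)
  stops <- c(ends, nchar(body))
  out <- trimws(substring(body, starts, stops))
  out[nzchar(out)]
}
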