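# Term units and their counts. Three unit types are extracted per document:
#   unigram - lexeme key of a single non-stopword token
#   bigram  - pair of adjacent lexeme keys within one sentence (or the
#             title), neither member a stopword
#   kb      - exact surface-token match of a knowledge-base phrase
# Counting is at the document level for document frequencies (a term counts
# once per abstract) and at the token level for mention counts (used by the
# redundancy rule and the bigram-expansion display).

#' Load a stopword list
#'
#' One word per line, `#` comments ignored. Defaults to the list shipped
#' with the package.
#'
#' @param path Optional path to a stopword file.
#' @return Character vector of lowercase stopwords.
#' @export
load_stopwords <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stopwords.txt", package = "itermine")
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  tolower(x[nzchar(x)])
}

#' Read knowledge-base term lists
#'
#' Flat phrase files, one term per line, `#` comments ignored. Several
#' files (one per vocabulary source) may be given; phrases are pooled.
#'
#' @param paths Character vector of file paths. `NULL` loads the packaged
#'   default list.
#' @return Named list mapping the normalized phrase to its token vector.
#' @export
read_kb_terms <- function(paths = NULL) {
  paths <- paths %||% system.file("extdata", "kb_terms.txt", package = "itermine")
  phrases <- unlist(lapply(paths, function(p) {
    x <- readLines(p, encoding = "UTF-8", warn = FALSE)
    x <- trimws(sub("#.*$", "", x))
    x[nzchar(x)]
  }))
  toks <- lapply(phrases, tokenize)
  keep <- lengths(toks) > 0L
  toks <- toks[keep]
  names(toks) <- vapply(toks, paste, "", collapse = " ")
  toks[!duplicated(names(toks))]
}

# tokens eligible as term members: not a stopword, more than one character,
# not a bare number
term_token_ok <- function(tokens, stopwords) {
  !(tokens %in% stopwords) & nchar(tokens) > 1L & !grepl("^[0-9]+$", tokens)
}

# lexeme keys with a per-call cache over unique tokens
keys_for <- function(tokens, cache = NULL) {
  u <- unique(tokens)
  k <- lexeme_of(u)
  k[match(tokens, u)]
}

#' Extract the term units present in one document
#'
#' Document-level presence: each term is reported once however often it
#' occurs.
#'
#' @param record A tokenized entry or one-row corpus.
#' @param stopwords Character vector of stopwords.
#' @param kb Optional knowledge-base phrase list from [read_kb_terms()].
#' @return A tibble with columns `term` and `type`.
#' @export
extract_terms <- function(record, stopwords = load_stopwords(), kb = NULL) {
  entry <- as_token_entry(record)
  uni <- character(0); bi <- character(0); kbt <- character(0)
  for (s in token_seqs(entry)) {
    if (length(s) == 0L) next
    ok <- term_token_ok(s, stopwords)
    keys <- keys_for(s)
    uni <- c(uni, keys[ok])
    if (length(s) > 1L) {
      i <- seq_len(length(s) - 1L)
      both <- ok[i] & ok[i + 1L]
      if (any(both)) bi <- c(bi, paste(keys[i][both], keys[i + 1L][both]))
    }
    if (!is.null(kb)) {
      for (ph in names(kb)) {
        if (contains_any(s, kb[ph])) kbt <- c(kbt, ph)
      }
    }
  }
  uni <- unique(uni); bi <- unique(bi); kbt <- unique(kbt)
  tibble::tibble(
    term = c(uni, bi, kbt),
    type = c(rep("unigram", length(uni)), rep("bigram", length(bi)),
             rep("kb", length(kbt)))
  )
}

#' Document frequencies of all terms in a corpus
#'
#' `df(term)` is the number of documents whose [extract_terms()] output
#' contains the term; lexeme variants are pooled by construction.
#'
#' @param tokens A [corpus_tokens()] list.
#' @inheritParams extract_terms
#' @return A tibble with columns `term`, `type` and `df`.
#' @export
document_frequencies <- function(tokens, stopwords = load_stopwords(), kb = NULL) {
  if (length(tokens) == 0L) stop("corpus is empty", call. = FALSE)
  all_terms <- character(0); all_types <- character(0)
  for (entry in tokens) {
    tt <- extract_terms(entry, stopwords, kb)
    all_terms <- c(all_terms, tt$term)
    all_types <- c(all_types, tt$type)
  }
  key <- paste(all_types, all_terms, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  tibble::tibble(
    term = vapply(parts, `[`, "", 2L),
    type = vapply(parts, `[`, "", 1L),
    df = as.integer(tab)
  )
}

#' Token-level mention counts of unigram and bigram terms
#'
#' Counts every occurrence (not just document presence) of each unigram
#' lexeme and adjacent bigram in a token list, along with the surface-form
#' counts of each lexeme key (used to pick a display form).
#'
#' @param tokens A [corpus_tokens()] list (typically the About Set).
#' @param stopwords Character vector of stopwords.
#' @return A list with tibbles `counts` (`term`, `type`, `count`) and
#'   `surfaces` (`key`, `surface`, `count`).
#' @export
term_mention_counts <- function(tokens, stopwords = load_stopwords()) {
  uni <- character(0); bi <- character(0)
  key_v <- character(0); surf_v <- character(0)
  for (entry in tokens) {
    for (s in token_seqs(entry)) {
      if (length(s) == 0L) next
      ok <- term_token_ok(s, stopwords)
      keys <- keys_for(s)
      uni <- c(uni, keys[ok])
      key_v <- c(key_v, keys[ok]); surf_v <- c(surf_v, s[ok])
      if (length(s) > 1L) {
        i <- seq_len(length(s) - 1L)
        both <- ok[i] & ok[i + 1L]
        if (any(both)) bi <- c(bi, paste(keys[i][both], keys[i + 1L][both]))
      }
    }
  }
  tab_u <- table(uni); tab_b <- table(bi)
  counts <- tibble::tibble(
    term = c(names(tab_u), names(tab_b)),
    type = c(rep("unigram", length(tab_u)), rep("bigram", length(tab_b))),
    count = c(as.integer(tab_u), as.integer(tab_b))
  )
  st <- table(paste(key_v, surf_v, sep = "\r"))
  parts <- strsplit(names(st), "\r", fixed = TRUE)
  surfaces <- tibble::tibble(
    key = vapply(parts, `[`, "", 1L),
    surface = vapply(parts, `[`, "", 2L),
    count = as.integer(st)
  )
  list(counts = counts, surfaces = surfaces)
}
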