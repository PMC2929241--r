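# The iTerm score and ranking. A term's score contrasts its normalized
# document frequency in the gene's About Set with the background:
#
#   s(t) = (df_a/N_a - df_b/N_b) * log(N_b / df_b)
#
# The first factor is the normalized document-frequency difference; the
# second is an IDF-like damping that penalizes terms frequent in the
# background (two terms with the same difference diverge sharply when one
# is rare in the background and the other ubiquitous). Natural log by
# default; the base is configurable.

#' Score a term against the background
#'
#' @param df_a,df_b Document frequencies in the About and Background Sets.
#'   `df_b` must be >= 1 (callers floor background-absent unigrams at 1).
#' @param n_a,n_b Sizes of the About and Background Sets (both > 0).
#' @param log_base Base of the damping logarithm (default natural).
#' @return Numeric score(s); zero when the normalized frequencies are
#'   equal, positive when the term is enriched in the About Set.
#' @examples
#' score_term(50, 100, 100, 10000)
#' @export
score_term <- function(df_a, n_a, df_b, n_b, log_base = exp(1)) {
  if (any(n_a <= 0) || any(n_b <= 0)) {
    stop("About and Background Set sizes must be positive", call. = FALSE)
  }
  if (any(df_b < 1)) stop("df_b must be >= 1 (floor background-absent terms at 1)",
                          call. = FALSE)
  (df_a / n_a - df_b / n_b) * log(n_b / df_b, base = log_base)
}

#' Rank informative terms for a gene
#'
#' Computes About-Set document frequencies with the same extraction
#' settings as the background, scores every term, and ranks:
#' * bigrams absent from the background or with `df_b` below
#'   `bigram_min_df_b` (default 10) are removed before scoring;
#' * unigrams and kb terms absent from the background get `df_b = 1`
#'   (maximal damping credit, keeps the log finite);
#' * terms with score <= 0 are background-typical and dropped;
#' * sorting is by descending score with lexicographic tie-break on the
#'   term string.
#' Each unigram row carries its most frequent adjacent bigrams (for the
#' expanded display) and a display form (the most frequent surface form of
#' the lexeme).
#'
#' @param about An `about_set` (or character vector of doc ids).
#' @param tokens A [corpus_tokens()] list covering the About Set.
#' @param background_df Background document frequencies from
#'   [document_frequencies()] (columns `term`, `type`, `df`).
#' @param n_b Background Set size.
#' @param stopwords,kb Extraction settings; must match those used for
#'   `background_df`.
#' @param bigram_min_df_b Background support threshold for bigrams.
#' @param log_base Damping log base.
#' @param n_bigram_assoc How many associated bigrams to keep per unigram.
#' @return An object of class `iterm_list`: a tibble with columns `rank`,
#'   `term`, `display`, `type`, `df_a`, `df_b`, `score` and `bigrams`
#'   (list), with the About-Set mention counts attached as attribute
#'   `"mentions"` and sizes as `"n_a"` / `"n_b"`.
#' @export
rank_iterms <- function(about, tokens, background_df, n_b,
                        stopwords = load_stopwords(), kb = NULL,
                        bigram_min_df_b = 10L, log_base = exp(1),
                        n_bigram_assoc = 3L) {
  ids <- if (inherits(about, "about_set")) about$doc_ids else as.character(about)
  atoks <- tokens[ids]
  n_a <- length(atoks)
  dfa <- document_frequencies(atoks, stopwords, kb)
  m <- match(paste(dfa$type, dfa$term, sep = "\r"),
             paste(background_df$type, background_df$term, sep = "\r"))
  df_b <- background_df$df[m]
  df_b[is.na(df_b)] <- 0L
  is_bigram <- dfa$type == "bigram"
  keep <- !is_bigram | df_b >= bigram_min_df_b
  dfa <- dfa[keep, ]; df_b <- df_b[keep]
  df_b[df_b < 1L] <- 1L
  score <- score_term(dfa$df, n_a, df_b, n_b, log_base = log_base)
  pos <- score > 0
  dfa <- dfa[pos, ]; df_b <- df_b[pos]; score <- score[pos]
  ord <- order(-score, dfa$term, dfa$type)
  out <- tibble::tibble(
    rank = seq_along(ord),
    term = dfa$term[ord],
    type = dfa$type[ord],
    df_a = dfa$df[ord],
    df_b = df_b[ord],
    score = score[ord]
  )
  mentions <- term_mention_counts(atoks, stopwords)
  out$display <- display_form(out$term, out$type, mentions$surfaces)
  out$bigrams <- bigram_assoc(out$term, out$type, mentions$counts, n_bigram_assoc)
  out <- out[, c("rank", "term", "display", "type", "df_a", "df_b", "score", "bigrams")]
  structure(out,
            class = c("iterm_list", class(tibble::tibble())),
            mentions = mentions,
            n_a = n_a, n_b = n_b,
            gene_id = if (inherits(about, "about_set")) about$gene_id else NA_character_)
}

# most frequent surface form of each lexeme key (alphabetical tie-break);
# bigram displays combine member displays, kb terms display as themselves
display_form <- function(term, type, surfaces) {
  best <- function(key) {
    s <- surfaces[surfaces$key == key, ]
    if (nrow(s) == 0L) return(key)
    s <- s[order(-s$count, s$surface), ]
    s$surface[1L]
  }
  vapply(seq_along(term), function(i) {
    if (type[i] == "kb") return(term[i])
    paste(vapply(strsplit(term[i], " ", fixed = TRUE)[[1L]], best, ""),
          collapse = " ")
  }, "")
}

# top adjacent bigrams (by About-Set mention count) containing a unigram key
bigram_assoc <- function(term, type, counts, n_top) {
  bc <- counts[counts$type == "bigram", ]
  words <- strsplit(bc$term, " ", fixed = TRUE)
  lapply(seq_along(term), function(i) {
    if (type[i] != "unigram") return(character(0))
    hit <- vapply(words, function(w) term[i] %in% w, logical(1))
    b <- bc[hit, ]
    if (nrow(b) == 0L) return(character(0))
    b <- b[order(-b$count, b$term), ]
    utils::head(stats::setNames(b$count, b$term), n_top)
  })
}

#' Remove unigrams made redundant by a bigram
#'
#' A unigram is removed when a single retained bigram containing it
#' accounts for at least `threshold` (default 75%) of the unigram's
#' About-Set occurrences - i.e. the unigram occurs alone less than a
#' quarter of the time, so the more informative bigram supersedes it.
#' A unigram like "repressor", whose occurrences split across several
#' bigrams (about 50% within "transcriptional repressor"), is kept.
#'
#' @param iterms An `iterm_list` from [rank_iterms()].
#' @param mention_counts Optional About-Set mention counts (tibble with
#'   `term`, `type`, `count`); defaults to those attached to `iterms`.
#' @param threshold Coverage fraction at which the unigram is removed.
#' @return The pruned, re-ranked `iterm_list`; removed terms are recorded
#'   in attribute `"removed"`.
#' @export
prune_redundant <- function(iterms, mention_counts = NULL, threshold = 0.75) {
  counts <- mention_counts %||% attr(iterms, "mentions")$counts
  if (is.null(counts)) stop("no mention counts available", call. = FALSE)
  cnt <- function(term, type) {
    v <- counts$count[counts$term == term & counts$type == type]
    if (length(v) == 0L) 0L else v[1L]
  }
  retained_bigrams <- iterms$term[iterms$type == "bigram"]
  bwords <- strsplit(retained_bigrams, " ", fixed = TRUE)
  drop <- logical(nrow(iterms))
  for (i in seq_len(nrow(iterms))) {
    if (iterms$type[i] != "unigram") next
    u <- iterms$term[i]
    cu <- cnt(u, "unigram")
    if (cu == 0L) next
    for (j in seq_along(retained_bigrams)) {
      if (!(u %in% bwords[[j]])) next
      if (cnt(retained_bigrams[j], "bigram") / cu >= threshold) {
        drop[i] <- TRUE
        break
      }
    }
  }
  removed <- iterms$term[drop]
  out <- iterms[!drop, ]
  out$rank <- seq_len(nrow(out))
  attr(out, "mentions") <- attr(iterms, "mentions")
  attr(out, "n_a") <- attr(iterms, "n_a")
  attr(out, "n_b") <- attr(iterms, "n_b")
  attr(out, "gene_id") <- attr(iterms, "gene_id")
  attr(out, "removed") <- removed
  class(out) <- class(iterms)
  out
}
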