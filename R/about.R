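# About-Set selection: keep Full-Set abstracts that focus on the gene
# rather than mention it in passing. An abstract qualifies when it mentions
# the gene at least three times (title included in the total) or mentions
# it in the title, the first, or the last body sentence.

#' Count gene mentions in a document
#'
#' Number of non-overlapping token-boundary occurrences of any query
#' variant in the title plus body. Overlapping variants at the same
#' position are counted once, longest match first.
#'
#' @param record A tokenized entry or one-row corpus.
#' @param expansion A `query_expansion`.
#' @return Integer count.
#' @export
mention_count <- function(record, expansion) {
  entry <- as_token_entry(record)
  sum(vapply(token_seqs(entry), function(s) {
    nrow(match_positions(s, expansion$variant_tokens))
  }, integer(1)))
}

#' Does an abstract focus on the gene?
#'
#' `TRUE` iff the gene is mentioned at least `min_mentions` times in total,
#' or a variant occurs in the title, the first body sentence, or the last
#' body sentence (inclusive OR). Adding a mention can only flip the result
#' from `FALSE` to `TRUE`.
#'
#' @inheritParams mention_count
#' @param min_mentions Mention-count threshold (default 3).
#' @return Logical.
#' @export
is_about <- function(record, expansion, min_mentions = 3L) {
  entry <- as_token_entry(record)
  if (mention_count(entry, expansion) >= min_mentions) return(TRUE)
  vt <- expansion$variant_tokens
  if (contains_any(entry$title_tokens, vt)) return(TRUE)
  ns <- length(entry$sent_tokens)
  if (ns == 0L) return(FALSE)
  contains_any(entry$sent_tokens[[1L]], vt) ||
    contains_any(entry$sent_tokens[[ns]], vt)
}

#' Select the About Set from a Full Set
#'
#' Filters the Full Set with [is_about()]. Warns when the About Set is
#' small (fewer than `low_data` documents; a stronger warning below
#' `very_low`), since frequency-based scores are unstable on small sets.
#' An empty About Set is an error (nothing is scorable).
#'
#' @param full A `full_set` from [egrab()], or a character vector of
#'   doc ids.
#' @param tokens A [corpus_tokens()] list covering the Full Set.
#' @param expansion A `query_expansion`.
#' @param min_mentions Mention-count threshold (default 3).
#' @param low_data,very_low Warning thresholds on the About-Set size.
#' @return An object of class `about_set`: list with `gene_id`, `doc_ids`
#'   and `n_a`.
#' @export
about_set <- function(full, tokens, expansion, min_mentions = 3L,
                      low_data = 50L, very_low = 30L) {
  ids <- if (inherits(full, "full_set")) full$doc_ids else as.character(full)
  miss <- setdiff(ids, names(tokens))
  if (length(miss)) stop("tokens are missing doc(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  keep <- vapply(ids, function(d) is_about(tokens[[d]], expansion, min_mentions),
                 logical(1))
  out_ids <- ids[keep]
  n_a <- length(out_ids)
  if (n_a == 0L) stop("About Set is empty: no abstract focuses on the gene",
                      call. = FALSE)
  if (n_a < very_low) {
    warning(sprintf("About Set has only %d documents (< %d); term scores will be very unstable",
                    n_a, very_low), call. = FALSE)
  } else if (n_a < low_data) {
    warning(sprintf("About Set has only %d documents (< %d); term scores may be unstable",
                    n_a, low_data), call. = FALSE)
  }
  gid <- if (inherits(full, "full_set")) full$gene_id else expansion$gene_id
  structure(list(gene_id = gid, doc_ids = out_ids, n_a = n_a),
            class = "about_set")
}

#' @export
print.about_set <- function(x, ...) {
  cat(sprintf("<About Set for gene %s: N_a = %d>\n", x$gene_id, x$n_a))
  invisible(x)
}
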