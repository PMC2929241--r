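# eGRAB: retrieval of candidate abstracts for a gene and disambiguation of
# ambiguous names with per-sense bigram language models.
#
# Training data is built automatically from "anchor" abstracts: an abstract
# mentioning two or more distinct names of the gene anchors the gene sense,
# while an abstract carrying a rival expansion phrase (or a detected
# abbreviation-expansion pair whose short form is the ambiguous name)
# anchors that rival sense. A smoothed bigram language model is trained per
# sense on its anchors; remaining abstracts are assigned to the sense whose
# model gives them the highest mean per-token log probability. Exact ties
# are left ambiguous and excluded from the Full Set (precision first).

#' Retrieve candidate abstracts for a query expansion
#'
#' Returns exactly the documents whose title or body contains at least one
#' query variant on token boundaries (multi-token variants match contiguous
#' token subsequences within a sentence).
#'
#' @param expansion A `query_expansion` from [expand_query()].
#' @param corpus An `abstract_corpus` (ignored when `tokens` is given).
#' @param tokens Optional pre-computed [corpus_tokens()] list.
#' @return Character vector of matching doc ids (possibly empty).
#' @export
retrieve <- function(expansion, corpus = NULL, tokens = NULL) {
  tokens <- tokens %||% corpus_tokens(corpus)
  hit <- vapply(tokens, doc_contains, logical(1), vtoks = expansion$variant_tokens)
  names(tokens)[hit]
}

# Rival senses discovered from abbreviation-expansion pairs in candidate
# docs: any long form paired with a gene variant that is not itself a gene
# name becomes a rival sense keyed by its normalized expansion.
discover_senses <- function(expansion, tokens, doc_ids) {
  norm_variants <- norm_phrase(expansion$variants)
  sf <- character(0); lf <- character(0); doc <- character(0)
  for (d in doc_ids) {
    ab <- detect_abbreviations(tokens[[d]])
    if (nrow(ab) == 0L) next
    sfn <- norm_phrase(ab$short_form)
    keep <- sfn %in% norm_variants
    if (!any(keep)) next
    sf <- c(sf, sfn[keep])
    lf <- c(lf, norm_phrase(ab$long_form[keep]))
    doc <- c(doc, rep(d, sum(keep)))
  }
  tibble::tibble(doc_id = doc, short_form = sf, long_form = lf,
                 is_gene = lf %in% norm_variants)
}

#' Anchor a document to a sense, if possible
#'
#' A document anchors the gene sense when it mentions two or more distinct
#' gene names; it anchors a rival sense when it contains that sense's
#' expansion phrase (or a detected abbreviation-expansion pair with the
#' ambiguous short form). A document matched by two or more senses' anchor
#' rules is in conflict and anchors nothing.
#'
#' @param record A tokenized entry or one-row corpus.
#' @param expansion The gene's `query_expansion`.
#' @param rivals Named list mapping rival sense id to its expansion
#'   phrase(s); may be empty.
#' @return The sense id (`"gene"` for the gene sense, otherwise the rival
#'   id) or `NA_character_` when no anchor rule (or more than one) applies.
#' @export
anchor_assign <- function(record, expansion, rivals = list()) {
  entry <- as_token_entry(record)
  gene_anchor <- length(matched_names(entry, expansion)) >= 2L
  rival_hits <- character(0)
  for (rid in names(rivals)) {
    ph <- lapply(rivals[[rid]], tokenize)
    ph <- ph[lengths(ph) > 0L]
    if (length(ph) && doc_contains(entry, ph)) rival_hits <- c(rival_hits, rid)
  }
  n_senses <- as.integer(gene_anchor) + length(rival_hits)
  if (n_senses != 1L) return(NA_character_)
  if (gene_anchor) "gene" else rival_hits
}

#' Train per-sense bigram language models
#'
#' Builds one add-k smoothed bigram model per sense from its anchored
#' training abstracts (title plus body sentences, each wrapped in
#' sentence-boundary markers). Senses with no training abstracts are
#' dropped with a warning; an error is raised when every sense is empty.
#' Training sets of different senses must be disjoint.
#'
#' @param anchored Named list mapping sense id to a character vector of
#'   training doc ids.
#' @param tokens A [corpus_tokens()] list covering the training docs.
#' @param k Add-k smoothing constant (default 1).
#' @return Named list of `sense_model` objects.
#' @export
train_sense_models <- function(anchored, tokens, k = 1) {
  sizes <- lengths(anchored)
  if (any(sizes == 0L)) {
    warning("dropping sense(s) with no training abstracts: ",
            paste(names(anchored)[sizes == 0L], collapse = ", "), call. = FALSE)
    anchored <- anchored[sizes > 0L]
  }
  if (length(anchored) == 0L) stop("no sense has any training abstract", call. = FALSE)
  all_docs <- unlist(anchored, use.names = FALSE)
  if (anyDuplicated(all_docs)) {
    stop("training sets of different senses overlap", call. = FALSE)
  }
  lapply(stats::setNames(names(anchored), names(anchored)), function(sid) {
    new_sense_model(sid, anchored[[sid]], tokens, k)
  })
}

new_sense_model <- function(sense_id, doc_ids, tokens, k) {
  w1 <- character(0); w2 <- character(0)
  for (d in doc_ids) {
    for (s in token_seqs(tokens[[d]])) {
      if (length(s) == 0L) next
      s2 <- c("<s>", s, "</s>")
      w1 <- c(w1, s2[-length(s2)])
      w2 <- c(w2, s2[-1L])
    }
  }
  if (length(w1) == 0L) stop("sense '", sense_id, "' has no training tokens", call. = FALSE)
  bigram_counts <- table(paste(w1, w2, sep = "\r"))
  context_counts <- table(w1)
  vocab_words <- setdiff(unique(c(w1, w2)), c("<s>", "</s>"))
  structure(list(
    sense_id = sense_id,
    vocab_words = vocab_words,
    # predicted-token space: vocabulary plus sentence-end marker plus UNK
    vspace = length(vocab_words) + 2L,
    bigram_counts = bigram_counts,
    context_counts = context_counts,
    k = k,
    training_doc_ids = doc_ids
  ), class = "sense_model")
}

#' @export
print.sense_model <- function(x, ...) {
  cat(sprintf("<sense model '%s': %d training docs, |V| = %d, k = %g>\n",
              x$sense_id, length(x$training_doc_ids),
              length(x$vocab_words), x$k))
  invisible(x)
}

#' Smoothed bigram probability under a sense model
#'
#' `P(w2 | w1) = (c(w1, w2) + k) / (c(w1) + k * V)` where `V` is the size
#' of the predicted-token space (vocabulary plus end marker plus UNK).
#' Out-of-vocabulary words are mapped to UNK. For every context the
#' probabilities sum to 1 over the predicted space.
#'
#' @param model A `sense_model`.
#' @param w1,w2 Tokens (use `"<s>"` / `"</s>"` for sentence boundaries).
#' @return Probability in (0, 1).
#' @export
bigram_prob <- function(model, w1, w2) {
  specials <- c("<s>", "</s>")
  if (!(w1 %in% c(model$vocab_words, specials))) w1 <- "<unk>"
  if (!(w2 %in% c(model$vocab_words, specials))) w2 <- "<unk>"
  c12 <- model$bigram_counts[paste(w1, w2, sep = "\r")]
  c12 <- if (is.na(c12)) 0 else as.numeric(c12)
  c1 <- model$context_counts[w1]
  c1 <- if (is.na(c1)) 0 else as.numeric(c1)
  (c12 + model$k) / (c1 + model$k * model$vspace)
}

#' Score an abstract under a sense model
#'
#' Mean per-token log probability of the document (title plus body
#' sentences) under the model, with out-of-vocabulary tokens mapped to UNK
#' and each sentence started from the `<s>` marker. The mean (rather than
#' the sum) normalizes for abstract length. An empty document scores
#' `-Inf`.
#'
#' @param model A `sense_model`.
#' @param record A tokenized entry or one-row corpus.
#' @return Finite numeric score for non-empty documents; `-Inf` otherwise.
#' @export
score_abstract <- function(model, record) {
  entry <- as_token_entry(record)
  lp <- numeric(0)
  for (s in token_seqs(entry)) {
    if (length(s) == 0L) next
    s[!(s %in% model$vocab_words)] <- "<unk>"
    prev <- c("<s>", s[-length(s)])
    c12 <- as.numeric(model$bigram_counts[paste(prev, s, sep = "\r")])
    c12[is.na(c12)] <- 0
    c1 <- as.numeric(model$context_counts[prev])
    c1[is.na(c1)] <- 0
    lp <- c(lp, log((c12 + model$k) / (c1 + model$k * model$vspace)))
  }
  if (length(lp) == 0L) return(-Inf)
  mean(lp)
}

#' Choose the most likely sense for an abstract
#'
#' Applies every sense model and picks the arg-max of [score_abstract()].
#' Exact ties yield `"ambiguous"`.
#'
#' @param record A tokenized entry or one-row corpus.
#' @param models Named list of `sense_model`s (at least one).
#' @return The winning sense id, or `"ambiguous"` on a tie, with the score
#'   vector attached as attribute `"scores"`.
#' @export
disambiguate <- function(record, models) {
  if (length(models) == 0L) stop("need at least one sense model", call. = FALSE)
  entry <- as_token_entry(record)
  scores <- vapply(models, score_abstract, numeric(1), record = entry)
  top <- which(scores == max(scores))
  out <- if (length(top) > 1L) "ambiguous" else names(models)[top]
  attr(out, "scores") <- scores
  out
}

#' Retrieve and disambiguate the Full Set for a gene
#'
#' Runs the whole retrieval + disambiguation stage: retrieves candidates,
#' discovers rival senses from abbreviation-expansion pairs, anchors
#' abstracts, trains per-sense bigram models, and assigns every remaining
#' abstract to its most likely sense. Abstracts assigned to rival senses
#' are excluded; exact ties are set aside as ambiguous. When no rival
#' sense is discoverable (no expansion of any kind found), all candidate
#' abstracts default to the gene sense, with a warning.
#'
#' @param expansion A `query_expansion`.
#' @param corpus An `abstract_corpus` (ignored when `tokens` is given).
#' @param k Add-k smoothing for the sense models.
#' @param tokens Optional pre-computed [corpus_tokens()] list.
#' @return An object of class `full_set`: list with `gene_id`, `doc_ids`
#'   (gene abstracts), `ambiguous_doc_ids`, `assignments` (tibble of
#'   doc_id / assignment / score), `retrieved`, `rivals` and `models`.
#' @export
egrab <- function(expansion, corpus = NULL, k = 1, tokens = NULL) {
  tokens <- tokens %||% corpus_tokens(corpus)
  cand <- retrieve(expansion, tokens = tokens)
  empty_assign <- tibble::tibble(doc_id = character(0),
                                 assignment = character(0),
                                 score = numeric(0))
  if (length(cand) == 0L) {
    return(structure(list(gene_id = expansion$gene_id, doc_ids = character(0),
                          ambiguous_doc_ids = character(0),
                          assignments = empty_assign, retrieved = character(0),
                          rivals = list(), models = list()),
                     class = "full_set"))
  }
  pairs <- discover_senses(expansion, tokens, cand)
  rival_lf <- unique(pairs$long_form[!pairs$is_gene])
  rivals <- stats::setNames(as.list(rival_lf), rival_lf)

  anchor <- vapply(cand, function(d) {
    a <- anchor_assign(tokens[[d]], expansion, rivals)
    if (is.na(a)) NA_character_ else a
  }, "")

  doc_id <- character(0); assignment <- character(0); score <- numeric(0)
  add <- function(d, a, s) {
    doc_id <<- c(doc_id, d); assignment <<- c(assignment, a); score <<- c(score, s)
  }
  gene_anchor_docs <- cand[!is.na(anchor) & anchor == "gene"]
  for (d in gene_anchor_docs) add(d, "anchor", NA_real_)

  unanchored <- cand[is.na(anchor)]
  models <- list()
  if (length(rivals) == 0L) {
    if (length(unanchored)) {
      warning("no rival sense expansion discoverable; assigning all ",
              length(unanchored),
              " unanchored abstract(s) to the gene sense by default",
              call. = FALSE)
      for (d in unanchored) add(d, "default", NA_real_)
    }
  } else {
    rival_anchors <- lapply(names(rivals), function(rid) {
      cand[!is.na(anchor) & anchor == rid]
    })
    names(rival_anchors) <- names(rivals)
    anchored <- c(list(gene = gene_anchor_docs), rival_anchors)
    models <- tryCatch(train_sense_models(anchored, tokens, k = k),
                       error = function(e) list())
    if (!("gene" %in% names(models)) || length(models) < 2L) {
      warning("fewer than two trainable senses; assigning ",
              length(unanchored),
              " unanchored abstract(s) to the gene sense by default",
              call. = FALSE)
      for (d in unanchored) add(d, "default", NA_real_)
    } else {
      for (d in unanchored) {
        sense <- disambiguate(tokens[[d]], models)
        sc <- attr(sense, "scores")[["gene"]]
        if (sense == "gene") add(d, "lm", sc)
        else if (sense == "ambiguous") add(d, "ambiguous", sc)
        # rival-assigned docs are excluded from the Full Set
      }
    }
  }
  amb <- doc_id[assignment == "ambiguous"]
  keep <- assignment != "ambiguous"
  structure(list(
    gene_id = expansion$gene_id,
    doc_ids = doc_id[keep],
    ambiguous_doc_ids = amb,
    assignments = tibble::tibble(doc_id = doc_id, assignment = assignment,
                                 score = score),
    retrieved = cand,
    rivals = rivals,
    models = models
  ), class = "full_set")
}

#' @export
print.full_set <- function(x, ...) {
  cat(sprintf("<Full Set for gene %s: %d abstracts (%d retrieved, %d ambiguous, %d rival senses)>\n",
              x$gene_id, length(x$doc_ids), length(x$retrieved),
              length(x$ambiguous_doc_ids), length(x$rivals)))
  invisible(x)
}
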