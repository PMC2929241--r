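# Evidence sentences: for each iTerm, every About-Set sentence containing
# the term (via any surface form of its lexeme), ranked by a rudimentary
# within-sentence score - the gene in initial position and the term close
# to the gene rank a sentence higher - plus species tagging of abstracts.

#' Default evidence-ranking weights
#'
#' @param w_position Weight of the gene-in-initial-position indicator.
#' @param w_proximity Weight of the proximity component
#'   `1 / (1 + distance)`.
#' @param k_initial A gene mention starting within the first `k_initial`
#'   tokens counts as initial (subject) position.
#' @return A named list.
#' @export
evidence_weights <- function(w_position = 1, w_proximity = 1, k_initial = 3L) {
  list(w_position = w_position, w_proximity = w_proximity,
       k_initial = as.integer(k_initial))
}

# start positions of term occurrences in one token vector
term_positions <- function(toks, keys, term, type, kb = NULL) {
  if (type == "unigram") return(which(keys == term))
  if (type == "bigram") {
    parts <- strsplit(term, " ", fixed = TRUE)[[1L]]
    if (length(toks) < 2L) return(integer(0))
    i <- seq_len(length(toks) - 1L)
    return(i[keys[i] == parts[1L] & keys[i + 1L] == parts[2L]])
  }
  # kb: exact surface phrase
  ph <- strsplit(term, " ", fixed = TRUE)[[1L]]
  mp <- match_positions(toks, list(ph))
  mp$pos
}

#' Score a sentence for a (gene, term) pair
#'
#' `score = w_position * [gene within first k tokens] +
#'  w_proximity / (1 + min token distance between gene and term)`.
#' Sentences without a gene mention score 0 and always rank below
#' sentences with one. The score depends only on within-sentence features.
#'
#' @param tokens Token vector of the sentence.
#' @param expansion A `query_expansion`.
#' @param term Term string (lexeme key / key pair / kb phrase).
#' @param type Term type: `"unigram"`, `"bigram"` or `"kb"`.
#' @param weights From [evidence_weights()].
#' @return Numeric score with attributes `has_gene`, `gene_initial` and
#'   `distance`.
#' @export
rank_sentence <- function(tokens, expansion, term, type = "unigram",
                          weights = evidence_weights()) {
  keys <- keys_for(tokens)
  tp <- term_positions(tokens, keys, term, type)
  if (length(tp) == 0L) stop("sentence does not contain the term", call. = FALSE)
  gp <- match_positions(tokens, expansion$variant_tokens)$pos
  if (length(gp) == 0L) {
    return(structure(0, has_gene = FALSE, gene_initial = FALSE,
                     distance = NA_integer_))
  }
  gene_initial <- any(gp <= weights$k_initial)
  dist <- min(abs(outer(gp, tp, "-")))
  score <- weights$w_position * gene_initial +
    weights$w_proximity / (1 + dist)
  structure(score, has_gene = TRUE, gene_initial = gene_initial,
            distance = as.integer(dist))
}

#' Evidence sentences for one term
#'
#' All About-Set body sentences containing any surface form of the term's
#' lexeme, ranked by [rank_sentence()]; sentences without a gene mention
#' rank below all sentences with one. Ties break by (doc_id, sentence
#' index). The `highlighted` column brackets the term (`[...]`) and the
#' gene (`{...}`) in the tokenized sentence.
#'
#' @param term Term string.
#' @param type Term type.
#' @param about An `about_set` or character vector of doc ids.
#' @param tokens A [corpus_tokens()] list.
#' @param expansion A `query_expansion`.
#' @param weights From [evidence_weights()].
#' @return A tibble with one row per evidence sentence, ranked.
#' @export
find_sentences <- function(term, type, about, tokens, expansion,
                           weights = evidence_weights()) {
  ids <- if (inherits(about, "about_set")) about$doc_ids else as.character(about)
  rows <- list()
  for (d in ids) {
    entry <- tokens[[d]]
    for (si in seq_along(entry$sent_tokens)) {
      toks <- entry$sent_tokens[[si]]
      if (length(toks) == 0L) next
      keys <- keys_for(toks)
      tp <- term_positions(toks, keys, term, type)
      if (length(tp) == 0L) next
      gp_df <- match_positions(toks, expansion$variant_tokens)
      has_gene <- nrow(gp_df) > 0L
      gene_initial <- has_gene && any(gp_df$pos <= weights$k_initial)
      dist <- if (has_gene) min(abs(outer(gp_df$pos, tp, "-"))) else NA_integer_
      score <- if (has_gene) {
        weights$w_position * gene_initial + weights$w_proximity / (1 + dist)
      } else 0
      tlen <- if (type == "bigram") 2L else length(strsplit(term, " ")[[1L]])
      hl <- toks
      for (p in tp) {
        e <- min(p + (if (type == "unigram") 1L else tlen) - 1L, length(hl))
        hl[p] <- paste0("[", hl[p]); hl[e] <- paste0(hl[e], "]")
      }
      if (has_gene) {
        for (r in seq_len(nrow(gp_df))) {
          p <- gp_df$pos[r]; e <- p + gp_df$len[r] - 1L
          hl[p] <- paste0("{", hl[p]); hl[e] <- paste0(hl[e], "}")
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = term, doc_id = d, sentence_index = si, score = score,
        has_gene = has_gene, gene_initial = gene_initial,
        distance = as.integer(dist),
        sentence = entry$sentences[si],
        highlighted = paste(hl, collapse = " ")
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(term = character(0), doc_id = character(0),
                          sentence_index = integer(0), score = numeric(0),
                          has_gene = logical(0), gene_initial = logical(0),
                          distance = integer(0), sentence = character(0),
                          highlighted = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(-out$has_gene, -out$score, out$doc_id, out$sentence_index), ]
}

#' Evidence sentences for the top iTerms
#'
#' @param iterms An `iterm_list`.
#' @param about An `about_set`.
#' @param tokens A [corpus_tokens()] list.
#' @param expansion A `query_expansion`.
#' @param top_n How many top-ranked terms to collect evidence for.
#' @param weights From [evidence_weights()].
#' @return A tibble of ranked evidence sentences for all selected terms.
#' @export
evidence_for <- function(iterms, about, tokens, expansion, top_n = 20L,
                         weights = evidence_weights()) {
  sel <- utils::head(iterms[order(iterms$rank), ], top_n)
  parts <- lapply(seq_len(nrow(sel)), function(i) {
    find_sentences(sel$term[i], sel$type[i], about, tokens, expansion, weights)
  })
  do.call(rbind, parts)
}

#' Read the species configuration
#'
#' YAML mapping each species label to its aliases (common names and Latin
#' binomials). The shipped default covers human, chicken, cattle, mouse
#' and pig.
#'
#' @param path Optional path to a species YAML.
#' @return Named list label -> character vector of aliases.
#' @export
read_species_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "species.yaml", package = "itermine")
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(x) tolower(unlist(x)))
}

#' Tag an abstract with the species it mentions
#'
#' A species label is attached when one of its names or aliases occurs in
#' the title, the body, or the MeSH descriptors. No gene-species linkage
#' is inferred; the tag only records that the species is mentioned.
#'
#' @param record A tokenized entry or one-row corpus.
#' @param species Species configuration from [read_species_config()].
#' @return Character vector of species labels (possibly empty).
#' @export
tag_species <- function(record, species = read_species_config()) {
  entry <- as_token_entry(record)
  mesh <- tolower(entry$mesh %||% character(0))
  hit <- vapply(names(species), function(lab) {
    aliases <- species[[lab]]
    atoks <- lapply(aliases, tokenize)
    atoks <- atoks[lengths(atoks) > 0L]
    if (length(atoks) && doc_contains(entry, atoks)) return(TRUE)
    any(vapply(aliases, function(a) {
      any(grepl(a, mesh, fixed = TRUE))
    }, logical(1)))
  }, logical(1))
  names(species)[hit]
}
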