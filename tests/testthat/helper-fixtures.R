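# Shared fixtures: tiny lexica, corpora and an independent brute-force
# ranking oracle. All fixtures are built in code.

# a one-gene lexicon tibble (entries across species share the symbol)
fixture_lexicon <- function(symbol = "GRO", name = "groucho protein",
                            synonyms = list(`9606` = "groucho")) {
  taxa <- names(synonyms)
  tibble::tibble(
    tax_id = taxa,
    gene_id = paste0("G", seq_along(taxa)),
    symbol = rep(symbol, length(taxa)),
    synonyms = unname(lapply(synonyms, as.character)),
    name = rep(name, length(taxa))
  )
}

fixture_expansion <- function(names = c("gro", "groucho")) {
  lex <- tibble::tibble(tax_id = "9606", gene_id = "G1",
                        symbol = names[1],
                        synonyms = list(names[-1]),
                        name = names[length(names)])
  expand_query(lex)
}

# corpus whose documents are given as body strings
fixture_corpus <- function(bodies, titles = NULL, ids = NULL) {
  n <- length(bodies)
  corpus(ids %||% sprintf("d%02d", seq_len(n)),
         titles %||% rep("A title", n),
         bodies)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent brute-force iTerm ranking: plain loops recompute per-document
# term presence, document frequencies, the score, the bigram gate and the
# sort, without going through document_frequencies()/rank_iterms().
oracle_rank_iterms <- function(atoks, btoks, stopwords, n_b = length(btoks),
                               bigram_min_df_b = 10) {
  doc_units <- function(entry) {
    segs <- c(list(entry$title_tokens), entry$sent_tokens)
    uni <- character(0); bi <- character(0)
    for (s in segs) {
      if (length(s) == 0) next
      keep <- !(s %in% stopwords) & nchar(s) > 1 & !grepl("^[0-9]+$", s)
      ks <- lexeme_of(s)
      uni <- c(uni, ks[keep])
      if (length(s) >= 2) {
        for (i in seq_len(length(s) - 1)) {
          if (keep[i] && keep[i + 1]) bi <- c(bi, paste(ks[i], ks[i + 1]))
        }
      }
    }
    list(uni = unique(uni), bi = unique(bi))
  }
  a_units <- lapply(atoks, doc_units)
  b_units <- lapply(btoks, doc_units)
  n_a <- length(atoks)
  terms <- unique(unlist(lapply(a_units, `[[`, "uni")))
  bigrams <- unique(unlist(lapply(a_units, `[[`, "bi")))
  row <- function(t, type) {
    fld <- if (type == "unigram") "uni" else "bi"
    df_a <- sum(vapply(a_units, function(u) t %in% u[[fld]], logical(1)))
    df_b <- sum(vapply(b_units, function(u) t %in% u[[fld]], logical(1)))
    if (type == "bigram" && df_b < bigram_min_df_b) return(NULL)
    if (df_b < 1) df_b <- 1
    s <- (df_a / n_a - df_b / n_b) * log(n_b / df_b)
    if (s <= 0) return(NULL)
    data.frame(term = t, type = type, df_a = df_a, df_b = df_b, score = s,
               stringsAsFactors = FALSE)
  }
  rows <- c(lapply(terms, row, type = "unigram"),
            lapply(bigrams, row, type = "bigram"))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(term = character(0), type = character(0),
                      df_a = integer(0), df_b = integer(0), score = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(-out$score, out$term, out$type), , drop = FALSE]
}
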