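# Seeded synthetic corpora with known ground truth. Documents are bags of
# sentences over pseudo-word vocabularies with Zipf-like baseline
# frequencies (so document-frequency tails are realistic and the damping
# factor matters). Three generators cover the three study designs:
#   generate_background       - a generic gene/protein background
#   generate_gene_corpus      - a gene's literature with planted enriched
#                               terms and planted focus/passing structure
#   generate_ambiguous_corpus - an ambiguous short name with 2+ senses of
#                               divergent vocabulary, anchor abstracts and
#                               abbreviation-expansion parentheticals
# Identical (config, seed) always yields byte-identical corpora.

#' Generator configuration
#'
#' Defaults define the benchmark conditions used throughout the package's
#' tests: a 1000-abstract background, a 60-abstract gene set of which 70%
#' focus on the gene, five planted terms included with probability 0.6 in
#' focused gene abstracts versus 0.05 in the background, and a two-sense
#' ambiguity benchmark with 150 documents per sense, a 0.3 anchor fraction
#' and high vocabulary divergence.
#'
#' @param seed Integer seed; every generator call is deterministic in
#'   (config, seed).
#' @param background_size Number of background abstracts.
#' @param gene_size Number of abstracts in the gene corpus.
#' @param focus_fraction Fraction of gene abstracts that focus on the gene.
#' @param vocab_size Size of the baseline pseudo-word vocabulary.
#' @param planted_terms Terms enriched in the gene's literature.
#' @param p_planted_about Per-document inclusion probability of each
#'   planted term in focused gene abstracts.
#' @param p_planted_background Per-document inclusion probability of each
#'   planted term in the background (and in passing gene abstracts).
#' @param gene_names The gene's names (first name is the primary mention).
#' @param position_fractions Distribution of focus-document mention
#'   placement over `title`, `first`, `last` and `count` (>= 3 scattered
#'   mentions).
#' @param sentences_per_doc,words_per_sentence Ranges sampled per document.
#' @param ambiguity List describing the ambiguous-name benchmark:
#'   `short_name`, `gene_names` (short + long form of the gene sense),
#'   `rivals` (expansion phrases of rival senses), `docs_per_sense`,
#'   `anchor_fraction` and `divergence` (`"low"`, `"med"` or `"high"`,
#'   i.e. 0.2 / 0.5 / 0.8 sense-exclusive vocabulary).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 7L,
                             background_size = 1000L,
                             gene_size = 60L,
                             focus_fraction = 0.7,
                             vocab_size = 2000L,
                             planted_terms = c("talfexin", "morvadin",
                                               "cretosome", "plaudicin",
                                               "vextrase"),
                             p_planted_about = 0.6,
                             p_planted_background = 0.05,
                             gene_names = c("tlf9", "talforin"),
                             position_fractions = c(title = 0.4, first = 0.2,
                                                    last = 0.2, count = 0.2),
                             sentences_per_doc = 3:6,
                             words_per_sentence = 8:14,
                             ambiguity = list(
                               short_name = "gro",
                               gene_names = c("gro", "groucho"),
                               rivals = c("gasoline range organics"),
                               docs_per_sense = 150L,
                               anchor_fraction = 0.3,
                               divergence = "high")) {
  probs <- c(p_planted_about, p_planted_background,
             ambiguity$anchor_fraction, focus_fraction, position_fractions)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!ambiguity$divergence %in% c("low", "med", "high")) {
    stop("divergence must be one of 'low', 'med', 'high'", call. = FALSE)
  }
  if (abs(sum(position_fractions) - 1) > 1e-8) {
    stop("position_fractions must sum to 1", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    background_size = as.integer(background_size),
    gene_size = as.integer(gene_size),
    focus_fraction = focus_fraction,
    vocab_size = as.integer(vocab_size),
    planted_terms = planted_terms,
    p_planted_about = p_planted_about,
    p_planted_background = p_planted_background,
    gene_names = gene_names,
    position_fractions = position_fractions,
    sentences_per_doc = sentences_per_doc,
    words_per_sentence = words_per_sentence,
    ambiguity = ambiguity
  ), class = "generator_config")
}

# deterministic pseudo-word vocabulary with Zipf sampling weights;
# reserved words (triggers, gene names, planted terms, rival expansions)
# are excluded so mentions are only where the generator puts them
synth_vocab <- function(config) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  # fixed enumeration (no RNG): the same vocabulary backs every corpus of a run
  words <- unique(as.vector(outer(syl, rev(syl), paste0)))
  reserved <- tolower(c("gene", "genes", "protein", "proteins",
                        config$planted_terms, config$gene_names,
                        config$ambiguity$gene_names,
                        unlist(strsplit(unlist(config$ambiguity$rivals), "\\s+"))))
  words <- setdiff(words, reserved)
  words <- utils::head(words, config$vocab_size)
  list(words = words, probs = (1 / seq_along(words)) / sum(1 / seq_along(words)))
}

sample_sentence <- function(vocab, probs, n_words) {
  sample(vocab, n_words, replace = TRUE, prob = probs)
}

# sample one element of x (safe for length-1 vectors, unlike sample(x, 1))
pick <- function(x) x[sample.int(length(x), 1L)]

cap_first <- function(words) {
  words[1L] <- paste0(toupper(substr(words[1L], 1L, 1L)), substr(words[1L], 2L, nchar(words[1L])))
  words
}

join_sentences <- function(sent_words) {
  paste(vapply(sent_words, function(w) paste0(paste(cap_first(w), collapse = " "), "."), ""),
        collapse = " ")
}

#' Generate a generic gene/protein background corpus
#'
#' Every title contains one of the trigger words gene(s)/protein(s);
#' bodies are Zipf-sampled sentences; each planted term is included in a
#' document with probability `p_planted_background`, so empirical
#' background document frequencies concentrate near that baseline.
#'
#' @param config A `generator_config`.
#' @return An `abstract_corpus` of `background_size` documents.
#' @export
generate_background <- function(config) {
  set.seed(config$seed)
  v <- synth_vocab(config)
  n <- config$background_size
  if (n == 0L) return(corpus(character(0), character(0), character(0)))
  triggers <- c("gene", "genes", "protein", "proteins")
  ids <- sprintf("bg%05d", seq_len(n))
  titles <- character(n); bodies <- character(n)
  mesh <- rep(list(character(0)), n)
  for (i in seq_len(n)) {
    tw <- sample_sentence(v$words, v$probs, 4L)
    trg <- sample(triggers, 1L)
    titles[i] <- paste(cap_first(c(tw[1L], trg, "of", tw[2L], tw[3L])), collapse = " ")
    ns <- pick(config$sentences_per_doc)
    sent <- lapply(seq_len(ns), function(j) {
      sample_sentence(v$words, v$probs, pick(config$words_per_sentence))
    })
    for (t in config$planted_terms) {
      if (stats::runif(1L) < config$p_planted_background) {
        j <- sample(ns, 1L)
        pos <- sample(length(sent[[j]]) + 1L, 1L)
        sent[[j]] <- append(sent[[j]], t, after = pos - 1L)
      }
    }
    bodies[i] <- join_sentences(sent)
    if (stats::runif(1L) < 0.3) {
      mesh[[i]] <- sample(c("Mice", "Humans", "Animals", "Cells, Cultured"), 1L)
    }
  }
  corpus(ids, titles, bodies, mesh)
}

#' Generate a gene corpus with planted structure
#'
#' Produces `gene_size` abstracts mentioning the gene. A `focus_fraction`
#' of them focus on it: the mention is planted in the title, the first or
#' the last sentence, or at least three mentions are scattered through the
#' body, following `position_fractions`. The remainder mention the gene
#' exactly once in a middle sentence ("passing"), so they fail the
#' About-Set rule by construction. Planted terms appear with probability
#' `p_planted_about` in focused documents and `p_planted_background`
#' otherwise.
#'
#' @param config A `generator_config`.
#' @return A list with `corpus` (an `abstract_corpus`), `truth` (tibble of
#'   `doc_id`, `focus`, `mode`, `n_mentions`) and `planted_keys` (lexeme
#'   keys of the planted terms).
#' @export
generate_gene_corpus <- function(config) {
  set.seed(config$seed + 1L)
  v <- synth_vocab(config)
  n <- config$gene_size
  n_focus <- round(config$focus_fraction * n)
  gene <- config$gene_names[1L]
  modes <- character(n)
  if (n_focus > 0L) {
    modes[seq_len(n_focus)] <- sample(names(config$position_fractions), n_focus,
                                      replace = TRUE,
                                      prob = config$position_fractions)
  }
  if (n_focus < n) modes[(n_focus + 1L):n] <- "passing"
  ids <- sprintf("gn%04d", seq_len(n))
  titles <- character(n); bodies <- character(n); n_mentions <- integer(n)
  mesh <- rep(list(character(0)), n)
  for (i in seq_len(n)) {
    ns <- pick(config$sentences_per_doc)
    sent <- lapply(seq_len(ns), function(j) {
      sample_sentence(v$words, v$probs, pick(config$words_per_sentence))
    })
    tw <- sample_sentence(v$words, v$probs, 4L)
    title_words <- c(tw[1L], tw[2L], "and", tw[3L])
    p_term <- if (modes[i] == "passing") config$p_planted_background else config$p_planted_about
    for (t in config$planted_terms) {
      if (stats::runif(1L) < p_term) {
        j <- sample(ns, 1L)
        pos <- sample(length(sent[[j]]) + 1L, 1L)
        sent[[j]] <- append(sent[[j]], t, after = pos - 1L)
      }
    }
    insert_gene <- function(j, mid_only = FALSE) {
      w <- sent[[j]]
      lo <- if (mid_only) 2L else 1L
      hi <- if (mid_only) max(lo, length(w) - 1L) else length(w) + 1L
      pos <- pick(lo:hi)
      sent[[j]] <<- append(w, gene, after = pos - 1L)
    }
    if (modes[i] == "title") {
      title_words <- c(gene, title_words[-1L])
      n_mentions[i] <- 1L
    } else if (modes[i] == "first") {
      insert_gene(1L); n_mentions[i] <- 1L
    } else if (modes[i] == "last") {
      insert_gene(ns); n_mentions[i] <- 1L
    } else if (modes[i] == "count") {
      k <- sample(3:5, 1L)
      for (r in seq_len(k)) insert_gene(sample(ns, 1L))
      n_mentions[i] <- k
    } else { # passing: one mention, mid-body, not first/last sentence
      j <- if (ns >= 3L) pick(2:(ns - 1L)) else 2L
      insert_gene(j, mid_only = TRUE)
      n_mentions[i] <- 1L
    }
    titles[i] <- paste(cap_first(title_words), collapse = " ")
    bodies[i] <- join_sentences(sent)
    if (stats::runif(1L) < 0.4) {
      mesh[[i]] <- sample(c("Mice", "Humans", "Sus scrofa"), 1L)
    }
  }
  truth <- tibble::tibble(doc_id = ids, focus = modes != "passing",
                          mode = modes, n_mentions = n_mentions)
  list(corpus = corpus(ids, titles, bodies, mesh),
       truth = truth,
       planted_keys = lexeme_of(tolower(config$planted_terms)))
}

#' Generate an ambiguous-name corpus with sense ground truth
#'
#' Every document mentions the shared short name. Documents of the gene
#' sense sample the gene topic's vocabulary; each rival sense has its own
#' topic. A `divergence` fraction of each sense's tokens comes from
#' sense-exclusive vocabulary (0.2 / 0.5 / 0.8 for low / med / high). An
#' `anchor_fraction` of gene-sense documents also mention the gene's long
#' name (two-name anchor); the same fraction of rival documents spell out
#' the rival expansion with a parenthetical abbreviation pattern.
#'
#' @param config A `generator_config`.
#' @return A list with `corpus` and `truth` (tibble of `doc_id`, `sense`,
#'   `anchor`).
#' @export
generate_ambiguous_corpus <- function(config) {
  set.seed(config$seed + 2L)
  amb <- config$ambiguity
  if (length(amb$rivals) < 1L && amb$docs_per_sense > 0L) {
    # single-sense degenerate case: all docs are trivially the gene sense
  }
  div <- c(low = 0.2, med = 0.5, high = 0.8)[[amb$divergence]]
  v <- synth_vocab(config)
  senses <- c("gene", unlist(amb$rivals))
  n_sense <- length(senses)
  # shared block + one exclusive block per sense
  n_shared <- floor(length(v$words) / 2)
  shared <- v$words[seq_len(n_shared)]
  rest <- v$words[(n_shared + 1L):length(v$words)]
  block <- floor(length(rest) / n_sense)
  excl <- lapply(seq_len(n_sense), function(s) rest[((s - 1L) * block + 1L):(s * block)])
  zipf <- function(k) (1 / seq_len(k)) / sum(1 / seq_len(k))
  p_shared <- zipf(length(shared))
  short <- tolower(amb$short_name)
  long_gene <- tolower(amb$gene_names[amb$gene_names != short][1L])
  ids <- character(0); titles <- character(0); bodies <- character(0)
  sense_lab <- character(0); anchor_lab <- logical(0)
  idx <- 0L
  for (s in seq_len(n_sense)) {
    p_excl <- zipf(length(excl[[s]]))
    for (d in seq_len(amb$docs_per_sense)) {
      idx <- idx + 1L
      ns <- pick(config$sentences_per_doc)
      sent <- lapply(seq_len(ns), function(j) {
        nw <- pick(config$words_per_sentence)
        from_excl <- stats::runif(nw) < div
        w <- character(nw)
        if (any(from_excl)) {
          w[from_excl] <- sample(excl[[s]], sum(from_excl), replace = TRUE, prob = p_excl)
        }
        if (any(!from_excl)) {
          w[!from_excl] <- sample(shared, sum(!from_excl), replace = TRUE, prob = p_shared)
        }
        w
      })
      is_anchor <- stats::runif(1L) < amb$anchor_fraction
      # every document mentions the short name
      j <- sample(ns, 1L)
      sent[[j]] <- append(sent[[j]], short, after = sample(length(sent[[j]]) + 1L, 1L) - 1L)
      first_sentence_override <- NULL
      if (is_anchor) {
        if (s == 1L) {
          j2 <- sample(ns, 1L)
          sent[[j2]] <- append(sent[[j2]], long_gene,
                               after = sample(length(sent[[j2]]) + 1L, 1L) - 1L)
        } else {
          exp_words <- strsplit(senses[s], "\\s+")[[1L]]
          first_sentence_override <- paste0(
            paste(cap_first(exp_words), collapse = " "),
            " (", toupper(short), ") ",
            paste(sent[[1L]], collapse = " "), ".")
        }
      }
      body <- if (is.null(first_sentence_override)) {
        join_sentences(sent)
      } else {
        paste(c(first_sentence_override,
                vapply(sent[-1L], function(w) paste0(paste(cap_first(w), collapse = " "), "."), "")),
              collapse = " ")
      }
      tw <- sample_sentence(v$words, v$probs, 4L)
      ids <- c(ids, sprintf("am%04d", idx))
      titles <- c(titles, paste(cap_first(tw), collapse = " "))
      bodies <- c(bodies, body)
      sense_lab <- c(sense_lab, senses[s])
      anchor_lab <- c(anchor_lab, is_anchor)
    }
  }
  list(corpus = corpus(ids, titles, bodies),
       truth = tibble::tibble(doc_id = ids, sense = sense_lab, anchor = anchor_lab))
}

#' Write a complete synthetic bundle to disk
#'
#' Writes the background, gene and ambiguous corpora in the flat dialect,
#' the truth tables as TSV, and a small gene lexicon covering the
#' synthetic gene (two species entries sharing the symbol), ready for
#' [run_pipeline()] or the command-line interface.
#'
#' @param config A `generator_config`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    background = file.path(dir, "background.txt"),
    gene_corpus = file.path(dir, "gene_corpus.txt"),
    ambiguous_corpus = file.path(dir, "ambiguous_corpus.txt"),
    gene_truth = file.path(dir, "gene_truth.tsv"),
    ambiguous_truth = file.path(dir, "ambiguous_truth.tsv"),
    lexicon = file.path(dir, "lexicon.tsv")
  )
  bg <- generate_background(config)
  gc <- generate_gene_corpus(config)
  ac <- generate_ambiguous_corpus(config)
  write_corpus(bg, paths[["background"]])
  write_corpus(gc$corpus, paths[["gene_corpus"]])
  write_corpus(ac$corpus, paths[["ambiguous_corpus"]])
  utils::write.table(gc$truth, paths[["gene_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ac$truth, paths[["ambiguous_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sym <- toupper(config$gene_names[1L])
  lex <- data.frame(
    tax_id = c("9606", "10090"),
    gene_id = c("G0001", "G1001"),
    symbol = c(sym, sym),
    synonyms = c(paste(config$gene_names[-1L], collapse = "|"),
                 paste(config$gene_names[-1L], collapse = "|")),
    name = c(config$gene_names[length(config$gene_names)],
             config$gene_names[length(config$gene_names)]),
    stringsAsFactors = FALSE
  )
  utils::write.table(lex, paths[["lexicon"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
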