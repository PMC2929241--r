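# Pipeline orchestration: one call runs retrieval + disambiguation, About
# Set selection, iTerm ranking, categorization and evidence collection for
# a gene, writing fullset.tsv, aboutset.tsv, iterms.tsv, evidence.tsv and
# a run log. All stages are deterministic, so identical configurations
# yield byte-identical outputs.

#' Pipeline configuration
#'
#' Paths to the inputs plus the method parameters. Defaults follow the
#' method's published settings: bigram background threshold 10, redundancy
#' threshold 75%, About-Set mention threshold 3, low-data warning at 50
#' documents.
#'
#' @param corpus,background,lexicon Paths to the gene corpus, background
#'   corpus and gene lexicon TSV.
#' @param out_dir Output directory.
#' @param corpus_format,background_format `"flat"` or `"medline-xml"`.
#' @param stopwords,kb_terms,scheme,species Optional paths overriding the
#'   packaged stopword list, knowledge-base term list, category scheme and
#'   species configuration.
#' @param smoothing_k Add-k smoothing of the sense models.
#' @param bigram_min_df_b Background support threshold for bigrams.
#' @param redundancy_threshold Unigram-vs-bigram redundancy threshold.
#' @param about_min_mentions About-Set mention-count threshold.
#' @param low_data_warning About-Set size below which a warning is logged.
#' @param log_base Damping log base of the term score.
#' @param evidence_top_n Number of top terms to collect evidence for.
#' @param weights Evidence-ranking weights, see [evidence_weights()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus, background, lexicon, out_dir,
                            corpus_format = "flat", background_format = "flat",
                            stopwords = NULL, kb_terms = NULL, scheme = NULL,
                            species = NULL,
                            smoothing_k = 1, bigram_min_df_b = 10L,
                            redundancy_threshold = 0.75,
                            about_min_mentions = 3L, low_data_warning = 50L,
                            log_base = exp(1), evidence_top_n = 20L,
                            weights = evidence_weights()) {
  stopifnot(bigram_min_df_b > 0, redundancy_threshold > 0,
            about_min_mentions > 0, low_data_warning > 0, smoothing_k > 0)
  structure(list(corpus = corpus, background = background, lexicon = lexicon,
                 out_dir = out_dir, corpus_format = corpus_format,
                 background_format = background_format,
                 stopwords = stopwords, kb_terms = kb_terms, scheme = scheme,
                 species = species, smoothing_k = smoothing_k,
                 bigram_min_df_b = bigram_min_df_b,
                 redundancy_threshold = redundancy_threshold,
                 about_min_mentions = about_min_mentions,
                 low_data_warning = low_data_warning, log_base = log_base,
                 evidence_top_n = evidence_top_n, weights = weights),
            class = "pipeline_config")
}

#' Run the full pipeline for one gene
#'
#' Reads the corpora and lexicon, expands the gene's names, builds the
#' Full Set (retrieval + disambiguation), selects the About Set, ranks and
#' categorizes iTerms, collects evidence sentences, and writes
#' `fullset.tsv`, `aboutset.tsv`, `iterms.tsv`, `evidence.tsv` and
#' `run.log` to the output directory. Warnings raised by the stages are
#' captured into the log (each once per trigger).
#'
#' @param config A `pipeline_config`.
#' @param gene A gene id or name resolvable in the lexicon. A query
#'   matching several genes raises an error listing the candidates.
#' @return Invisibly, a list with the stage objects and output paths.
#' @export
run_pipeline <- function(config, gene) {
  for (p in c(config$corpus, config$background, config$lexicon)) {
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  }
  loglines <- character(0)
  note <- function(...) loglines <<- c(loglines, sprintf(...))
  capture <- function(expr) {
    withCallingHandlers(expr,
      warning = function(w) {
        loglines <<- c(loglines, paste0("WARNING: ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        loglines <<- c(loglines, paste0("NOTE: ", sub("\n$", "", conditionMessage(m))))
        invokeRestart("muffleMessage")
      })
  }
  lex <- read_gene_lexicon(config$lexicon)
  entries <- gene_entries(lex, gene)
  expansion <- expand_query(entries)
  note("gene %s (%s): %d names, %d query variants", expansion$gene_id,
       expansion$symbol, length(expansion$names), length(expansion$variants))

  corp <- capture(read_corpus(config$corpus, config$corpus_format))
  bg <- capture(read_corpus(config$background, config$background_format))
  bg <- capture(build_background(bg))
  note("corpus: %d documents; background: %d documents", nrow(corp), nrow(bg))

  tokens <- corpus_tokens(corp)
  btokens <- corpus_tokens(bg)
  stop_list <- load_stopwords(config$stopwords)
  kb <- read_kb_terms(config$kb_terms)
  scheme <- read_category_scheme(config$scheme)

  full <- capture(egrab(expansion, tokens = tokens, k = config$smoothing_k))
  note("retrieved %d candidates; Full Set %d (ambiguous %d, rival senses %d)",
       length(full$retrieved), length(full$doc_ids),
       length(full$ambiguous_doc_ids), length(full$rivals))

  about <- capture(about_set(full, tokens, expansion,
                             min_mentions = config$about_min_mentions,
                             low_data = config$low_data_warning))
  note("About Set: N_a = %d", about$n_a)

  bdf <- document_frequencies(btokens, stop_list, kb)
  iterms <- rank_iterms(about, tokens, bdf, n_b = nrow(bg),
                        stopwords = stop_list, kb = kb,
                        bigram_min_df_b = config$bigram_min_df_b,
                        log_base = config$log_base)
  n_before <- nrow(iterms)
  iterms <- prune_redundant(iterms, threshold = config$redundancy_threshold)
  note("iTerms: %d ranked, %d pruned as redundant (%.1f%%)",
       nrow(iterms), n_before - nrow(iterms),
       if (n_before > 0) 100 * (n_before - nrow(iterms)) / n_before else 0)
  iterms <- group_by_category(categorize_terms(iterms, scheme), scheme)

  ev <- evidence_for(iterms, about, tokens, expansion,
                     top_n = config$evidence_top_n, weights = config$weights)
  note("evidence: %d sentences for top %d terms", nrow(ev),
       min(config$evidence_top_n, nrow(iterms)))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fullset = file.path(config$out_dir, "fullset.tsv"),
             aboutset = file.path(config$out_dir, "aboutset.tsv"),
             iterms = file.path(config$out_dir, "iterms.tsv"),
             evidence = file.path(config$out_dir, "evidence.tsv"),
             log = file.path(config$out_dir, "run.log"))
  write_fullset(full, paths[["fullset"]])
  write_aboutset(about, paths[["aboutset"]])
  write_iterms(iterms, paths[["iterms"]])
  write_evidence(ev, paths[["evidence"]])
  writeLines(loglines, paths[["log"]], useBytes = TRUE)
  invisible(list(expansion = expansion, full = full, about = about,
                 iterms = iterms, evidence = ev, paths = paths,
                 log = loglines))
}

# ---- stable TSV serialization -------------------------------------------

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", trimws(formatC(x, format = "g", digits = 8)))
}

write_stable_tsv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.list(col)) {
      vapply(col, function(v) {
        if (length(v) == 0L) return("")
        if (!is.null(names(v))) paste(sprintf("%s:%s", names(v), fmt_num(as.numeric(v))), collapse = ";")
        else paste(v, collapse = ";")
      }, "")
    } else if (is.double(col)) fmt_num(col)
    else as.character(col)
  })
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a Full Set as TSV
#' @param full A `full_set`.
#' @param path Output path.
#' @return `path` (writer) or a tibble (reader), invisibly for the writer.
#' @export
write_fullset <- function(full, path) {
  df <- full$assignments
  df <- tibble::tibble(gene_id = rep(full$gene_id, nrow(df)),
                       doc_id = df$doc_id, assignment = df$assignment,
                       score = df$score)
  amb <- setdiff(full$ambiguous_doc_ids, df$doc_id)
  if (length(amb)) {
    df <- rbind(df, tibble::tibble(gene_id = full$gene_id, doc_id = amb,
                                   assignment = "ambiguous", score = NA_real_))
  }
  write_stable_tsv(df, path)
}

#' @rdname write_fullset
#' @export
read_fullset <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character", quote = "")
  tibble::tibble(gene_id = df$gene_id, doc_id = df$doc_id,
                 assignment = df$assignment,
                 score = suppressWarnings(as.numeric(df$score)))
}

#' Write / read an About Set as TSV
#' @param about An `about_set`.
#' @param path Output path.
#' @return `path` (writer) or an `about_set` (reader).
#' @export
write_aboutset <- function(about, path) {
  write_stable_tsv(tibble::tibble(gene_id = rep(about$gene_id, about$n_a),
                                  doc_id = about$doc_ids), path)
}

#' @rdname write_aboutset
#' @export
read_aboutset <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character", quote = "")
  structure(list(gene_id = df$gene_id[1], doc_ids = df$doc_id,
                 n_a = nrow(df)), class = "about_set")
}

#' Write / read an iTerm list as TSV
#' @param iterms An `iterm_list` (optionally categorized).
#' @param path Output path.
#' @return `path` (writer) or a tibble (reader).
#' @export
write_iterms <- function(iterms, path) {
  df <- iterms
  if (!"category" %in% names(df)) df$category <- ""
  df <- df[, c("rank", "term", "display", "type", "df_a", "df_b", "score",
               "category", "bigrams")]
  write_stable_tsv(df, path)
}

#' @rdname write_iterms
#' @export
read_iterms <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character", quote = "")
  tibble::tibble(rank = as.integer(df$rank), term = df$term,
                 display = df$display, type = df$type,
                 df_a = as.integer(df$df_a), df_b = as.integer(df$df_b),
                 score = as.numeric(df$score), category = df$category,
                 bigrams = strsplit(df$bigrams, ";", fixed = TRUE))
}

write_evidence <- function(ev, path) {
  write_stable_tsv(ev, path)
}
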