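# Gene lexicon: reading an EntrezGene gene_info-style TSV, species-restricted
# synonym collection, and expansion of names into hyphen/space variants for
# retrieval and mention counting.

#' Read a gene lexicon
#'
#' Expects a UTF-8 TSV with header columns `tax_id`, `gene_id`, `symbol`,
#' `synonyms` (pipe-separated, `-` for none) and `name`. One row per
#' (gene, species) entry; a logical gene may have entries in several
#' species sharing the same symbol.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `synonyms` as a list column.
#' @export
read_gene_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("tax_id", "gene_id", "symbol", "synonyms", "name")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("lexicon is missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  syn <- lapply(df$synonyms, function(s) {
    if (is.na(s) || s %in% c("", "-")) return(character(0))
    unlist(strsplit(s, "|", fixed = TRUE))
  })
  tibble::tibble(tax_id = df$tax_id, gene_id = df$gene_id, symbol = df$symbol,
                 synonyms = syn, name = df$name)
}

#' Lexicon entries matching a query
#'
#' Case-insensitive match of a query against gene ids, symbols, official
#' names and synonyms. Mirrors a search page: all matching entries are
#' returned so a user can select a gene by id when the query is ambiguous.
#'
#' @param lexicon A lexicon tibble from [read_gene_lexicon()].
#' @param query A gene id or any name.
#' @return The matching rows of `lexicon`.
#' @export
lexicon_matches <- function(lexicon, query) {
  q <- tolower(trimws(query))
  hit <- lexicon$gene_id == query |
    tolower(lexicon$symbol) == q |
    tolower(lexicon$name) == q |
    vapply(lexicon$synonyms, function(s) q %in% tolower(s), logical(1))
  lexicon[hit, ]
}

#' All entries of one logical gene
#'
#' Resolves a query to a single logical gene (all species entries sharing
#' the matched symbol). If the query matches entries of more than one
#' symbol, an error of class `itermine_ambiguous_gene` is raised carrying
#' the candidate listing, so a caller can display it and ask the user to
#' select by id.
#'
#' @inheritParams lexicon_matches
#' @return The entries (rows) of the resolved gene.
#' @export
gene_entries <- function(lexicon, query) {
  hits <- lexicon_matches(lexicon, query)
  if (nrow(hits) == 0L) stop("no lexicon entry matches '", query, "'", call. = FALSE)
  # an exact gene_id match pins the gene even if the name is shared
  id_hit <- hits[hits$gene_id == query, ]
  if (nrow(id_hit) > 0L) hits <- id_hit
  symbols <- unique(tolower(hits$symbol))
  if (length(symbols) > 1L) {
    cand <- hits[, c("gene_id", "tax_id", "symbol", "name")]
    cond <- structure(
      class = c("itermine_ambiguous_gene", "error", "condition"),
      list(message = paste0(
             "query '", query, "' matches several genes; select one by id:\n",
             paste(sprintf("  %s (%s, tax %s): %s", cand$gene_id, cand$symbol,
                           cand$tax_id, cand$name), collapse = "\n")),
           call = sys.call(-1), candidates = cand)
    )
    stop(cond)
  }
  lexicon[tolower(lexicon$symbol) %in% symbols, ]
}

#' Hyphen/space variants of a name
#'
#' Returns the closure of a name under replacing each internal hyphen or
#' space boundary with a hyphen, a space, or nothing, lowercased. A name
#' with no boundary has a single variant.
#'
#' @param name A non-empty gene name.
#' @return Character vector of lowercase variants (sorted, unique).
#' @examples
#' name_variants("JAM-1")
#' name_variants("dentin phosphoprotein")
#' @export
name_variants <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  name <- tolower(gsub("\\s+", " ", trimws(name)))
  parts <- strsplit(name, "[- ]+")[[1L]]
  parts <- parts[nzchar(parts)]
  k <- length(parts) - 1L
  if (k <= 0L) return(name)
  if (k > 4L) {
    # cap combinatorial growth for very long names: uniform separators only
    return(sort(unique(c(name,
                         paste(parts, collapse = "-"),
                         paste(parts, collapse = " "),
                         paste(parts, collapse = "")))))
  }
  seps <- expand.grid(rep(list(c("-", " ", "")), k),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- vapply(seq_len(nrow(seps)), function(r) {
    s <- unlist(seps[r, ], use.names = FALSE)
    v <- parts[1L]
    for (j in seq_len(k)) v <- paste0(v, s[j], parts[j + 1L])
    v
  }, "")
  sort(unique(c(name, out)))
}

#' Species-restricted synonym collection
#'
#' A synonym is retained when it appears in an entry of a priority species
#' (human, mouse, rat by default) or in entries of at least two other
#' species. Official symbols and names of every entry are always retained.
#'
#' @param entries Entries of one logical gene (rows of a lexicon tibble).
#' @param priority_taxa Taxon ids whose synonyms are always trusted.
#' @return Character vector of retained lowercase names.
#' @export
collect_synonyms <- function(entries, priority_taxa = c("9606", "10090", "10116")) {
  if (is.null(entries) || nrow(entries) == 0L) {
    stop("empty entry set", call. = FALSE)
  }
  official <- tolower(c(entries$symbol, entries$name))
  official <- official[nzchar(official) & official != "-"]
  syn <- character(0); syn_tax <- character(0)
  for (i in seq_len(nrow(entries))) {
    s <- tolower(entries$synonyms[[i]])
    s <- s[nzchar(s) & s != "-"]
    syn <- c(syn, s)
    syn_tax <- c(syn_tax, rep(entries$tax_id[i], length(s)))
  }
  keep <- character(0)
  for (s in unique(syn)) {
    taxa <- unique(syn_tax[syn == s])
    if (any(taxa %in% priority_taxa) || length(setdiff(taxa, priority_taxa)) >= 2L) {
      keep <- c(keep, s)
    }
  }
  sort(unique(c(official, keep)))
}

#' Expand a gene's names into a retrieval query
#'
#' Takes the union of [name_variants()] over all names retained by
#' [collect_synonyms()], lowercased and deduplicated. The result carries
#' pre-tokenized variants and the base name each variant came from (used to
#' count *distinct* names for anchor assignment).
#'
#' @inheritParams collect_synonyms
#' @return An object of class `query_expansion` with elements `gene_id`,
#'   `symbol`, `names`, `variants`, `variant_tokens` and `variant_name`.
#' @export
expand_query <- function(entries, priority_taxa = c("9606", "10090", "10116")) {
  nms <- collect_synonyms(entries, priority_taxa)
  vmap <- lapply(nms, name_variants)
  variant <- unlist(vmap, use.names = FALSE)
  base <- rep(nms, lengths(vmap))
  # first base name wins when two names share a variant
  dup <- duplicated(variant)
  variant <- variant[!dup]; base <- base[!dup]
  toks <- lapply(variant, tokenize)
  ok <- lengths(toks) > 0L
  variant <- variant[ok]; base <- base[ok]; toks <- toks[ok]
  ord <- order(variant)
  # prefer a priority-taxon gene_id as the canonical id
  prio <- entries$tax_id %in% priority_taxa
  gid <- if (any(prio)) entries$gene_id[prio][1L] else entries$gene_id[1L]
  structure(list(
    gene_id = gid,
    symbol = entries$symbol[1L],
    names = nms,
    variants = variant[ord],
    variant_tokens = toks[ord],
    variant_name = base[ord]
  ), class = "query_expansion")
}

#' @export
print.query_expansion <- function(x, ...) {
  cat(sprintf("<query expansion for gene %s: %d names, %d variants>\n",
              x$gene_id, length(x$names), length(x$variants)))
  invisible(x)
}

# Distinct base names of the expansion matched anywhere in a tokenized doc.
matched_names <- function(entry, expansion) {
  hit <- character(0)
  for (s in token_seqs(entry)) {
    mp <- match_positions(s, expansion$variant_tokens)
    if (nrow(mp)) hit <- c(hit, expansion$variant_name[mp$v])
  }
  unique(hit)
}
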