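# iTerm categorization. Categories are configuration: a YAML scheme maps
# each category to vocabulary files, word-ending (suffix) rules and cue
# words. Assignment is first-match-wins over the scheme's precedence order
# (primary categories first, then secondary, Unclassified as fallback), so
# every term receives exactly one label. The shipped scheme is a small
# curated default and is fully replaceable.

#' Read a category scheme
#'
#' The YAML file holds a `categories` list; each entry has `name`, `kind`
#' (`primary` or `secondary`), optional `vocab` (file of terms, one per
#' line, relative to the scheme file), optional `suffixes` and optional
#' `cues`. Vocabulary entries are matched both on their surface-token form
#' and on their lexeme-normalized form, so they align with the term keys
#' produced by [rank_iterms()].
#'
#' @param path Path to a scheme YAML; defaults to the packaged scheme.
#' @return An object of class `category_scheme`.
#' @export
read_category_scheme <- function(path = NULL) {
  path <- path %||% system.file("extdata", "categories", "scheme.yaml",
                                package = "itermine")
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  cats <- lapply(raw$categories, function(cc) {
    vocab <- character(0)
    for (vf in cc$vocab %||% character(0)) {
      vp <- if (file.exists(vf)) vf else file.path(base, vf)
      x <- readLines(vp, encoding = "UTF-8", warn = FALSE)
      x <- trimws(sub("#.*$", "", x))
      x <- x[nzchar(x)]
      vocab <- c(vocab,
                 norm_phrase(x),
                 vapply(x, function(s) paste(lexeme_of(tokenize(s)), collapse = " "),
                        "", USE.NAMES = FALSE))
    }
    list(name = cc$name,
         kind = cc$kind %||% "primary",
         vocab = unique(vocab),
         suffixes = tolower(unlist(cc$suffixes %||% character(0))),
         cues = unique(c(tolower(unlist(cc$cues %||% character(0))),
                         lexeme_of(tolower(unlist(cc$cues %||% character(0)))))))
  })
  # primary categories keep file order and precede secondary ones
  kinds <- vapply(cats, `[[`, "", "kind")
  cats <- c(cats[kinds == "primary"], cats[kinds != "primary"])
  structure(list(categories = cats,
                 order = c(vapply(cats, `[[`, "", "name"), "Unclassified")),
            class = "category_scheme")
}

#' Assign a category to a term
#'
#' First category (in precedence order) whose vocabulary contains the
#' term, or whose suffix / cue-word rule fires; `"Unclassified"` otherwise.
#' A pure function of (term, scheme).
#'
#' @param term A term string (lexeme key, key pair, or kb phrase).
#' @param scheme A `category_scheme`.
#' @return A single category name.
#' @export
assign_category <- function(term, scheme) {
  words <- strsplit(term, " ", fixed = TRUE)[[1L]]
  for (cc in scheme$categories) {
    if (term %in% cc$vocab) return(cc$name)
    if (length(cc$suffixes)) {
      for (sfx in cc$suffixes) {
        if (any(endsWith(words, sfx) & nchar(words) > nchar(sfx))) return(cc$name)
      }
    }
    if (length(cc$cues) && any(words %in% cc$cues)) return(cc$name)
  }
  "Unclassified"
}

#' Categorize every iTerm
#'
#' @param iterms An `iterm_list`.
#' @param scheme A `category_scheme`.
#' @return `iterms` with a `category` column added.
#' @export
categorize_terms <- function(iterms, scheme = read_category_scheme()) {
  iterms$category <- vapply(iterms$term, assign_category, "", scheme = scheme,
                            USE.NAMES = FALSE)
  iterms
}

#' Group iTerms by category for display
#'
#' Orders terms by category block (primary categories first, in scheme
#' order, then secondary, Unclassified last) and by descending score
#' within each block. The per-category sublists partition the input.
#'
#' @inheritParams categorize_terms
#' @return The reordered `iterm_list` (with `category`).
#' @export
group_by_category <- function(iterms, scheme = read_category_scheme()) {
  if (!"category" %in% names(iterms)) iterms <- categorize_terms(iterms, scheme)
  blk <- match(iterms$category, scheme$order)
  ord <- order(blk, -iterms$score, iterms$term)
  out <- iterms[ord, ]
  for (a in c("mentions", "n_a", "n_b", "gene_id", "removed")) {
    attr(out, a) <- attr(iterms, a)
  }
  class(out) <- class(iterms)
  out
}
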