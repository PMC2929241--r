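# Abstract corpora: construction, flat and MEDLINE XML readers, the flat
# writer, background selection, and the tokenized view used by all
# downstream stages.
#
# Flat dialect (UTF-8): one record per block, blocks separated by one or
# more blank lines. Each line is "TAG<TAB>value" with TAG one of PMID, TI,
# AB, MH. MH values are pipe-separated descriptors; the MH line is omitted
# when a record has none. Tabs/newlines inside values are replaced by
# spaces on write, so write-then-read round-trips exactly.

#' Construct an abstract corpus
#'
#' A corpus is a tibble with one row per document and columns `doc_id`,
#' `title`, `body` and `mesh` (a list column of descriptor strings).
#' Document ids must be unique.
#'
#' @param doc_id Character vector of unique document identifiers.
#' @param title Character vector of titles.
#' @param body Character vector of abstract bodies.
#' @param mesh Optional list of character vectors of MeSH-style descriptors.
#' @return An object of class `abstract_corpus` (a tibble).
#' @export
corpus <- function(doc_id, title, body, mesh = NULL) {
  doc_id <- as.character(doc_id)
  title <- as.character(title)
  body <- as.character(body)
  n <- length(doc_id)
  if (length(title) != n || length(body) != n) {
    stop("doc_id, title and body must have equal length", call. = FALSE)
  }
  if (anyDuplicated(doc_id)) {
    stop("duplicate doc_id: ", paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(mesh)) mesh <- rep(list(character(0)), n)
  if (length(mesh) != n) stop("mesh must have one entry per document", call. = FALSE)
  mesh <- lapply(mesh, as.character)
  out <- tibble::tibble(doc_id = doc_id, title = title, body = body, mesh = mesh)
  class(out) <- c("abstract_corpus", class(out))
  out
}

#' Number of documents in a corpus
#' @param x An `abstract_corpus`.
#' @return Integer count.
#' @export
n_docs <- function(x) nrow(x)

#' @export
print.abstract_corpus <- function(x, ...) {
  cat(sprintf("<abstract corpus: %d document%s>\n", nrow(x), if (nrow(x) == 1) "" else "s"))
  NextMethod()
}

#' Read an abstract corpus
#'
#' Reads either the package's flat tab-tagged dialect or MEDLINE/PubMed XML
#' (`PubmedArticle` element set: PMID, ArticleTitle, AbstractText,
#' MeshHeading/DescriptorName). Records with an empty abstract body are
#' excluded from the returned corpus (with a message), since analysis sets
#' only admit non-empty abstracts.
#'
#' @param path Path to the corpus file.
#' @param format `"flat"` or `"medline-xml"`.
#' @param drop_empty Drop records with an empty body (default `TRUE`).
#' @return An `abstract_corpus`.
#' @export
read_corpus <- function(path, format = c("flat", "medline-xml"), drop_empty = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  out <- switch(format,
    "flat" = read_corpus_flat(path),
    "medline-xml" = read_corpus_xml(path)
  )
  if (drop_empty) {
    empty <- !nzchar(trimws(out$body))
    if (any(empty)) {
      message(sprintf("excluding %d record(s) with empty abstract body: %s",
                      sum(empty), paste(utils::head(out$doc_id[empty], 5L), collapse = ", ")))
      out <- out[!empty, ]
    }
  }
  out
}

read_corpus_flat <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (all(blank)) {
    return(corpus(character(0), character(0), character(0)))
  }
  grp <- cumsum(blank)[!blank]
  recs <- split(lines[!blank], grp)
  parse_rec <- function(rec, pos) {
    m <- regmatches(rec, regexec("^(PMID|TI|AB|MH)\t(.*)$", rec))
    bad <- vapply(m, length, 0L) != 3L
    if (any(bad)) {
      stop(sprintf("malformed line in record %d: %s", pos, rec[bad][1L]), call. = FALSE)
    }
    tags <- vapply(m, `[`, "", 2L)
    vals <- vapply(m, `[`, "", 3L)
    if (!"PMID" %in% tags) stop(sprintf("record %d has no PMID line", pos), call. = FALSE)
    field <- function(tag) {
      v <- vals[tags == tag]
      if (length(v) == 0L) "" else paste(v, collapse = " ")
    }
    mh <- vals[tags == "MH"]
    mesh <- if (length(mh)) unlist(strsplit(mh, "|", fixed = TRUE)) else character(0)
    list(doc_id = field("PMID"), title = field("TI"), body = field("AB"), mesh = mesh)
  }
  parsed <- Map(parse_rec, recs, seq_along(recs))
  corpus(
    doc_id = vapply(parsed, `[[`, "", "doc_id"),
    title = vapply(parsed, `[[`, "", "title"),
    body = vapply(parsed, `[[`, "", "body"),
    mesh = lapply(parsed, `[[`, "mesh")
  )
}

read_corpus_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (length(arts) == 0L) stop("no PubmedArticle elements found in ", path, call. = FALSE)
  one <- function(a, pos) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID | .//PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      stop(sprintf("PubmedArticle %d has no PMID", pos), call. = FALSE)
    }
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    if (is.na(title)) title <- ""
    abs_nodes <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    body <- paste(xml2::xml_text(abs_nodes), collapse = " ")
    mesh <- xml2::xml_text(xml2::xml_find_all(a, ".//MeshHeading/DescriptorName"))
    list(doc_id = pmid, title = title, body = body, mesh = mesh)
  }
  parsed <- Map(one, arts, seq_along(arts))
  corpus(
    doc_id = vapply(parsed, `[[`, "", "doc_id"),
    title = vapply(parsed, `[[`, "", "title"),
    body = vapply(parsed, `[[`, "", "body"),
    mesh = lapply(parsed, `[[`, "mesh")
  )
}

#' Write a corpus in the flat dialect
#'
#' @param x An `abstract_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  clean <- function(s) gsub("[\t\r\n]+", " ", s)
  blocks <- vapply(seq_len(nrow(x)), function(i) {
    lines <- c(
      paste0("PMID\t", clean(x$doc_id[i])),
      paste0("TI\t", clean(x$title[i])),
      paste0("AB\t", clean(x$body[i]))
    )
    if (length(x$mesh[[i]])) {
      lines <- c(lines, paste0("MH\t", paste(clean(x$mesh[[i]]), collapse = "|")))
    }
    paste(lines, collapse = "\n")
  }, "")
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' Select the generic gene/protein background
#'
#' Retains records whose title contains any of the whole words "gene",
#' "genes", "protein" or "proteins" (disjunctive reading). The result is a
#' subset of the input and the operation is idempotent.
#'
#' @param x An `abstract_corpus`.
#' @param triggers Title words that admit a record.
#' @return An `abstract_corpus` subset of `x`.
#' @export
build_background <- function(x, triggers = c("gene", "genes", "protein", "proteins")) {
  keep <- vapply(seq_len(nrow(x)),
                 function(i) any(tokenize(x$title[i]) %in% triggers),
                 logical(1))
  out <- x[keep, ]
  if (nrow(out) == 0L) warning("background selection is empty", call. = FALSE)
  out
}

#' Tokenized view of a corpus
#'
#' Splits each document into sentences and tokens once, for reuse by every
#' downstream stage. The result is a list named by `doc_id`; each element
#' holds the raw title/sentences and their token vectors plus the MeSH
#' descriptors.
#'
#' @param x An `abstract_corpus`.
#' @return Named list of per-document token structures.
#' @export
corpus_tokens <- function(x) {
  out <- lapply(seq_len(nrow(x)), function(i) {
    sents <- split_sentence_text(x$body[i])
    list(
      doc_id = x$doc_id[i],
      title = x$title[i],
      sentences = sents,
      title_tokens = tokenize(x$title[i]),
      sent_tokens = lapply(sents, tokenize),
      mesh = x$mesh[[i]]
    )
  })
  names(out) <- x$doc_id
  out
}

# All token sequences of a tokenized document (title first, then body
# sentences), used for mention counting and language-model training.
token_seqs <- function(entry) {
  c(list(entry$title_tokens), entry$sent_tokens)
}

# Coerce either a tokenized entry or a one-row corpus slice to an entry.
as_token_entry <- function(record) {
  if (is.list(record) && !is.data.frame(record) &&
      "sent_tokens" %in% names(record)) return(record)
  if (inherits(record, "abstract_corpus") && nrow(record) == 1L) {
    return(corpus_tokens(record)[[1L]])
  }
  stop("record must be a tokenized entry (see corpus_tokens()) or a one-row corpus",
       call. = FALSE)
}
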