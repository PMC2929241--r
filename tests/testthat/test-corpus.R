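# corpus reading/writing, tokenization, sentence splitting, background

test_that("flat reader parses records, drops empty bodies, and round-trips", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(
    "PMID\ta1\nTI\tFirst title\nAB\tBody one. Body two.\nMH\tMice|Humans",
    "PMID\ta2\nTI\tSecond title\nAB\tOnly sentence.",
    "PMID\ta3\nTI\tThird title\nAB\tAnother body.",
    sep = "\n\n"), f)
  cc <- read_corpus(f, "flat")
  expect_s3_class(cc, "abstract_corpus")
  expect_equal(n_docs(cc), 3L)
  expect_equal(cc$mesh[[1]], c("Mice", "Humans"))
  expect_equal(cc$mesh[[2]], character(0))

  # empty body excluded from the analysis corpus
  writeLines("PMID\tb1\nTI\tT\nAB\t\n\nPMID\tb2\nTI\tT\nAB\tReal body.", f)
  expect_message(cc2 <- read_corpus(f, "flat"), "empty abstract body")
  expect_equal(cc2$doc_id, "b2")

  # write-then-read identity
  g <- withr::local_tempfile(fileext = ".txt")
  write_corpus(cc, g)
  cc3 <- read_corpus(g, "flat")
  expect_equal(as.data.frame(cc3), as.data.frame(cc))
})

test_that("malformed flat records raise an error naming the position", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("PMID\tok1\nTI\tT\nAB\tB.\n\nXX\tbad line", f)
  expect_error(read_corpus(f, "flat"), "record 2")
  writeLines("TI\tno id\nAB\tB.", f)
  expect_error(read_corpus(f, "flat"), "PMID")
})

test_that("MEDLINE XML reader extracts PMID, title, abstract and MeSH", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<PubmedArticleSet>
 <PubmedArticle><MedlineCitation><PMID>12345</PMID>
  <Article><ArticleTitle>A gene study</ArticleTitle>
   <Abstract><AbstractText>Part one.</AbstractText>
    <AbstractText>Part two.</AbstractText></Abstract></Article>
  <MeshHeadingList><MeshHeading><DescriptorName>Mice</DescriptorName></MeshHeading>
  </MeshHeadingList></MedlineCitation></PubmedArticle>
</PubmedArticleSet>', f)
  cc <- read_corpus(f, "medline-xml")
  expect_equal(cc$doc_id, "12345")
  expect_equal(cc$title, "A gene study")
  expect_equal(cc$body, "Part one. Part two.")
  expect_equal(cc$mesh[[1]], "Mice")
})

test_that("tokenize lowercases, strips punctuation and keeps internal hyphens", {
  expect_equal(tokenize("WD40 domain."), c("wd40", "domain"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("JAM-1 mediates"), c("jam-1", "mediates"))
  # deterministic / pure
  expect_equal(tokenize("Alpha, beta; gamma!"), tokenize("Alpha, beta; gamma!"))
})

test_that("sentence splitting keeps the title apart and indexes sentences", {
  s <- split_sentences("The title", "First sentence here. Second sentence.")
  expect_equal(s$title, "The title")
  expect_length(s$sentences, 2L)

  # terse splitter fixture: last-sentence index
  s2 <- split_sentences("T", "A. B. C.")
  expect_equal(s2$sentences, c("A.", "B.", "C."))

  # degenerate single-sentence body: first == last
  s3 <- split_sentences("T", "Only one sentence.")
  expect_equal(s3$sentences[1], s3$sentences[length(s3$sentences)])

  # abbreviation exceptions do not split
  s4 <- split_sentences("T", "We use e.g. bigrams here. Second claim.")
  expect_length(s4$sentences, 2L)
})

test_that("background keeps gene/protein titles, is a subset and idempotent", {
  cc <- corpus(c("x1", "x2", "x3", "x4"),
               c("A novel gene regulating X",
                 "Effects of exercise on mood",
                 "Heat shock proteins in yeast",
                 "Genetics of sleep"),
               rep("Body sentence.", 4))
  bg <- build_background(cc)
  expect_setequal(bg$doc_id, c("x1", "x3"))
  expect_true(all(bg$doc_id %in% cc$doc_id))
  expect_equal(as.data.frame(build_background(bg)), as.data.frame(bg))
  expect_warning(build_background(cc[2, ]), "empty")
})
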