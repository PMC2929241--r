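# retrieval, abbreviation detection, sense models, disambiguation

test_that("retrieve matches variants on token boundaries", {
  exp <- fixture_expansion(c("Groucho", "JAM 1"))
  cc <- fixture_corpus(c(
    "The groucho corepressor acts here.",
    "Nothing relevant at all.",
    "We studied jam 1 subunits.",     # multi-token variant
    "Grouchomarx is a different token.",
    "A jam-1 mention via the hyphen variant."))
  ids <- retrieve(exp, cc)
  expect_setequal(ids, c("d01", "d03", "d05"))
})

test_that("abbreviation-expansion pairs satisfy the alignment conditions", {
  cc <- fixture_corpus(c(paste(
    "Dentin phosphoprotein (DPP) is cleaved.",
    "The growth related oncogene (GRO) was induced.",
    "Our results (ABC) were inconclusive.",
    "We then mapped DPP (dentin phosphoprotein) directly.")))
  ab <- detect_abbreviations(cc)
  expect_true(nrow(ab) == 3L)
  expect_true(all(c("dpp", "gro") %in% ab$short_form))
  expect_true("dentin phosphoprotein" %in% ab$long_form)
  expect_true("growth related oncogene" %in% ab$long_form)
  expect_false("abc" %in% ab$short_form)  # no aligning long form
  # invariants: short <= long, first chars align at a word start
  expect_true(all(nchar(ab$short_form) <= nchar(ab$long_form)))
  expect_true(all(substr(ab$short_form, 1, 1) ==
                  substr(ab$long_form, 1, 1)))
})

test_that("anchoring needs two gene names or a rival expansion", {
  exp <- fixture_expansion(c("gro", "groucho"))
  rivals <- list("gasoline range organics" = "gasoline range organics")
  two_names <- fixture_corpus("The gro corepressor, also called groucho, acts.")
  one_name <- fixture_corpus("Only gro appears in this abstract.")
  rival <- fixture_corpus("Measuring gasoline range organics (gro) in soil.")
  conflict <- fixture_corpus("The gro groucho story meets gasoline range organics.")
  expect_equal(anchor_assign(two_names, exp, rivals), "gene")
  expect_equal(anchor_assign(one_name, exp, rivals), NA_character_)
  expect_equal(anchor_assign(rival, exp, rivals), "gasoline range organics")
  expect_equal(anchor_assign(conflict, exp, rivals), NA_character_)
})

test_that("bigram models count, smooth and normalize as specified", {
  cc <- fixture_corpus("a b a b.", titles = "")
  tk <- corpus_tokens(cc)
  m <- train_sense_models(list(s = "d01"), tk)$s
  expect_equal(as.integer(m$bigram_counts[["a\rb"]]), 2L)

  # add-one smoothing: context count 4, predicted space 10 -> unseen = 1/14
  cc2 <- fixture_corpus("a b. a c. a d. a e. f g h.", titles = "")
  tk2 <- corpus_tokens(cc2)
  m2 <- train_sense_models(list(s = "d01"), tk2)$s
  expect_equal(length(m2$vocab_words) + 2L, 10L)
  expect_equal(bigram_prob(m2, "a", "zzz"), 1 / 14)
  # each probability row sums to one over the predicted space
  for (w1 in c("a", "f", "<s>")) {
    row <- vapply(c(m2$vocab_words, "</s>", "zz-unseen"),
                  function(w2) bigram_prob(m2, w1, w2), numeric(1))
    expect_equal(sum(row), 1, tolerance = 1e-12)
  }
})

test_that("score_abstract is the mean log transition probability", {
  cc <- fixture_corpus("a b a b.", titles = "")
  tk <- corpus_tokens(cc)
  m <- train_sense_models(list(s = "d01"), tk)$s
  doc <- fixture_corpus("a b.", titles = "", ids = "t1")
  # hand computation from raw counts: P(a|<s>) = (1+1)/(1+4), P(b|a) = (2+1)/(2+4)
  expect_equal(score_abstract(m, doc), mean(log(c(2 / 5, 3 / 6))))
  empty <- fixture_corpus("", titles = "", ids = "t2")
  expect_identical(suppressMessages(score_abstract(m, corpus_tokens(empty)[[1]])), -Inf)
})

test_that("disambiguation follows likelihood dominance and ties are ambiguous", {
  train_a <- fixture_corpus(rep("alpha beta gamma delta.", 3), ids = sprintf("a%d", 1:3))
  train_b <- fixture_corpus(rep("omega psi chi phi.", 3), ids = sprintf("b%d", 1:3))
  tk <- c(corpus_tokens(train_a), corpus_tokens(train_b))
  models <- train_sense_models(list(A = sprintf("a%d", 1:3), B = sprintf("b%d", 1:3)), tk)
  doc_a <- fixture_corpus("alpha beta gamma.", titles = "", ids = "t")
  expect_gt(score_abstract(models$A, doc_a), score_abstract(models$B, doc_a))
  expect_equal(as.character(disambiguate(doc_a, models)), "A")
  # identical models force an exact tie
  expect_equal(as.character(disambiguate(doc_a, list(m1 = models$A, m2 = models$A))),
               "ambiguous")
})

test_that("egrab assembles the Full Set and keeps training sets disjoint", {
  cfg <- generator_config(seed = 3)
  cfg$ambiguity$docs_per_sense <- 40L
  ac <- generate_ambiguous_corpus(cfg)
  exp <- fixture_expansion(c("gro", "groucho"))
  tk <- corpus_tokens(ac$corpus)
  full <- suppressWarnings(egrab(exp, tokens = tk))
  expect_s3_class(full, "full_set")
  expect_true(all(full$doc_ids %in% full$retrieved))
  expect_length(intersect(full$doc_ids, full$ambiguous_doc_ids), 0L)
  # sense training sets disjoint; anchored docs bypass scoring
  tr <- lapply(full$models, `[[`, "training_doc_ids")
  expect_equal(anyDuplicated(unlist(tr)), 0L)
  lm_docs <- full$assignments$doc_id[full$assignments$assignment == "lm"]
  expect_length(intersect(lm_docs, unlist(tr)), 0L)
  # rival-anchored docs are excluded
  rival_anchor <- ac$truth$doc_id[ac$truth$anchor & ac$truth$sense != "gene"]
  expect_length(intersect(full$doc_ids, rival_anchor), 0L)
})

test_that("a gene with a unique unambiguous name keeps all retrieved docs", {
  exp <- fixture_expansion("uniquegene")
  cc <- fixture_corpus(c("The uniquegene locus is amplified.",
                         "Unrelated text with nothing.",
                         "More uniquegene biology."))
  full <- suppressWarnings(egrab(exp, corpus = cc))
  expect_setequal(full$doc_ids, retrieve(exp, cc))
  expect_true(all(full$assignments$assignment %in% c("anchor", "default")))
})

test_that("names with no discoverable expansion default to the gene sense", {
  # Kip1-style case: short synonym, no parenthetical expansions anywhere
  exp <- fixture_expansion(c("cib1", "kip1"))
  cc <- fixture_corpus(c("The kip1 inhibitor binds cyclin complexes.",
                         "Another kip1 abstract about cell cycle."))
  expect_warning(full <- egrab(exp, corpus = cc), "default")
  expect_setequal(full$doc_ids, c("d01", "d02"))
  expect_true(all(full$assignments$assignment == "default"))
})
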