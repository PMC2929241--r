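# About-Set selection: mention counting and the focus rule

test_that("mention_count counts non-overlapping token-boundary occurrences", {
  exp <- fixture_expansion(c("gro", "groucho"))
  cc <- fixture_corpus("The groucho protein recruits gro. Then groucho departs.",
                       titles = "No mention here")
  expect_equal(mention_count(cc, exp), 3L)
  none <- fixture_corpus("Nothing to see.", titles = "Still nothing")
  expect_equal(mention_count(none, exp), 0L)
  # overlapping variants at one position count once (longest match wins)
  exp2 <- fixture_expansion(c("jam", "jam 1"))
  cc2 <- fixture_corpus("Binding of jam 1 was measured.", titles = "")
  expect_equal(mention_count(cc2, exp2), 1L)
})

test_that("is_about requires three mentions or a title/first/last position", {
  exp <- fixture_expansion("bmp2")
  title_hit <- fixture_corpus("Osteoblasts were profiled. Results follow.",
                              titles = "Bmp2 is essential for postnatal osteogenesis")
  expect_true(is_about(title_hit, exp))

  exp_g <- fixture_expansion("groucho")
  passing <- fixture_corpus(
    "Forebrain patterning was studied. A role for groucho was once noted. Conclusions differ.",
    titles = "Formation and patterning of the forebrain by zinc-finger genes")
  expect_false(is_about(passing, exp_g))

  three_mid <- fixture_corpus(
    "Intro sentence first. Then bmp2 and bmp2 and bmp2 appear. Final words here.",
    titles = "A study")
  expect_true(is_about(three_mid, exp))

  one_mid <- fixture_corpus(
    "Intro sentence first. Here bmp2 appears once. Final words here.",
    titles = "A study")
  expect_false(is_about(one_mid, exp))

  # monotone: adding a mention can only flip FALSE -> TRUE
  more <- fixture_corpus(
    "Intro sentence first. Here bmp2 appears once and bmp2 twice and bmp2 thrice. Final words here.",
    titles = "A study")
  expect_true(is_about(more, exp))
})

test_that("about_set filters, counts and warns on low data", {
  exp <- fixture_expansion("genex")
  focus <- sprintf("Genex is central here. It does things. More genex and genex facts.")
  pass <- "Something else entirely. A genex aside sits here. Final thought."
  cc <- fixture_corpus(c(rep(focus, 6), rep(pass, 4)), titles = rep("T", 10))
  tk <- corpus_tokens(cc)
  ab <- suppressWarnings(about_set(cc$doc_id, tk, exp))
  expect_s3_class(ab, "about_set")
  expect_equal(ab$n_a, 6L)
  expect_true(all(ab$doc_ids %in% cc$doc_id))

  # all focused -> identity
  cc2 <- fixture_corpus(rep(focus, 3))
  ab2 <- suppressWarnings(about_set(cc2$doc_id, corpus_tokens(cc2), exp))
  expect_setequal(ab2$doc_ids, cc2$doc_id)

  # idempotent on its own doc ids
  ab3 <- suppressWarnings(about_set(ab$doc_ids, tk, exp))
  expect_equal(ab3$doc_ids, ab$doc_ids)

  expect_warning(about_set(cc$doc_id, tk, exp, very_low = 2L), "< 50")
  expect_error(suppressWarnings(about_set(cc$doc_id[7:10], tk, exp)), "empty")
})

test_that("the about rule matches planted labels on a generated fixture", {
  cfg <- generator_config(seed = 11)
  cfg$gene_size <- 20L
  gc <- generate_gene_corpus(cfg)
  exp <- fixture_expansion(cfg$gene_names)
  tk <- corpus_tokens(gc$corpus)
  pred <- vapply(gc$truth$doc_id, function(d) is_about(tk[[d]], exp), logical(1))
  expect_equal(unname(pred), gc$truth$focus)
})
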