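# synthetic-corpus generators: determinism, planted structure, rates

test_that("generation is byte-identical under the same (config, seed)", {
  cfg <- generator_config(seed = 5)
  cfg$background_size <- 50L
  cfg$gene_size <- 12L
  cfg$ambiguity$docs_per_sense <- 10L
  a1 <- generate_background(cfg); a2 <- generate_background(cfg)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  g1 <- generate_gene_corpus(cfg); g2 <- generate_gene_corpus(cfg)
  expect_identical(g1, g2)
  m1 <- generate_ambiguous_corpus(cfg); m2 <- generate_ambiguous_corpus(cfg)
  expect_identical(m1, m2)
  # a different seed changes the text
  cfg2 <- generator_config(seed = 6)
  cfg2$background_size <- 50L
  expect_false(identical(generate_background(cfg2)$body, a1$body))
})

test_that("background titles carry trigger words and planted rates hold", {
  cfg <- generator_config(seed = 9)
  bg <- generate_background(cfg)
  expect_equal(nrow(bg), 1000L)
  trig <- c("gene", "genes", "protein", "proteins")
  expect_true(all(vapply(bg$title, function(t) any(tokenize(t) %in% trig),
                         logical(1))))
  # empirical planted-term df concentrates near the configured baseline
  hits <- vapply(seq_len(nrow(bg)), function(i) {
    "talfexin" %in% tokenize(bg$body[i])
  }, logical(1))
  expect_lt(abs(mean(hits) - cfg$p_planted_background), 0.03)
  # degenerate size
  cfg0 <- generator_config(seed = 9); cfg0$background_size <- 0L
  expect_equal(nrow(generate_background(cfg0)), 0L)
})

test_that("gene-corpus truth matches its construction", {
  cfg <- generator_config(seed = 13)
  gc <- generate_gene_corpus(cfg)
  expect_equal(nrow(gc$corpus), cfg$gene_size)
  expect_equal(sum(gc$truth$focus), round(cfg$focus_fraction * cfg$gene_size))
  exp <- fixture_expansion(cfg$gene_names)
  tk <- corpus_tokens(gc$corpus)
  # passing docs fail the focus rule, focused docs pass it - by construction
  for (i in seq_len(nrow(gc$truth))) {
    expect_equal(is_about(tk[[gc$truth$doc_id[i]]], exp), gc$truth$focus[i],
                 info = gc$truth$doc_id[i])
  }
  # planted terms score positively with the generated frequencies
  cfg_bg <- generator_config(seed = 13); cfg_bg$background_size <- 300L
  bg <- generate_background(cfg_bg)
  about_ids <- gc$truth$doc_id[gc$truth$focus]
  n_a <- length(about_ids); n_b <- nrow(bg)
  akeys <- lapply(about_ids, function(d) {
    unique(lexeme_of(tokenize(gc$corpus$body[gc$corpus$doc_id == d])))
  })
  bkeys <- lapply(bg$body, function(b) unique(lexeme_of(tokenize(b))))
  for (t in gc$planted_keys) {
    df_a <- sum(vapply(akeys, function(k) t %in% k, logical(1)))
    df_b <- max(1L, sum(vapply(bkeys, function(k) t %in% k, logical(1))))
    expect_gt(score_term(df_a, n_a, df_b, n_b), 0)
  }
})

test_that("ambiguous corpus plants anchors at the configured fraction", {
  cfg <- generator_config(seed = 17)
  ac <- generate_ambiguous_corpus(cfg)
  n <- nrow(ac$truth)
  expect_equal(n, 2L * cfg$ambiguity$docs_per_sense)
  # every doc mentions the short name
  expect_true(all(vapply(seq_len(n), function(i) {
    "gro" %in% tokenize(ac$corpus$body[i])
  }, logical(1))))
  # anchor fraction is approximately as configured (binomial, seeded)
  expect_lt(abs(mean(ac$truth$anchor) - cfg$ambiguity$anchor_fraction), 0.08)
  # rival anchors carry a detectable abbreviation-expansion pattern
  tk <- corpus_tokens(ac$corpus)
  rival_anchor <- ac$truth$doc_id[ac$truth$anchor & ac$truth$sense != "gene"][1:5]
  for (d in rival_anchor) {
    ab <- detect_abbreviations(tk[[d]])
    expect_true("gro" %in% ab$short_form, info = d)
  }
  # single-sense degenerate case: all docs are the gene sense
  cfg1 <- generator_config(seed = 17)
  cfg1$ambiguity$rivals <- character(0)
  cfg1$ambiguity$docs_per_sense <- 8L
  ac1 <- generate_ambiguous_corpus(cfg1)
  expect_true(all(ac1$truth$sense == "gene"))
})

test_that("config validation rejects bad probabilities and divergence", {
  expect_error(generator_config(p_planted_about = 1.4), "probabilities")
  expect_error(generator_config(ambiguity = list(short_name = "x",
                                                 gene_names = c("x", "y"),
                                                 rivals = "z z z",
                                                 docs_per_sense = 5L,
                                                 anchor_fraction = 0.2,
                                                 divergence = "extreme")),
               "divergence")
  expect_error(generator_config(position_fractions = c(title = 0.5, first = 0.2,
                                                       last = 0.2, count = 0.2)),
               "sum to 1")
})
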