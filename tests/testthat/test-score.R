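# the iTerm score, ranking, gating and redundancy pruning

test_that("score_term has the required shape", {
  # zero at equal normalized frequencies
  expect_equal(score_term(10, 100, 1000, 10000), 0)
  # hand-computed value
  expect_equal(score_term(50, 100, 100, 10000), 0.49 * log(100), tolerance = 1e-9)
  # strictly increasing in df_a
  s <- score_term(1:50, 100, 100, 10000)
  expect_true(all(diff(s) > 0))
  # for a fixed normalized difference, strictly decreasing in df_b
  n_b <- 10000
  df_b <- c(10, 100, 1000, 5000)
  df_a <- (0.13 + df_b / n_b) * 100
  s2 <- score_term(df_a, 100, df_b, n_b)
  expect_true(all(diff(s2) < 0))
  # sign follows the normalized difference
  expect_lt(score_term(1, 100, 5000, 10000), 0)
  expect_gt(score_term(50, 100, 10, 10000), 0)
  # guards
  expect_error(score_term(1, 0, 1, 10), "positive")
  expect_error(score_term(1, 10, 0, 10), "df_b")
  # configurable log base scales the damping only
  expect_equal(score_term(50, 100, 100, 10000, log_base = 10),
               0.49 * log10(100), tolerance = 1e-9)
})

test_that("equal-difference terms diverge with background rarity", {
  n_a <- 100; n_b <- 10000
  rare <- score_term((0.13 + 100 / n_b) * n_a, n_a, 100, n_b)
  common <- score_term((0.13 + 8000 / n_b) * n_a, n_a, 8000, n_b)
  expect_gt(rare / common, 5)
})

test_that("rank_iterms gates bigrams at the background threshold", {
  sw <- load_stopwords()
  cc <- fixture_corpus(rep("Alpha beta complexes and gamma subunits interact.", 6),
                       titles = rep("", 6))
  tk <- corpus_tokens(cc)
  bg_df <- tibble::tibble(
    term = c("alpha beta", "beta complex", "alpha", "beta", "gamma"),
    type = c("bigram", "bigram", "unigram", "unigram", "unigram"),
    df = c(9L, 10L, 20L, 20L, 15L))
  it <- rank_iterms(cc$doc_id, tk, bg_df, n_b = 1000L, stopwords = sw)
  expect_false("alpha beta" %in% it$term[it$type == "bigram"])   # df_b = 9
  expect_true("beta complex" %in% it$term[it$type == "bigram"])  # df_b = 10
  # unigram absent from background floors df_b at 1
  expect_equal(it$df_b[it$term == "subunit"], 1L)
  # no non-positive scores, ranks strictly ordered
  expect_true(all(it$score > 0))
  expect_true(all(diff(it$score) <= 0))
  expect_equal(it$rank, seq_len(nrow(it)))
  # lexicographic tie-break on equal scores
  ties <- it[duplicated(it$score) | duplicated(it$score, fromLast = TRUE), ]
  if (nrow(ties) > 1) expect_true(all(diff(order(ties$score, decreasing = TRUE)) >= 0))
})

test_that("redundant unigrams are removed at 75% coverage and kept below", {
  mk_list <- function() {
    out <- tibble::tibble(
      rank = 1:3,
      term = c("lymphoblastic leukemia", "lymphoblastic", "repressor"),
      display = c("lymphoblastic leukemia", "lymphoblastic", "repressor"),
      type = c("bigram", "unigram", "unigram"),
      df_a = c(40L, 45L, 30L), df_b = c(10L, 12L, 20L),
      score = c(3, 2.5, 2), bigrams = list(character(0), character(0), character(0)))
    class(out) <- c("iterm_list", class(tibble::tibble()))
    out
  }
  counts <- tibble::tibble(
    term = c("lymphoblastic", "lymphoblastic leukemia",
             "repressor", "transcriptional repressor"),
    type = c("unigram", "bigram", "unigram", "bigram"),
    count = c(100L, 80L, 100L, 50L))
  pruned <- prune_redundant(mk_list(), counts)
  expect_false("lymphoblastic" %in% pruned$term)   # 80% >= 75%
  expect_true("repressor" %in% pruned$term)        # 50% < 75%
  expect_equal(attr(pruned, "removed"), "lymphoblastic")
  expect_equal(pruned$rank, seq_len(nrow(pruned)))

  # exact-threshold arithmetic: 75 of 100 removes
  counts$count[counts$term == "lymphoblastic leukemia"] <- 75L
  expect_false("lymphoblastic" %in% prune_redundant(mk_list(), counts)$term)
  counts$count[counts$term == "lymphoblastic leukemia"] <- 74L
  expect_true("lymphoblastic" %in% prune_redundant(mk_list(), counts)$term)
})

test_that("ranking agrees with the brute-force oracle on a small corpus", {
  sw <- load_stopwords()
  cfg <- generator_config(seed = 21)
  cfg$gene_size <- 10L
  cfg$background_size <- 25L
  gc <- generate_gene_corpus(cfg)
  bg <- generate_background(cfg)
  tk <- corpus_tokens(gc$corpus)
  btk <- corpus_tokens(bg)
  bdf <- document_frequencies(btk, sw)
  it <- rank_iterms(gc$corpus$doc_id, tk, bdf, n_b = nrow(bg), stopwords = sw)
  ora <- oracle_rank_iterms(tk, btk, sw, n_b = nrow(bg))
  expect_equal(it$term, ora$term)
  expect_equal(it$df_a, ora$df_a)
  expect_equal(it$df_b, as.integer(ora$df_b))
  expect_equal(it$score, ora$score, tolerance = 1e-12)
})
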