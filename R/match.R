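# Token-boundary matching of name variants in tokenized text. Variants are
# pre-tokenized (multi-token variants match contiguous token subsequences);
# overlapping matches are resolved longest-first, left to right, so a
# position is never counted twice.

# Positions of non-overlapping variant matches in one token vector.
# vtoks: list of non-empty token vectors. Returns a data.frame with
# columns pos (start index), len, v (index into vtoks).
match_positions <- function(tokens, vtoks) {
  empty <- data.frame(pos = integer(0), len = integer(0), v = integer(0))
  n <- length(tokens)
  if (n == 0L || length(vtoks) == 0L) return(empty)
  heads <- vapply(vtoks, `[`, "", 1L)
  if (!any(tokens %in% heads)) return(empty)
  ord <- order(-lengths(vtoks))
  res_pos <- integer(0); res_len <- integer(0); res_v <- integer(0)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (j in ord) {
      vt <- vtoks[[j]]
      L <- length(vt)
      if (i + L - 1L > n) next
      if (tokens[i] != vt[1L]) next
      if (L == 1L || all(tokens[i:(i + L - 1L)] == vt)) {
        res_pos <- c(res_pos, i); res_len <- c(res_len, L); res_v <- c(res_v, j)
        hit <- L
        break
      }
    }
    i <- i + if (hit > 0L) hit else 1L
  }
  data.frame(pos = res_pos, len = res_len, v = res_v)
}

# TRUE if any variant matches in the token vector.
contains_any <- function(tokens, vtoks) {
  nrow(match_positions(tokens, vtoks)) > 0L
}

# TRUE if any variant matches anywhere in a tokenized document.
doc_contains <- function(entry, vtoks) {
  for (s in token_seqs(entry)) {
    if (contains_any(s, vtoks)) return(TRUE)
  }
  FALSE
}
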