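---
title: "Mining informative terms for genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining informative terms for genes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itermine)
```

`itermine` turns a gene's literature into a ranked list of informative
terms (iTerms) with supporting sentences. This vignette explains the
models behind each stage, the parameters that matter, what the
synthetic benchmarks do and do not demonstrate, and the design
decisions taken where the method left room.

## The pipeline at a glance

1. **Query expansion** — all names and synonyms of the gene, restricted
   by species, closed under hyphen/space variation.
2. **Retrieval + disambiguation (eGRAB)** — candidate abstracts are
   retrieved by token-boundary matching; ambiguous names are resolved
   with per-sense bigram language models trained on automatically
   identified anchor abstracts. The result is the *Full Set*.
3. **About filter** — keeps abstracts that focus on the gene (≥ 3
   mentions, or a mention in the title / first / last sentence),
   yielding the *About Set* of size `N_a`.
4. **Term scoring** — lexeme-pooled unigrams, bigrams and matched
   knowledge-base phrases are scored against a large gene/protein
   background corpus and ranked.
5. **Categorization and evidence** — single-label category assignment
   and per-term ranked evidence sentences.

## Disambiguation model

Gene short names are treated like ambiguous abbreviations: each sense
is characterized by the words around it. Training data is bootstrapped,
not annotated: an abstract mentioning **two or more distinct names** of
the gene anchors the gene sense, and an abstract containing a rival
**expansion phrase** (or a parenthetical abbreviation–expansion pair
whose short form is the ambiguous name, detected by character
alignment) anchors that rival. An abstract matched by two anchor rules
is in conflict and trains nothing.

Each sense gets a bigram language model over title + body tokens with
sentence-boundary markers. Probabilities are add-*k* smoothed over the
predicted-token space (training vocabulary, the sentence-end marker,
and UNK):

$$P(w_2 \mid w_1) = \frac{c(w_1,w_2) + k}{c(w_1) + k\,V}$$

An abstract is scored by the **mean** log transition probability of its
tokens (the sentence-end transition is not scored), and assigned to the
arg-max sense. Choices made here:

* **k = 1 by default.** Add-one is the simplest smoother with no
  hyperparameter search; `smoothing_k` is exposed for corpora where
  training anchors are very sparse. Note that duplicating a sense's
  training corpus scales all counts and therefore changes smoothed
  probabilities only through the relative weight of `k` — the model is
  insensitive to corpus duplication in the large-count limit.
* **Mean, not sum.** The sum of log probabilities scales with abstract
  length; the mean makes scores comparable across abstracts.
* **Exact ties → ambiguous.** Tied abstracts are excluded from the Full
  Set rather than guessed: the filter is precision-first. In practice
  ties occur only in degenerate cases (identical models).
* **No rival discoverable → default to the gene.** When a short synonym
  has no expansion of any kind anywhere in the corpus, there is nothing
  to train against; all its abstracts are assigned to the gene with a
  logged warning. This mirrors how such names must be handled at corpus
  scale, and it is the known failure mode of the stage: a truly
  ambiguous name with no discoverable expansion contaminates the Full
  Set.
* Anchored abstracts bypass scoring — they are training data, and the
  training sets of different senses are disjoint by construction.

## The About rule

An abstract focuses on the gene when it mentions it at least
`about_min_mentions = 3` times (title included), **or** mentions it in
the title, the first or the last body sentence — "and/or" is read as an
inclusive OR, the reading consistent with how single first-sentence
mentions are admitted. Counting is over non-overlapping token-boundary
matches of any query variant, longest variant first, and the total
pools all variants rather than requiring distinct ones. Family names
("BMP" for *BMP2*) are deliberately **not** counted. Because score
normalization divides by `N_a`, small About Sets make scores unstable;
the package warns below 50 documents and more strongly below 30.

## The term score

$$s(t) = \left(\frac{df_a(t)}{N_a} - \frac{df_b(t)}{N_b}\right)\,
        \ln\!\frac{N_b}{df_b(t)}$$

Document frequencies, not raw term frequencies, are used: relevance to
the *set* of abstracts matters, not repetition within one abstract.
The damping factor is the step that separates discriminative terms from
ubiquitous ones: two terms with the same normalized difference diverge
sharply when one is rare in the background. The natural log is the
default (`log_base` is configurable); the difference-times-damping form
reproduces the intended qualitative behaviour — at an equal difference
of 0.13, a background-rare term outscores a background-ubiquitous one
by well over five-fold.

Numerical and boundary choices:

* **`df_b` floor.** A unigram or knowledge-base phrase absent from the
  background gets `df_b := 1`: it earns the maximal damping credit
  while keeping the log finite.
* **Bigram gate.** Bigrams require `df_b ≥ 10`: with a large
  background, an accidental rare bigram would otherwise get an enormous
  damping factor. The gate is inclusive at 10. Knowledge-base phrases
  are not gated — they are vetted terms by construction.
* **Scores ≤ 0 are discarded** as background-typical.
* **Ties break lexicographically** on the term string, so rankings are
  fully deterministic.
* **Lexemes.** The morphological processor is a deterministic,
  dictionary-free suffix stripper: plural (`-s/-es/-ies`), `-ed`,
  `-ing` (with final-consonant undoubling, sparing `ss`/`ll`), agentive
  `-or/-er`, a final `-e` on stems of five or more characters, and
  `-ion` only when the remainder ends in a double `s` (so *repression*
  joins *repress* while *segmentation* stays itself). Keys are
  canonical strings, not words; the display layer maps a key to its
  most frequent surface form. Over-stemming collisions (e.g. *rated* /
  *rat*) are possible but rare in practice and are a deliberate
  trade-off for having no dictionary dependency. Word-order variants
  (*transcriptional activation* vs *activation of transcription*) are
  intentionally **not** merged.
* **Redundancy.** A unigram is removed when a single retained bigram
  containing it covers ≥ 75% of the unigram's About-Set mention count
  ("occurs alone" < 25% of the time). Mention counts, not document
  frequencies, are used — the rule is about how the word is actually
  used. A unigram whose occurrences split across several bigrams (the
  *repressor* pattern: roughly half inside *transcriptional repressor*)
  is kept.

## Categorization

The category scheme is configuration, not code: a YAML file maps each
category to vocabulary files, word-ending rules and cue words. The
shipped scheme is a small curated default. Precedence is first match
wins, primary categories (in their listed order) before secondary, so
every term receives exactly one label; where ontologies overlap (a
GO-style process that is also a disease term), the earlier category
takes the term — a deliberate, deterministic resolution of an
undefined case.

## Evidence sentences

Sentence ranking is rudimentary by design:

$$\mathrm{score} = w_1\,[\text{gene within first } k \text{ tokens}]
 + w_2\,\frac{1}{1 + d}$$

with `w1 = w2 = 1`, `k = 3` and `d` the minimal token distance between
a gene mention and the term. "Initial (subject) position" is
operationalized as the gene starting within the first three tokens — a
parse-free approximation. Sentences without a gene mention always rank
below sentences with one; ties break by document id and sentence index.
Species tags record only that a species name or alias occurs in the
title, body or MeSH descriptors — no gene–species linkage is inferred.

## What the synthetic benchmarks show — and what they do not

The generator builds bag-of-sentence documents over pseudo-word
vocabularies with Zipf-distributed frequencies, which gives realistic
document-frequency tails (the damping factor has something to do). Its
defaults are the package's benchmark conditions:

* background of 1000 abstracts, every title containing gene(s) /
  protein(s);
* a 60-abstract gene corpus, 70% focused, with five planted terms at
  inclusion probability 0.6 in focused abstracts versus 0.05 in the
  background — an enrichment a frequency-contrast method must recover;
* a two-sense ambiguity benchmark (150 documents per sense, 30% anchor
  abstracts) at three divergence levels — 0.2 / 0.5 / 0.8 of tokens
  drawn from sense-exclusive vocabulary — emulating the short-name
  scenario with anchor abstracts and parenthetical expansions.

These sizes keep the full suite within a few minutes while leaving
enough statistics for stable checks (about 200 non-anchor test
documents per divergence level; binomial fluctuations of a couple of
percent). On these conditions the package recovers all planted terms in
the top 20, matches the About labels perfectly (the labels are planted,
so this validates the implementation, not the heuristic), and separates
the two senses essentially perfectly at high divergence.

What passing these benchmarks does **not** show: real abstracts are not
bags of independent words — real synonymy, family names, species mixes,
multi-topic abstracts and genuinely correlated bigrams are absent, so
synthetic redundancy pruning rates (typically 0% here) are much lower
than on real literature, and synthetic disambiguation accuracy
overstates what mixed real senses with shared technical vocabulary
would give. The corpus-scale published behaviour of this family of
methods can only be re-established on Medline with human judgment.

## Known limitations

* Frequency-based selection misses important but rarely mentioned
  properties and is slow to pick up recent discoveries.
* Semantically redundant terms (*apoptosis* / *programmed cell death*)
  are not grouped; only lexeme-level redundancy is handled.
* The category vocabularies shipped are small seeds, intended to be
  replaced with full controlled vocabularies where available.
* The sentence ranker has no syntax: "initial position" is a token
  offset, not a subject detection.
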