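---
title: "Ranking-based readability assessment: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking-based readability assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(readrank)
```

## Why ranking

Grade-level formulas (Flesch-Kincaid, Gunning Fog, Dale-Chall, ...) map
surface statistics to a school grade. For clinical narratives this
breaks down twice: the mapping's assumption — longer words and sentences
mean harder text — fails on abbreviation-dense, list-structured EHR
notes; and the absolute grade is rarely what an application needs.
Patient-facing systems want *relative* judgements: which of these
documents is harder, which educational material matches this reader.

`readrank` therefore learns to *order* documents by difficulty from
human pairwise ratings, rather than to predict a level from a fixed set.

## The model

Each rater judges side-by-side document pairs on a 1–10 difficulty
scale. Within one rater's document set, any two documents with different
ratings yield a training example: the feature difference vector
`x′ = x_harder − x_easier`, label +1. Pairs are never formed across
raters — two raters' scales need not be mutually consistent, while a
single rater's ratings induce a coherent partial order.

Training minimizes

    ½‖w‖² + C Σ max(0, 1 − w·x′)

the hinge-loss relaxation of "minimize the number of discordant pairs",
i.e. a binary-classification SVM on the difference vectors. Design
choices, with reasons:

* **No intercept.** An intercept cancels in `x_i − x_j` and is
  unidentifiable; fitting one would only distort the solver.
* **Single orientation.** Each pair is stored once as
  (harder − easier, +1). Training on the mirrored two-class set is
  provably equivalent (the mirrored constraint is the same constraint;
  it halves into a doubled C) and the test suite verifies this
  numerically against the solver.
* **Rating magnitude ignored.** A 9-vs-2 pair contributes exactly like a
  6-vs-5 pair; only the sign of the difference matters. No margin
  rescaling by rating gap.
* **Solver.** Dual coordinate descent with liblinear-style shrinking,
  deterministic given its seed (own RNG, independent of R's). Stopping:
  projected-gradient range < `tol` (default 1e-4) or `max_epochs`
  (default 1000; the hard cases in the acceptance harness raise it). A
  cap hit produces a warning, never a silent result.
* **Ties in ratings** produce no example (no preference was expressed).
  A rater rating the same document in two of their pairs contributes its
  mean rating for example generation and rates it consistently in the
  simulator.

Scoring is the pure linear functional `w·x`; ranking sorts by descending
score with lexicographic doc-id tie-breaks, so output order is
deterministic and permutation-invariant.

## Features (416 dimensions, five named blocks)

* `formula[4]` — words/sentence and syllables/word (the FKGL inputs),
  proportion of polysyllabic words, and the difficult-word percentage.
  *Polysyllabic* here means **strictly more than 3 syllables**, following
  the stricter of the two conventions in circulation; the test suite
  pins a 3-syllable word as not polysyllabic. *Difficult* means absent
  from the easy-word list after lowercasing; purely numeric tokens count
  as easy. The bundled easy-word list (~900 common English words) is a
  constructed stand-in — it is *not* the New Dale-Chall 3000-word list,
  which cannot be redistributed here; supply the real list via
  `read_easy_words()` when grading real text. Synthetic studies use the
  generator's own easy lexicon, making the feature exact in that world.
* `freq_bins[10]` — the share of the document's tokens in each decile of
  the corpus log-frequency distribution over word *types*. The bin-edge
  construction (deciles of log type frequency; midpoints between order
  statistics; ties nudged so all eleven edges stay strictly ascending)
  is a package choice — equal-width and linear-scale binning would be
  defensible too. Out-of-vocabulary tokens land in the lowest bin:
  unseen ≈ rare. The frequency source defaults to the combined
  two-source study corpus, but a general-English table can be supplied —
  both readings of "word frequency" are expressible via configuration.
* `length[2]` — token and sentence counts.
* `embed_wiki[200]`, `embed_ehr[200]` — mean of skip-gram vectors of
  in-vocabulary tokens, one embedding per source. Mean pooling is the
  minimal defensible aggregation of word vectors into a document vector.
  **Both** embeddings are applied to every document regardless of its
  own source, because at inference time a document's provenance is
  unknown. A document with no in-vocabulary token gets the zero vector.

Skip-gram training (dim 200, window 5, min_count 2, 10 epochs, 5
negative samples, initial rate 0.025) is single-threaded with an
internal RNG, so corpus + seed reproduce vectors bit-identically. Only
`dim = 200` is externally anchored; the rest are conventional word2vec
defaults, all config-overridable.

### Tokenization and syllables

Tokens are maximal alphanumeric runs allowing internal apostrophes,
hyphens and slashes — so "140/90" and "follow-up" are single tokens.
Sentences split at terminal punctuation followed by whitespace and a
capital/digit, **plus hard newlines** (default mode): without newline
splitting, the list-style lines of clinical notes collapse into one
mega-sentence and every length feature is distorted. A `punct`-only mode
exists for conventional prose.

Syllables: a small exception dictionary, then a vowel-group heuristic
(count maximal `aeiouy` groups; subtract a silent terminal "e" unless
the word ends consonant+"le"; floor 1, so vowel-free abbreviations like
"HTN" count 1). No hyphenation library is available offline; the
heuristic is deterministic, total, and pinned by tests ("readability" →
5).

## Standardization

Raw features mix counts (hundreds) with embedding coordinates (~0.01).
The pipeline z-scores each column on the training documents and then
divides each column by √(block width), so a 200-wide embedding block
carries the same aggregate variance as the 4-wide formula block instead
of drowning it. Both transforms are stored in the model and applied
transparently at scoring time; the low-level `train_ranker()` is left
raw so oracle tests compare like with like. Whether the original system
standardized is unknowable; the diagnostics expose everything needed to
observe a discrepancy.

## Evaluation protocol

Per rater: restrict the system's scores to that rater's documents, rank
both (rater ties get average ranks), compute the two-ranking
tie-corrected Kendall W,

    W = 12 S / ( m²(n³−n) − m Σ T_j ),   T_j = Σ_groups (t³ − t),

then average W over raters. Raters with fewer than two distinctly-rated
documents are excluded with a warning. The FKGL baseline runs through
the *identical* code path with the FKGL grade as score. Paired per-rater
W values are compared with a two-sided Wilcoxon signed-rank test (exact
for ≤ 25 untied non-zero differences, normal approximation with
continuity correction otherwise; all-zero differences report p = 1).
Splitting is by document (all ratings follow their document, preventing
leakage), stratified by topic, 60/20/20 within one document per stratum,
deterministic given the seed. C is tuned on the development set by mean
per-rater W, ties to the smallest C.

## The synthetic world

No annotated corpus of this kind is public, so the generator *is* the
test bed. What it emulates:

* two sources (wikipedia/ehr) × three disease topics; EHR documents get
  list-style lines and abbreviations;
* pseudo-word lexicons built from syllable templates (easy: short,
  frequent; hard: long, rare, polysyllabic) — generated, not copied from
  any real text, keeping the package self-contained and license-clean;
* a latent difficulty per document, a fixed monotone function of the
  **realized** jargon fraction, realized mean sentence length, and
  realized abbreviation fraction (`5·d + 0.1·s + 3·a`). Realized, not
  the sampling dials: a rater responds to the text actually in front of
  them. This also makes the latent exactly linear in the surface
  features, which is what the parameter-recovery tests stipulate;
* raters: 20 pairs each, 5 wiki-wiki / 5 ehr-ehr / 10 mixed, pairs
  matched within 50 tokens and 0.5 FKGL grade, sampled without
  replacement within a rater and with replacement across raters so most
  documents collect ≥ 2 ratings (enabling the controversial-document
  screen). Ratings are a clipped affine map of standardized latent plus
  Gaussian noise (sd in latent-SD units) and a per-rater offset;
  eccentric raters apply the reversed map, `round(fraction × n_raters)`
  of them;
* presets: `tiny` (48 docs, 6 raters — unit tests), `default` (150
  docs, 20 raters), `vocabulary` (difficulty planted *only* in word
  identity: both lexicons share length and frequency profiles, sentence
  length constant — formulas are blind there by construction),
  `recovery` (strictly monotone raters, below), `paper_scale` (90
  raters, 20 pairs each, ~930 documents).

**The rater response model is a stand-in.** The true distribution of
crowd raters' response functions is unknowable; clipped-affine-plus-noise
is the minimal model producing realistic ties and disagreement. One
consequence worth knowing: an affine map of a roughly normal latent onto
ten integer levels piles the middle of the corpus onto few levels, which
caps the two-ranking W of even a perfect predictor near 0.98. The
`recovery` preset therefore switches to a quantile response — the rater
spreads ratings over the deciles of their own sample, range-frequency
style — which is strictly monotone up to rounding and lets a perfect
predictor reach W ≈ 0.998. The parameter-recovery tests use `recovery`
at the emulated study's 90 raters; the noiseless run trains at fixed
C = 10 because the world is separable there (discordant count reaches 0)
and a development set cannot distinguish C = 1 from C = 10 in that
regime, while the tie rule would pick the smaller, slightly worse one.

**What a green test does not establish.** Synthetic documents have the
statistical structure the features measure, and nothing else: no
syntax, no discourse, no semantics, no real medical vocabulary. A green
recovery test says the pipeline can find a planted linear signal under
the stated noise; it says nothing about concordance with real readers
of real clinical text.

## Rater quality control

Pairwise rater W is computed over the raters' shared documents only (the
only well-defined comparison for partially overlapping sets); pairs
sharing fewer than two usable documents are omitted. Conformity is a
rater's mean W against peers; *eccentric* means conformity < 0.5 (the
crisper of the two published characterizations; the alternative — below
0.5 against more than 10 peers — selects a slightly different set).
*Controversial* documents have ≥ 2 raters and a maximum rating
difference strictly greater than 5. Filtering removes every record
touching a dropped rater or document and then drops orphaned pair
partners; it refuses to produce an untrainable remnant (< 2 raters or
< 4 documents).

## Numerical and degenerate-input policy

* Empty or token-free documents are `DegenerateDocument`-class errors at
  tokenization, never NaNs downstream; admitted feature vectors are
  checked finite.
* The W denominator can only vanish when every rater ties everything; W
  is defined as 1 there (vacuous agreement), and clamped to [0, 1]
  against rounding.
* Model files store weights at 17 significant digits (IEEE round-trip
  exact) with a layout-version string; loading against a different
  feature layout is a hard error, as is a corrupt file.
* All randomness flows from one integer seed through a stable string
  hash (`derive_seed(seed, stage)`), so stages re-run in isolation
  reproduce.

## Known limitations

* The easy-word list is a stand-in; Dale-Chall percentages on real
  English text are approximations until the real list is supplied.
* Syllable counts use a heuristic; systematic errors on unusual
  orthography shift the formula features (consistently, so rankings
  within a corpus are less affected than absolute values).
* The SGNS implementation is single-threaded by design (determinism over
  speed); very large corpora would want a parallel trainer at the cost
  of bitwise reproducibility.
* No rater-bias modelling (offsets/scales are simulated but not
  estimated); no listwise objectives; no nonlinear kernels — the method
  under study is linear, and the package stays faithful to it.
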