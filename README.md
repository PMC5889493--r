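# readrank

Ranking-based readability assessment for medical documents.

## The problem

Patients increasingly read their own electronic health record (EHR)
notes, but clinical narratives are hard: dense jargon, abbreviations,
list fragments. Classic readability formulas such as the Flesch-Kincaid
Grade Level (FKGL),

```
FKGL = 0.39 · (words / sentence) + 11.8 · (syllables / word) − 15.59
```

assume *longer words and sentences ⇒ harder text*. EHR notes break that
assumption — abbreviations and terse list items read as short words and
short sentences, so formulas systematically under-grade them.

`readrank` instead treats readability as a **ranking** problem. Human
raters judge side-by-side document pairs on a 1–10 difficulty scale.
Within each rater, every pair of documents with different ratings yields
a training example: the feature difference vector `x′ = x_harder −
x_easier` with label +1. A linear max-margin ranker is then the
no-intercept SVM

```
min_w  ½‖w‖² + C Σ ξ_ij    s.t.  wᵀ(x_i − x_j) ≥ 1 − ξ_ij,  ξ_ij ≥ 0
```

solved by dual coordinate descent on the difference vectors. `w · x` is
a difficulty score: higher = harder. No cross-rater pairs are formed
(raters' scales need not be mutually consistent), and no intercept is
fitted (it cancels in differences).

Documents are represented by 416 features in five named blocks:

| block | width | content |
|---|---|---|
| `formula` | 4 | words/sentence, syllables/word, polysyllabic proportion (> 3 syllables), difficult-word % (off an easy-word list) |
| `freq_bins` | 10 | share of tokens in each corpus log-frequency decile |
| `length` | 2 | token count, sentence count |
| `embed_wiki` | 200 | mean skip-gram vector, Wikipedia-trained embedding |
| `embed_ehr` | 200 | mean skip-gram vector, EHR-trained embedding |

Agreement with a rater is measured by the tie-corrected **Kendall
coefficient of concordance**

```
W = 12 S / ( m² (n³ − n) − m Σ_j T_j )
```

between the rater's ordering and the system's ordering of that rater's
documents (m = 2), averaged over raters, and compared against the FKGL
baseline with a two-sided Wilcoxon signed-rank test.

Because no study of this kind ships its annotations, the package
includes a **synthetic study generator**: pseudo-word corpora with a
planted latent difficulty (jargon density, sentence length, abbreviation
rate), simulated raters with configurable noise and "eccentric"
(scale-inverted) members, side-by-side pairs matched within 50 tokens
and 0.5 FKGL grade, and a topic-stratified 60/20/20 split. Everything in
the test suite and the example below runs on generated data.

## Worked example

```r
library(readrank)

st <- simulate_study(study_config("default"), seed = 3)
fz <- build_featurizer(st$frequency_table, easy_words = st$easy_words,
                       embedding_wiki = st$embedding_wiki,
                       embedding_ehr  = st$embedding_ehr)
feats <- featurize_corpus(fz, st$docs)

tr <- split_ratings(st$ratings, st$split, "train")
dv <- split_ratings(st$ratings, st$split, "dev")
te <- split_ratings(st$ratings, st$split, "test")

m <- fit_ranker(feats, tr, dev_ratings = dv, c_grid = 10^(-3:1))
rep  <- system_vs_rater_concordance(score(m, feats), te)
base <- fkgl_baseline_concordance(te, st$docs)
compare_concordance(rep, base)
```

Output from this exact run:

```
<concordance> mean W = 0.851 over 20 raters
  baseline mean W = 0.886; Wilcoxon p = 0.0883 (not significant at alpha=0.05)
```

Read: on the *default* synthetic world the trained system agrees with
held-out raters at mean W ≈ 0.85 — and FKGL does too, because the default
generator plants much of its difficulty in word length, exactly the
channel FKGL measures. Plant difficulty purely in vocabulary choice
(word lengths and frequencies held flat) and the formulas go blind while
the embedding features still see it:

```r
sv <- simulate_study(study_config("vocabulary"), seed = 5)
# ... same pipeline ...
#> system mean W = 0.925, FKGL baseline = 0.389, Wilcoxon p = 1.9e-06
```

which reproduces the qualitative finding that motivates the method —
and, in the matching ablation (`ablation_run(sv)`), removing the
embedding block causes by far the largest drop in W (0.92 → 0.72) while
removing frequency, formula, or length features barely moves it.

## Command line

```sh
Rscript inst/exec/readrank simulate --preset default --seed 7 --out study/
Rscript inst/exec/readrank train    --in study/ --seed 7 --tune --out model.json
Rscript inst/exec/readrank rank     --model model.json --in study/ --out ranking.tsv
Rscript inst/exec/readrank evaluate --model model.json --in study/ \
                                    --baseline fkgl --report report.json
Rscript inst/exec/readrank qc       --in study/ --report qc.json \
                                    --drop-eccentric --out filtered.csv
```

## Documentation

The methods vignette (`vignettes/readability-ranking.Rmd`) describes the
model, the rater response models, every tunable parameter with its
default and rationale, what the generator does and does not emulate, and
known limitations.
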