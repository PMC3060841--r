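---
title: "Models and methods behind rhetzone"
author: "rhetzone authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhetzone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhetzone)
```

## The problem

Readers of biomedical abstracts — here, cancer risk assessors reviewing
the literature on a chemical — look for specific kinds of information:
the aim of a study, its methods, its results, the authors' conclusions.
*Information structure* schemes formalize this by assigning each sentence
a functional category. `rhetzone` implements three such schemes side by
side:

* **S1, section names** — the 4-way division familiar from structured
  abstracts: `OBJ`, `METH`, `RES`, `CON`.
* **S2, argumentative zoning** — 7 categories following the rhetorical
  progression of the scientific argument (`BKG`, `OBJ`, `METH`, `RES`,
  `CON`, `REL`, `FUT`).
* **S3, core scientific concepts** — 11 concept-driven categories that
  view a paper as the record of an investigation (`HYP`, `MOT`, `BKG`,
  `GOAL`, `OBJT`, `EXP`, `MOD`, `METH`, `OBS`, `RES`, `CON`).

The package provides (i) a corpus data model with JSON-Lines
serialization, (ii) sentence classifiers over ten linguistic feature
families, (iii) annotation analytics — inter-annotator agreement,
between-scheme association, and fault-tolerant subsumption checking —
and (iv) analysis of expert reading-time logs. Because the original
annotated corpus was never distributed, a seeded synthetic generator
reproduces its statistical structure for testing and benchmarking; the
published summary tables that *were* printed (category distributions,
agreement confusion matrices, mean reading times) ship as package data
(`cra_sentence_counts`, `cra_agreement_tables`, `cra_user_times`).

## Preprocessing

Sentence splitting is rule-based: a split occurs at `.`, `!` or `?`
followed by whitespace, except after a known abbreviation or between two
digits. Tokenization splits on whitespace and then detaches only
*leading and trailing* punctuation, so systematic chemical names such as
`2-amino-3,8-diethylimidazo[4,5-f]quinoxaline` stay intact while
`(p53)` splits into three tokens.

Syntactic annotation (POS tags, lemmas, verb-centric grammatical
relations, voice) is a pluggable backend contract
(`register_backend()`). The built-in `fallback` backend is a
lexicon-plus-suffix tagger, a rule lemmatizer, and a heuristic relation
extractor: the nearest preceding noun of a verb becomes its `ncsubj`,
the first following noun group its `dobj`, and a *be*-form followed by a
past participle marks the subject relation with `"obj"` — the passive
signal consumed by `detect_voice()`. It is deliberately simple; it
exists so that the full pipeline runs deterministically with no external
tools, and any stronger parser can be plugged in behind the same
contract, mapping its native labels onto `ncsubj`/`dobj`/`iobj`/`obj2`.
We lemmatize all lexical material before feature construction (words,
bigrams, relation triples alike), resolving in favor of uniformity the
question of whether non-verb tokens should be lemmatized.

## Features

Ten families, selectable by name for ablations
(`--features`/`features =`): `history`, `location`, `word`, `bigram`,
`verb`, `verbclass`, `pos`, `gr`, `subjobj`, `voice`. All but history
and location are binary presence features. Frequency cutoffs follow the
method's stated thresholds exactly: words and relation triples need at
least 2 training occurrences, bigrams at least 5. Two choices deserve
note:

* **Location.** Word `w` of an `N`-word abstract belongs to part
  `ceiling(10 w / N)`; the feature is the pair of parts containing the
  sentence's first and last word. The boundary arithmetic (1-based
  ceiling) is our choice; any fixed convention satisfies the published
  description.
* **Vocabulary fitting.** Cutoffs are re-fitted on each training fold by
  default, so no test material influences the feature space; a
  `global_vocab = TRUE` switch reproduces the corpus-wide variant. The
  per-fold default is mildly conservative.
* **Voice** is one four-valued sentence-level feature
  (`active`/`passive`/`both`/`none`), generalizing per-verb voice to the
  sentence unit the classifiers operate on.
* **Verb classes.** The primary path is a user-supplied TSV mapping verb
  lemmas to up to 60 lexical-semantic classes. When no table is
  available, `cluster_verbs()` provides a deterministic k-means
  clustering of verb co-occurrence vectors — a simple stand-in, fitted
  on training text only, with a fixed seed.

## Classifiers

* **Naive Bayes** — multinomial over the binary presence features with
  Laplace add-1 smoothing (the smoothing constant is our choice; the
  posterior is exposed via `nb_posterior()` and is oracle-tested against
  brute-force Bayes).
* **SVM** — one-vs-rest with a linear kernel, cost `C = 1` by default.
  The margin optimization is delegated to libsvm (via \pkg{e1071}); the
  one-vs-rest wrapper, orientation of decision values, and sparse
  instance representation live here. One-vs-rest was chosen because the
  multiclass strategy is otherwise unspecified for this method family.
* **CRF** — a linear-chain conditional random field over the sentence
  sequence of each abstract, written in R: emission, transition and
  start weights, exact forward-backward gradients, an L2 penalty
  (`lambda = 0.01`), `stats::optim` (L-BFGS-B) for fitting and Viterbi
  for decoding. The CRF consumes no explicit history feature — label
  transitions carry the sequential signal — which resolves the open
  design question of whether history should be duplicated there.
* **Baseline** — i.i.d. sampling from the empirical training label
  distribution. Its expected accuracy against labels from the same
  distribution is the collision probability $\sum_i p_i^2$, which is the
  yardstick the evaluation reports.

**History decoding.** For NB/SVM with the history family enabled,
prediction is greedy left-to-right: sentence $i$ consumes the
*predicted* label of sentence $i-1$ (`START` for the first). Greedy
decoding is the simplest reading of the error-propagation behavior this
feature is known for; a beam is a possible extension, not implemented.

## Evaluation

`zone_cv()` runs 10-fold cross-validation with the *abstract* as the
fold unit: history decoding and the CRF need intact sentence sequences,
and sentence-level splits would leak context across folds. Folds differ
in size by at most one abstract and are seeded. The pooled score is the
micro-average over all held-out sentences; per-fold metrics and the
macro-average of per-category F across folds are reported as well, since
either pooling convention is defensible. Categories that are never
predicted (or absent from a fold) get precision/recall/F of 0 with an
explicit `zero_division` flag rather than `NaN`.

## Annotation analytics

`cohen_kappa()` uses the standard chance correction from marginal
products. `chi2_stats()` reports Pearson and likelihood-ratio statistics
(zero-observed cells contribute 0 to the LR sum; degenerate tables get
`df = 0`), `assoc_coefficients()` the contingency coefficient and
Cramer's V, and `gk_lambda()` the Goodman-Kruskal proportional reduction
in error, in both directions.

Subsumption checking between categories of two schemes follows the
fault-tolerant rule: category $X$ is subsumed by target set $Y$ when at
most a tolerance fraction $T_k$ (default 0.1) of $X$'s instances carry a
label outside $Y$. The printed formula in the source material is
truncated; we reconstruct the statistic from its verbal gloss as the
out-of-target fraction with unit instance weights, and accept an
optional weight vector for the general weighted form.
`subsumption_graph()` grows union targets greedily by descending mapping
proportion until the relation holds, reporting the minimal union per
source category — it computes relations rather than hard-coding any
published list, whose printed form contains typos.

## The synthetic corpus

The generator (`generate_corpus()`) emulates the study conditions of a
1000-abstract annotated corpus:

* **Sequences.** Fine-grained (S3) labels follow a first-order Markov
  chain over categories plus a `START` state. The chain's structure
  encodes the coarse rhetorical ordering background → goal/object →
  methods → results → conclusions with small off-pattern mass, and
  category self-transitions are boosted so runs of a category occur.
  `calibrate_transitions()` then reweights category attractiveness until
  the *realized* marginal distribution — computed exactly by matrix
  products over the abstract-length distribution, no simulation —
  matches the target marginals. The default targets are the published
  per-category sentence fractions of the original corpus
  (`cra_sentence_counts$S3`). Abstract lengths are uniform on 5–12
  sentences, bracketing the original corpus mean of ~8 sentences per
  abstract.
* **Parallel labels.** S2 and S1 labels are deterministic images of the
  S3 label under `default_mapping()`, whose entries follow the dominant
  targets of the published between-scheme subsumption relations (for
  union targets, the first-listed member; two typographic errors in the
  published relation list are normalized to `GOAL → OBJ → OBJ` and
  `EXP → METH → METH`). Generating S3 first and deriving the coarser
  schemes makes the subsumption chain true by construction, which is
  what lets tests treat it as recoverable ground truth.
* **Text.** Sentences are realized from small per-category template
  lexicons that embed the cue signals the features rely on: cue verbs
  (measure/inject in experimental text, conclude/suggest in
  conclusions), tense, and passive templates in methods/experiment
  categories. No attempt is made at realistic prose.

**What passing tests do and do not show.** The synthetic corpus is far
more separable than real abstracts: lexicons are small, cues are
reliable, and classifier accuracy approaches 1.0 where the published
experiments on real text reached 0.81–0.90. Tests on it verify that the
pipeline is correct (features carry the intended signal, decoding uses
history, cross-validation does not leak, the subsumption machinery
recovers a known chain) — not that these accuracy levels transfer to
real biomedical text.

## Numerical and reporting conventions

* Exact Mann-Whitney p-values by full enumeration when $n+m \le 12$
  (valid under ties), tie-corrected normal approximation with continuity
  correction otherwise; tests are two-sided, since reading-time
  differences can go either way (and some published savings are
  negative). No multiple-testing correction is applied, matching the
  original analysis at $\alpha = 0.05$.
* Time savings are whole-percent roundings of $100(1 - t_a/t_0)$
  computed from cell means.
* Character spans are 0-based half-open; sentence indices 0-based in
  serialized form, 1-based inside R.
* Agreement and association values are reported at full precision and
  conventionally rounded to 2 decimals for display.
* The expected accuracy of the sampling baseline on the published
  fine-scheme (S3) distribution is $\sum p_i^2 = 0.171$, which rounds to
  0.17, not the 0.15 printed in the original summary table; the S1/S2
  analogues (0.288 → .29, 0.251 → .25) do agree. We treat the S3 cell as
  a misprint and exclude it from reproduction checks.

## Problem sizes

Default test and acceptance runs use the full 1000-abstract synthetic
corpus (≈8,600 sentences) for the cross-validated SVM comparison and the
subsumption recovery, 100 seeds for stochastic-expectation checks, and
1000 random small tables for the statistic-vs-oracle equivalences; toy
corpora of 2–200 abstracts back the unit tests. These sizes were chosen
to mirror the original study's scale while keeping a full check run in
the minutes range on one CPU.

## Known limitations

* The fallback syntactic backend is heuristic; its relation extraction
  is tuned for simple declarative sentences and will mislabel complex
  coordination. Real applications should plug in a biomedical parser.
* The CRF uses binary emission features shared with the other models and
  no feature conjunctions; it is a reference implementation, not a
  speed-optimized one, and is best used at moderate corpus sizes.
* `S2` categories `REL` and `FUT` never occur in synthetic corpora
  (no S3 category maps to them), mirroring their near-absence in the
  original data.
* The verb clusterer is a stand-in; published verb classifications
  should be supplied as a TSV when available.
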