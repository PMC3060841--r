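# rhetzone

Sentence-level classification of biomedical abstracts into
information-structure categories, with the annotation analytics that go
with such corpora.

Cancer risk assessors (and many other readers of biomedical literature)
scan abstracts for specific kinds of information: the aim of a study,
its methods, the results, the authors' conclusions. `rhetzone`
implements three sentence-annotation schemes of increasing granularity
and everything needed to work with them:

* **S1 — section names** (4 categories: OBJ, METH, RES, CON),
* **S2 — argumentative zoning** (7 categories: BKG, OBJ, METH, RES,
  CON, REL, FUT),
* **S3 — core scientific concepts** (11 categories: HYP, MOT, BKG,
  GOAL, OBJT, EXP, MOD, METH, OBS, RES, CON).

The package provides:

* a corpus data model (sentence spans + parallel per-scheme labels) with
  JSON-Lines and TSV readers/writers;
* biomedicine-aware sentence splitting and tokenization, plus a
  pluggable syntactic backend producing POS tags, lemmas, verb-centric
  grammatical relations (`ncsubj`, `dobj`, `iobj`, `obj2`) and voice;
* ten sentence feature families (previous-sentence **history**, abstract
  **location** in word-count tenths, words, bigrams, verbs, 60-way verb
  classes, verb POS/tense, relation triples, subject/object lemmas,
  voice) with the standard frequency cutoffs (words/relations >= 2,
  bigrams >= 5);
* four classifiers behind one fitting function `zone_model()`:
  Naive Bayes (Laplace add-1), one-vs-rest linear SVM, a linear-chain
  CRF with Viterbi decoding, and a distribution-sampling baseline whose
  expected accuracy is the collision probability sum(p_i^2); NB/SVM use
  greedy left-to-right decoding of the history feature;
* 10-fold abstract-level cross-validation (`zone_cv()`) with accuracy,
  per-category precision/recall/F and confusion matrices;
* annotation analytics: Cohen's kappa, pairwise-kappa averaging,
  Pearson/likelihood-ratio chi-squared, contingency coefficient,
  Cramer's V, Goodman-Kruskal lambda, mapping proportions, and
  fault-tolerant subsumption checking (X is subsumed by Y when at most a
  fraction T_k = 0.1 of X's instances fall outside Y);
* analysis of expert reading-time logs: cell means, whole-percent time
  savings, exact/approximate Mann-Whitney U tests, answer agreement;
* a seeded synthetic-corpus generator (`generate_corpus()`) that stands
  in for the undistributed original corpus: Markov category sequences
  calibrated to published category marginals, cue-bearing template
  text, and coarse labels derived from the fine ones so the
  between-scheme subsumption chain holds by construction.

The published summary tables of the original study corpus ship as data:
`cra_sentence_counts` (category distributions), `cra_agreement_tables`
(annotator confusion matrices) and `cra_user_times` (mean reading
times).

## Worked example

```r
library(rhetzone)

corp <- generate_corpus(generator_config(n_abstracts = 200, seed = 7))
corp
#> Annotated corpus: 200 abstracts, 1747 sentences
#> provenance: synthetic corpus (seed 7)

corpus_stats(corp, "S1")
#>   category words sentences  fraction
#> 1      OBJ  4900       469 0.2684602
#> 2     METH  2863       291 0.1665713
#> 3      RES  6507       717 0.4104179
#> 4      CON  2786       270 0.1545507

m <- zone_model(corp, "S1", kind = "svm", seed = 42)
pr <- predict(m, generate_corpus(generator_config(n_abstracts = 3,
                                                  seed = 8)))
head(pr, 4)
#>   abstract_id sentence_index label
#> 1  synth-0001              0   OBJ
#> 2  synth-0001              1  METH
#> 3  synth-0001              2  METH
#> 4  synth-0001              3   RES
```

The category fractions track the configured targets (27/17/40/16 percent
for OBJ/METH/RES/CON), and the fitted classifier labels new abstracts
sentence by sentence in the rhetorical order the generator encodes.

Agreement and user-test statistics work straight off the shipped
reference tables:

```r
cohen_kappa(cra_agreement_tables$S3)
#> Cohen's kappa = 0.60 (P_a = 0.654, P_e = 0.142, n = 2720)

mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#> Mann-Whitney U = 0 (n = 3, m = 3), two-sided p = 0.1 [exact]

percent_saving(58.2, 69.5)
#> [1] 16
```

The kappa of 0.60 is the domain-expert/linguist agreement on the
fine-grained scheme; the 16 is the percent reading-time saving of expert
A with coarse-scheme annotations. Between-scheme association and
subsumption on a parallel-annotated corpus:

```r
scheme_association(scheme_table(corp, "S1", "S2"))
#> Pearson X2 = 5241.0, LR X2 = 4562.1, df = 18 (n = 1747)
#> C = 0.866, Cramer's V = 1.000
#> lambda(B|A) = 0.833, lambda(A|B) = 1.000

head(subsumption_graph(corp), 3)
#>  source_scheme source target_scheme targets T holds
#>             S3    HYP            S2     BKG 0  TRUE
#>             S3    MOT            S2     BKG 0  TRUE
#>             S3    BKG            S2     BKG 0  TRUE
```

(Cramer's V is exactly 1 here because the generator derives S1
deterministically from S2; real annotations give values below 1.)

A thin command-line front end over the same functions is installed at
`inst/scripts/rhetzone` (`simulate`, `train`, `predict`, `evaluate`,
`agree`, `compare`, `subsume`, `usertest`).

## Vignette

`vignettes/rhetzone-methods.Rmd` documents the models, the feature
definitions and their cutoffs, the decoding and evaluation conventions,
the synthetic generator's calibration, and known limitations.
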