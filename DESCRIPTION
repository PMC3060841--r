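Package: rhetzone
Title: Rhetorical Zone Classification and Annotation Analytics for Biomedical Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sentence-level classification of biomedical abstracts into
    information-structure categories under three annotation schemes of
    increasing granularity: section names (4 categories), argumentative
    zoning (7 categories) and core scientific concepts (11 categories).
    Provides a corpus data model with JSON-Lines readers and writers, a
    biomedicine-aware tokenizer and pluggable syntactic annotation backend,
    ten sentence feature families (including previous-sentence history,
    abstract location, grammatical relations, verb classes and voice),
    Naive Bayes, one-vs-rest linear support vector machine, linear-chain
    conditional random field and distribution-sampling baseline classifiers
    with 10-fold cross-validation, inter-annotator agreement and
    between-scheme association statistics (Cohen's kappa, chi-squared,
    Goodman-Kruskal lambda, Cramer's V), fault-tolerant category
    subsumption checking, analysis of expert reading-time logs
    (Mann-Whitney U tests and time-saving summaries), and a seeded
    generator of scheme-parallel synthetic corpora for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    e1071,
    SparseM,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
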