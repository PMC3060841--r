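#' Configuration of the synthetic corpus generator
#'
#' The generator emulates a scheme-annotated corpus of biomedical
#' abstracts: fine-grained (S3) category sequences are drawn from a
#' first-order Markov chain whose realized category marginals are
#' calibrated to a target distribution, sentence text is realized from
#' small category-specific lexicons carrying the cue signals the feature
#' families rely on (cue verbs, tense, voice templates), and the coarser
#' S2/S1 labels are deterministic images of the S3 label under a
#' subsumption mapping — so the generated corpus has the between-scheme
#' subsumption structure by construction.
#'
#' @param n_abstracts Number of abstracts to generate.
#' @param sentence_lengths Integer vector of admissible
#'   sentences-per-abstract values, sampled uniformly (default 5..12).
#' @param marginals Named target S3 category distribution; the default is
#'   the category distribution reported for the original 7,985-sentence
#'   cancer-risk-assessment corpus (see [cra_sentence_counts]).
#' @param transitions Optional transition matrix (rows `START` + the 11
#'   S3 categories, columns the categories, rows summing to 1). When
#'   `NULL`, [calibrate_transitions()] builds one whose realized marginal
#'   matches `marginals`.
#' @param lexicon Per-category sentence templates; see
#'   [default_lexicon()].
#' @param mapping S3 -> S2 -> S1 label mapping; see [default_mapping()].
#' @param seed Integer seed (mandatory).
#' @return Object of class `"zone_gen_config"`.
#' @export
generator_config <- function(n_abstracts = 1000, sentence_lengths = 5:12,
                             marginals = NULL, transitions = NULL,
                             lexicon = default_lexicon(),
                             mapping = default_mapping(), seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cats <- zone_categories("S3")
  if (is.null(marginals)) {
    cnt <- cra_sentence_counts$S3
    marginals <- stats::setNames(cnt$sentences / sum(cnt$sentences),
                                 cnt$category)
  }
  stopifnot(setequal(names(marginals), cats),
            abs(sum(marginals) - 1) < 1e-9)
  marginals <- marginals[cats]
  if (is.null(transitions))
    transitions <- calibrate_transitions(marginals, sentence_lengths)
  if (!identical(rownames(transitions), c("START", cats)) ||
      !identical(colnames(transitions), cats) ||
      any(abs(rowSums(transitions) - 1) > 1e-8))
    stop("invalid transition matrix", call. = FALSE)
  if (!setequal(names(mapping$S3_S2), cats) ||
      !all(mapping$S3_S2 %in% zone_categories("S2")) ||
      !all(mapping$S2_S1 %in% zone_categories("S1")))
    stop("mapping tables must be total functions on the category sets",
         call. = FALSE)
  structure(list(n_abstracts = n_abstracts,
                 sentence_lengths = as.integer(sentence_lengths),
                 marginals = marginals, transitions = transitions,
                 lexicon = lexicon, mapping = mapping,
                 seed = as.integer(seed)),
            class = "zone_gen_config")
}

#' Default S3 -> S2 -> S1 subsumption mapping
#'
#' Each fine-grained (S3) category maps to a single argumentative-zoning
#' (S2) category and onward to a single section-name (S1) category,
#' following the dominant target of the between-scheme subsumption
#' relations (for categories subsumed by a union, the dominant member is
#' used). The mapping is total and single-valued over all 11 S3
#' categories.
#'
#' @return List with named character vectors `S3_S2` and `S2_S1`.
#' @examples
#' default_mapping()$S3_S2[["OBS"]]  # "RES"
#' @export
default_mapping <- function() {
  list(S3_S2 = c(HYP = "BKG", MOT = "BKG", BKG = "BKG", GOAL = "OBJ",
                 OBJT = "OBJ", EXP = "METH", MOD = "METH", METH = "METH",
                 OBS = "RES", RES = "RES", CON = "CON"),
       S2_S1 = c(BKG = "OBJ", OBJ = "OBJ", METH = "METH", RES = "RES",
                 CON = "CON", REL = "CON", FUT = "CON"))
}

# coarse rhetorical stage of each S3 category; transitions prefer staying
# in a stage or advancing to the next one
.s3_stages <- c(HYP = 1, MOT = 1, BKG = 1, GOAL = 2, OBJT = 2, EXP = 3,
                MOD = 3, METH = 3, OBS = 4, RES = 4, CON = 5)

#' Calibrate a category transition matrix to target marginals
#'
#' Builds a first-order transition matrix over the S3 categories (plus a
#' `START` row) with the coarse stage ordering background/motivation ->
#' goal/object -> methods/experiment -> observations/results ->
#' conclusions, and iteratively reweights the category attractiveness so
#' that the marginal category distribution realized over abstracts of the
#' given lengths matches `target`. The occupancy used for calibration is
#' computed exactly by matrix products (no simulation), so the procedure
#' is deterministic.
#'
#' @param target Named target distribution over the 11 S3 categories.
#' @param sentence_lengths Admissible abstract lengths (uniformly
#'   sampled at generation time).
#' @param max_iter,tol Calibration iteration cap and max absolute
#'   marginal error tolerance.
#' @return Transition matrix (rows `START` + categories) with rows
#'   summing to 1.
#' @export
calibrate_transitions <- function(target, sentence_lengths = 5:12,
                                  max_iter = 400, tol = 0.002) {
  cats <- zone_categories("S3")
  target <- target[cats]
  stage <- .s3_stages[cats]
  K <- length(cats)
  delta_w <- function(d) {
    if (d < 0) 0.02
    else switch(as.character(d), "0" = 1, "1" = 1.2, "2" = 0.3,
                "3" = 0.08, "4" = 0.02)
  }
  D <- outer(stage, stage, Vectorize(function(a, b) delta_w(b - a)))
  diag(D) <- diag(D) * 1.5                      # runs of a category
  start_w <- c("1" = 1, "2" = 0.35, "3" = 0.08, "4" = 0.03,
               "5" = 0.01)[as.character(stage)]
  # position weights: expected number of abstracts still active at step t
  maxlen <- max(sentence_lengths)
  posw <- vapply(seq_len(maxlen),
                 function(t) sum(sentence_lengths >= t), 0)
  w <- target
  for (it in seq_len(max_iter)) {
    P <- D * rep(w, each = K)
    P <- P / rowSums(P)
    s0 <- start_w * w; s0 <- s0 / sum(s0)
    occ <- matrix(0, maxlen, K)
    occ[1, ] <- s0
    for (t in 2:maxlen) occ[t, ] <- occ[t - 1, ] %*% P
    marg <- colSums(occ * posw)
    marg <- marg / sum(marg)
    err <- max(abs(marg - target))
    if (err < tol) break
    w <- w * (target / pmax(marg, 1e-12))^0.7
    w <- w / sum(w)
  }
  out <- rbind(START = s0, P)
  dimnames(out) <- list(c("START", cats), cats)
  out
}

#' Category lexicons for text realization
#'
#' Small hand-written template sets per S3 category. Templates embed the
#' cue signals that distinguish categories in real abstracts: cue verbs
#' (e.g. measure/inject for experimental text, conclude/suggest for
#' conclusions), tense (past in results, past participle in
#' conclusions), and voice (passive frequent in methods). Slots `{chem}`,
#' `{noun}`, `{num}` are filled at generation time. No attempt is made at
#' realistic biomedical prose; the templates exist to give the feature
#' pipeline the statistical structure it assumes.
#'
#' @return Named list (per S3 category) of lists with elements
#'   `templates` (character) and `nouns` (character).
#' @export
default_lexicon <- function() {
  list(
    HYP = list(templates = c(
      "We hypothesized that {chem} may promote {noun}.",
      "It is possible that {noun} drives the response to {chem}.",
      "{chem} might act through {noun}."),
      nouns = c("tumor formation", "oxidative stress", "dna repair",
                "cell proliferation")),
    MOT = list(templates = c(
      "The carcinogenic potential of {chem} remains poorly understood.",
      "Little is known about {noun} after exposure to {chem}.",
      "There is a need to clarify the role of {noun}."),
      nouns = c("chronic exposure", "species differences",
                "the underlying mechanism", "risk to humans")),
    BKG = list(templates = c(
      "Previous studies have shown that {chem} induces {noun} in rodents.",
      "{chem} is widely used in industry and laboratory research.",
      "It is known that {noun} contributes to carcinogenesis.",
      "Earlier reports described {noun} in exposed workers."),
      nouns = c("liver tumors", "chromosomal aberrations",
                "enzyme induction", "dna damage", "genotoxic effects")),
    GOAL = list(templates = c(
      "The aim of this study was to determine the effect of {chem} on {noun}.",
      "We sought to evaluate {noun} following {chem} treatment.",
      "The goal was to characterize {noun}."),
      nouns = c("adduct formation", "mutation frequency",
                "tumor incidence", "metabolic activation")),
    OBJT = list(templates = c(
      "This study focuses on {noun} in the rat liver.",
      "Here we present an analysis of {noun}.",
      "This paper addresses {noun} induced by {chem}."),
      nouns = c("gene expression profiles", "protein adducts",
                "cell cycle regulation", "apoptotic pathways")),
    EXP = list(templates = c(
      "Rats were injected with {num} mg/kg of {chem} for {num} weeks.",
      "Mice were exposed to {chem} in drinking water for {num} days.",
      "Animals were dosed daily and sacrificed after {num} weeks.",
      "Cells were incubated with {chem} at {num} micromolar."),
      nouns = c("male rats", "female mice", "cultured hepatocytes")),
    MOD = list(templates = c(
      "A pharmacokinetic model was used to simulate {noun}.",
      "We assumed a linear dose response model for {noun}.",
      "The two-stage model describes {noun}."),
      nouns = c("tissue dosimetry", "clonal expansion",
                "metabolite kinetics")),
    METH = list(templates = c(
      "Samples were analyzed by liquid chromatography.",
      "{noun} was measured using a standard assay.",
      "Dna adduct levels were quantified by mass spectrometry.",
      "{noun} was assessed with the comet assay."),
      nouns = c("enzyme activity", "adduct level", "micronucleus frequency",
                "cell viability", "protein expression")),
    OBS = list(templates = c(
      "A marked increase in {noun} was observed in treated animals.",
      "No significant change in {noun} was noted at low doses.",
      "Elevated {noun} was detected after {num} weeks."),
      nouns = c("adduct levels", "micronuclei", "serum enzymes",
                "tumor multiplicity")),
    RES = list(templates = c(
      "Treatment with {chem} significantly increased {noun}.",
      "{chem} reduced {noun} by {num} percent.",
      "The incidence of {noun} increased with dose.",
      "Exposure elevated {noun} in a dose dependent manner."),
      nouns = c("tumor incidence", "mutant frequency", "adduct formation",
                "cell proliferation", "apoptosis")),
    CON = list(templates = c(
      "We conclude that {chem} is genotoxic in mice.",
      "These findings suggest that {noun} mediates the response.",
      "Our results indicate that {chem} acts via a nongenotoxic mechanism.",
      "Taken together the data support a role for {noun}."),
      nouns = c("oxidative stress", "receptor activation", "dna damage",
                "regenerative proliferation")))
}

#' Generate a scheme-parallel synthetic corpus
#'
#' @param config A [generator_config()].
#' @return A [zone_corpus()] with all three schemes labeled on every
#'   sentence; the attribute `"ground_truth"` carries the mapping tables
#'   used. Identical config and seed give an identical corpus.
#' @examples
#' corp <- generate_corpus(generator_config(n_abstracts = 3, seed = 7))
#' corpus_stats(corp, "S3")
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "zone_gen_config"))
  cats <- zone_categories("S3")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  P <- config$transitions
  map32 <- config$mapping$S3_S2
  map21 <- config$mapping$S2_S1
  abstracts <- vector("list", config$n_abstracts)
  for (i in seq_len(config$n_abstracts)) {
    m <- if (length(config$sentence_lengths) == 1) config$sentence_lengths
         else sample(config$sentence_lengths, 1)
    labs <- character(m)
    prev <- "START"
    for (t in seq_len(m)) {
      labs[t] <- sample(cats, 1, prob = P[prev, ])
      prev <- labs[t]
    }
    chem <- sample(.chemicals, 1)
    sents <- vapply(labs, function(cat) {
      lx <- config$lexicon[[cat]]
      tpl <- if (length(lx$templates) == 1) lx$templates
             else sample(lx$templates, 1)
      tpl <- gsub("{chem}", chem, tpl, fixed = TRUE)
      while (grepl("{noun}", tpl, fixed = TRUE)) {
        nn <- if (length(lx$nouns) == 1) lx$nouns else sample(lx$nouns, 1)
        tpl <- sub("{noun}", nn, tpl, fixed = TRUE)
      }
      while (grepl("{num}", tpl, fixed = TRUE))
        tpl <- sub("{num}", sample(c(2, 4, 5, 10, 25, 50), 1), tpl,
                   fixed = TRUE)
      tpl
    }, "", USE.NAMES = FALSE)
    text <- paste(sents, collapse = " ")
    ends <- cumsum(nchar(sents) + 1L) - 1L
    starts <- c(0L, ends[-m] + 1L)
    sdf <- data.frame(start = starts, end = ends,
                      S1 = unname(map21[map32[labs]]),
                      S2 = unname(map32[labs]), S3 = labs,
                      stringsAsFactors = FALSE)
    abstracts[[i]] <- zone_abstract(sprintf("synth-%04d", i), text, sdf,
                                    chemical = chem)
  }
  corp <- zone_corpus(abstracts,
                      provenance = sprintf("synthetic corpus (seed %d)",
                                           config$seed))
  attr(corp, "ground_truth") <- list(mapping = config$mapping,
                                     marginals = config$marginals)
  corp
}

#' Randomly perturb scheme labels (simulated second annotator)
#'
#' Each sentence's label under `scheme` is, with probability
#' `noise_rate`, reassigned uniformly over all k categories of the scheme
#' (including its current one), so the expected fraction of changed
#' labels is `noise_rate * (k - 1) / k`.
#'
#' @param corpus A [zone_corpus()].
#' @param scheme Scheme id to perturb.
#' @param noise_rate Reassignment probability in \[0, 1\].
#' @param seed Integer seed.
#' @return The perturbed corpus.
#' @export
perturb_annotations <- function(corpus, scheme = "S3", noise_rate, seed) {
  scheme <- match.arg(scheme, c("S1", "S2", "S3"))
  if (noise_rate < 0 || noise_rate > 1)
    stop("noise_rate must be in [0, 1]", call. = FALSE)
  cats <- zone_categories(scheme)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  corpus$abstracts <- lapply(corpus$abstracts, function(a) {
    lab <- a$sentences[[scheme]]
    hit <- !is.na(lab) & stats::runif(length(lab)) < noise_rate
    if (any(hit))
      a$sentences[[scheme]][hit] <- sample(cats, sum(hit), replace = TRUE)
    a
  })
  corpus
}
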