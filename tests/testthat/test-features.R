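test_that("vocabulary cutoffs are exactly >=2 words/GRs and >=5 bigrams", {
  # "adduct" occurs twice, "quinoxaline" once
  corp <- zone_corpus(list(
    make_abstract("v-1", c("Adducts formed quickly.",
                           "Adducts formed in quinoxaline groups.")),
    make_abstract("v-2", c("Tissue samples lacked signal."))))
  voc <- fit_vocabulary(corp)
  expect_true("adduct" %in% voc$words)
  expect_false("quinoxaline" %in% voc$words)
  # bigram boundary: 4 occurrences out, 5 in ("adduct levels" lemmatized)
  mk_rep <- function(n) zone_corpus(lapply(seq_len(n), function(i)
    make_abstract(paste0("r-", i), "Adduct levels increased.")))
  expect_false("adduct_level" %in% fit_vocabulary(mk_rep(4))$bigrams)
  expect_true("adduct_level" %in% fit_vocabulary(mk_rep(5))$bigrams)
  empty <- fit_vocabulary(zone_corpus())
  expect_length(empty$words, 0)
  expect_length(empty$bigrams, 0)
  expect_length(empty$grs, 0)
})

test_that("vocabulary thresholds hold on generated corpora", {
  corp <- generate_corpus(generator_config(n_abstracts = 30, seed = 13))
  parses <- annotate_corpus(corp)
  voc <- fit_vocabulary(corp, parses)
  counts <- list(word = new.env(parent = emptyenv()),
                 bigram = new.env(parent = emptyenv()),
                 gr = new.env(parent = emptyenv()))
  bump <- function(env, k) assign(k, (if (exists(k, env,
                                             inherits = FALSE))
                                        get(k, env) else 0) + 1,
                                  envir = env)
  for (a in parses) for (p in a) {
    lem <- p$tokens$lemma
    for (w in lem) bump(counts$word, w)
    if (length(lem) > 1)
      for (b in paste(lem[-length(lem)], lem[-1], sep = "_"))
        bump(counts$bigram, b)
    if (nrow(p$grs))
      for (g in paste(p$grs$relation, p$grs$head_lemma, p$grs$dep_lemma,
                      sep = "|"))
        bump(counts$gr, g)
  }
  expect_true(all(vapply(voc$words, get, 0, envir = counts$word) >= 2))
  expect_true(all(vapply(voc$bigrams, get, 0,
                         envir = counts$bigram) >= 5))
  expect_true(all(vapply(voc$grs, get, 0, envir = counts$gr) >= 2))
})

test_that("location splits the abstract into ten word-count parts", {
  expect_equal(location_feature(1, 37), c(begin = 1L, end = 10L))
  # 100-word abstract: sentence covering words 15..35 -> parts (2, 4)
  expect_equal(location_feature(2, c(14, 21, 65)),
               c(begin = 2L, end = 4L))
  # the last word alone is part (10, 10)
  expect_equal(location_feature(2, c(99, 1)), c(begin = 10L, end = 10L))
  expect_error(location_feature(1, integer()), "no words")
  expect_error(location_feature(1, 0), "no words")
})

test_that("location parts are monotone across a document", {
  set.seed(41)
  for (rep in 1:50) {
    wc <- sample(1:30, sample(2:12, 1), replace = TRUE)
    parts <- t(vapply(seq_along(wc), location_feature, integer(2),
                      word_counts = wc))
    expect_true(all(parts[, 1] <= parts[, 2]))
    expect_true(all(parts >= 1 & parts <= 10))
    if (nrow(parts) > 1)
      expect_true(all(parts[-nrow(parts), 2] <= parts[-1, 1] + 1))
  }
})

test_that("history feature validates its category", {
  expect_identical(history_feature("START", "S1"), "hist=START")
  expect_identical(history_feature("RES", "S1"), "hist=RES")
  expect_error(history_feature("OBJT", "S1"), "not a category")
})

test_that("lexical features use verbs identified by POS", {
  corp <- zone_corpus(list(make_abstract(
    "lx", c("We conclude that styrene is genotoxic.",
            "We conclude that styrene is genotoxic."))))
  parses <- annotate_corpus(corp)
  voc <- fit_vocabulary(corp, parses)
  lex <- lexical_features(parses[[1]][[1]], voc)
  expect_setequal(lex$verb, c("verb=conclude", "verb=be"))
  expect_true(all(startsWith(lex$pos, "pos=VB")))
  # nothing in vocabulary: no word features
  voc0 <- fit_vocabulary(zone_corpus())
  p <- annotate_syntax(tokenize_sentence("Novel lexemes everywhere."))
  expect_length(lexical_features(p, voc0)$word, 0)
  # adjacency bound on bigram candidates
  expect_lte(length(lexical_features(parses[[1]][[1]], voc)$bigram),
             nrow(parses[[1]][[1]]$tokens) - 1)
})

test_that("verb classes map through the table with OTHER fallback", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("measure\t7", "inject\t7", "conclude\t12"), f)
  cls <- read_verb_classes(f)
  voc <- structure(list(verb_classes = cls), class = "zone_vocab")
  expect_identical(verb_class_feature(c("measure", "inject"), voc),
                   "vclass=7")
  expect_identical(verb_class_feature("warble", voc), "vclass=OTHER")
  expect_length(verb_class_feature(character(), voc), 0)
  bad <- tempfile(fileext = ".tsv")
  writeLines("measure\tnot-a-number", bad)
  expect_error(suppressWarnings(read_verb_classes(bad)), "malformed|class")
})

test_that("GR features carry triples, detached lemmas and voice", {
  corp <- zone_corpus(list(make_abstract(
    "gr", c("We investigated mice.", "We investigated mice."))))
  parses <- annotate_corpus(corp)
  voc <- fit_vocabulary(corp, parses)
  g <- gr_features(parses[[1]][[1]], voc)
  expect_true("gr=dobj|investigate|mouse" %in% g$gr)
  expect_true("subjobj=mouse" %in% g$subjobj)
  expect_identical(g$voice, "voice=active")
  pas <- annotate_syntax(tokenize_sentence("Tumors were induced."))
  expect_identical(gr_features(pas, voc)$voice, "voice=passive")
  none <- annotate_syntax(tokenize_sentence("The big styrene trial."))
  g0 <- gr_features(none, voc)
  expect_length(g0$gr, 0)
  expect_length(g0$subjobj, 0)
  expect_identical(g0$voice, "voice=none")
})

test_that("instance assembly is compositional over feature groups", {
  corp <- zone_corpus(list(make_abstract(
    "as", c("We measured adducts.", "We measured adducts."))))
  parses <- annotate_corpus(corp)
  voc <- fit_vocabulary(corp, parses)
  p <- parses[[1]][[1]]
  wc <- c(4L, 4L)
  all_ids <- assemble_instance(p, voc, sentence_index = 1,
                               word_counts = wc)
  g1 <- c("word", "verb")
  g2 <- c("location", "voice")
  u <- assemble_instance(p, voc, groups = union(g1, g2),
                         sentence_index = 1, word_counts = wc)
  expect_setequal(u, union(
    assemble_instance(p, voc, groups = g1, sentence_index = 1,
                      word_counts = wc),
    assemble_instance(p, voc, groups = g2, sentence_index = 1,
                      word_counts = wc)))
  # single-group and degenerate calls
  loc_only <- assemble_instance(p, voc, groups = "location",
                                sentence_index = 1, word_counts = wc)
  # word 1 of 8 sits in part ceiling(10/8) = 2; word 4 in part 5
  expect_setequal(loc_only, c("locb=2", "loce=5"))
  expect_length(assemble_instance(p, voc, groups = character(),
                                  sentence_index = 1, word_counts = wc), 0)
  expect_error(assemble_instance(p, voc, groups = "wordz"),
               "unknown feature group")
  expect_true(all(c("voice=active", "pos=VBD") %in% all_ids))
})

test_that("the stand-in verb clusterer is deterministic", {
  corp <- generate_corpus(generator_config(n_abstracts = 20, seed = 3))
  parses <- annotate_corpus(corp)
  c1 <- cluster_verbs(parses, k = 5, seed = 2)
  c2 <- cluster_verbs(parses, k = 5, seed = 2)
  expect_identical(c1, c2)
  expect_true(all(c1 >= 1 & c1 <= 5))
  expect_length(cluster_verbs(list(), k = 5, seed = 2), 0)
})
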