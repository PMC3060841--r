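# small corpus with two easily separable S1 categories plus one sentence
# whose label is only distinguishable through the history feature is built
# where needed; most oracle checks work on hand-sized instance sets.

test_that("Naive Bayes posteriors equal hand-applied Bayes with add-1", {
  corp <- zone_corpus(list(
    make_abstract("nb-1", c("Mice were dosed daily.",
                            "Adduct levels increased."),
                  S1 = c("METH", "RES")),
    make_abstract("nb-2", c("Rats were dosed daily.",
                            "Mutant levels increased."),
                  S1 = c("METH", "RES"))))
  m <- zone_model(corp, "S1", kind = "nb", seed = 1,
                  features = c("word", "verb"))
  # brute-force Bayes on the same binary instances, rebuilt independently
  parses <- annotate_corpus(corp)
  voc <- fit_vocabulary(corp, parses)
  probe <- annotate_syntax(tokenize_sentence("Adduct levels increased."))
  ids <- assemble_instance(probe, voc, groups = c("word", "verb"))
  ids <- intersect(ids, m$feature_ids)
  P <- length(m$feature_ids)
  classes <- m$classes
  # per-class counts of each feature over the 4 training sentences
  train_ids <- lapply(seq_along(parses), function(k)
    lapply(parses[[k]], function(p)
      intersect(assemble_instance(p, voc, groups = c("word", "verb")),
                m$feature_ids)))
  gold <- unlist(lapply(corp$abstracts, function(a) a$sentences$S1))
  flat <- unlist(train_ids, recursive = FALSE)
  post <- vapply(classes, function(cl) {
    sel <- which(gold == cl)
    cnt <- function(f) sum(vapply(flat[sel], function(v) f %in% v, TRUE))
    tot <- sum(lengths(flat[sel]))
    lp <- log(length(sel) / length(gold))
    for (f in ids) lp <- lp + log((cnt(f) + 1) / (tot + P))
    lp
  }, 0)
  post <- exp(post - max(post)); post <- post / sum(post)
  expect_equal(unname(nb_posterior(m, ids)[classes]), unname(post),
               tolerance = 1e-12)
  expect_equal(sum(nb_posterior(m, ids)), 1, tolerance = 1e-9)
})

test_that("NB equals brute-force Bayes on random toy sets", {
  set.seed(7)
  feats <- paste0("word=f", 1:5)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    ids <- lapply(seq_len(n), function(i)
      sample(feats, sample(0:3, 1)))
    y <- sample(c("METH", "RES"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    X <- rhetzone:::.instance_matrix(ids, feats)
    fit <- rhetzone:::.fit_nb(X, y, sort(unique(y)))
    probe <- sample(feats, 2)
    s <- drop(rhetzone:::.instance_matrix(list(probe), feats) %*%
                fit$loglik) + fit$log_prior
    # independent brute force
    oracle <- vapply(sort(unique(y)), function(cl) {
      sel <- which(y == cl)
      tot <- sum(lengths(ids[sel]))
      lp <- log(length(sel) / n)
      for (f in probe)
        lp <- lp + log((sum(vapply(ids[sel], function(v) f %in% v,
                                   TRUE)) + 1) / (tot + length(feats)))
      lp
    }, 0)
    expect_equal(unname(s), unname(oracle), tolerance = 1e-10)
  }
})

test_that("single-class training yields a constant predictor", {
  corp <- zone_corpus(lapply(1:4, function(i)
    make_abstract(paste0("sc-", i),
                  c("Mice were dosed daily.", "Rats were dosed daily."),
                  S1 = c("METH", "METH"))))
  for (kind in c("nb", "svm", "crf", "baseline")) {
    m <- zone_model(corp, "S1", kind = kind, seed = 3)
    pr <- predict(m, corp)
    expect_true(all(pr$label == "METH"), info = kind)
  }
})

test_that("training and prediction are deterministic given the seed", {
  corp <- generate_corpus(generator_config(n_abstracts = 12, seed = 21))
  probe <- generate_corpus(generator_config(n_abstracts = 4, seed = 22))
  for (kind in c("nb", "svm", "baseline")) {
    m1 <- zone_model(corp, "S1", kind = kind, seed = 5)
    m2 <- zone_model(corp, "S1", kind = kind, seed = 5)
    expect_identical(predict(m1, probe), predict(m2, probe), info = kind)
  }
})

test_that("greedy decoding follows the hand trace on a history toy", {
  # the second sentence is identical in both abstract types and is
  # separable only through the predicted label of sentence 1; classes are
  # balanced so the class token totals are equal and the hand trace below
  # is exact
  corp <- zone_corpus(list(
    make_abstract("h-1", c("Mice were dosed daily.",
                           "The signal was clear."),
                  S1 = c("METH", "METH")),
    make_abstract("h-2", c("Adduct levels increased today.",
                           "The signal was clear."),
                  S1 = c("RES", "RES")),
    make_abstract("h-3", c("Mice were dosed daily.",
                           "The signal was clear."),
                  S1 = c("METH", "METH")),
    make_abstract("h-4", c("Adduct levels increased today.",
                           "The signal was clear."),
                  S1 = c("RES", "RES"))))
  m <- zone_model(corp, "S1", kind = "nb", seed = 1,
                  features = c("word", "history"))
  pr <- predict(m, corp)
  # hand Bayes trace (add-1, equal class totals of 24, P = 13 ids):
  # sentence 2 given hist=METH scores 3*3*5*3*5*3 vs 3*3*3*3*5*1 for RES,
  # and the ratios flip when hist=RES; greedy decoding must follow
  expect_identical(pr$label[pr$abstract_id == "h-1"], c("METH", "METH"))
  expect_identical(pr$label[pr$abstract_id == "h-2"], c("RES", "RES"))
  # first sentence of an abstract decodes against the START history
  one <- zone_corpus(list(make_abstract("h-5", "Mice were dosed daily.",
                                        S1 = "METH")))
  pr1 <- predict(m, one)
  expect_equal(nrow(pr1), 1)
  expect_identical(pr1$label, "METH")
})

test_that("history is inert when disabled", {
  corp <- generate_corpus(generator_config(n_abstracts = 15, seed = 31))
  m <- zone_model(corp, "S1", kind = "nb", seed = 1,
                  features = c("word", "verb", "location"))
  probe <- generate_corpus(generator_config(n_abstracts = 5, seed = 32))
  pr_seq <- predict(m, probe)
  # per-sentence argmax computed directly from the score matrix
  parses <- annotate_corpus(probe)
  built <- rhetzone:::.build_instances(probe, parses, m$vocab,
                                       m$features, "S1")
  lab <- unlist(lapply(built, function(b) {
    X <- rhetzone:::.instance_matrix(b$ids, m$feature_ids)
    s <- rhetzone:::.score_matrix(m, X)
    colnames(s)[max.col(s, ties.method = "first")]
  }))
  expect_identical(pr_seq$label, lab)
})

test_that("a saturated model memorizes repeated abstracts", {
  a <- make_abstract("m-1", c("Mice were dosed daily.",
                              "Adduct levels increased.",
                              "We conclude styrene acts."),
                     S1 = c("METH", "RES", "CON"))
  reps <- lapply(1:6, function(i) { b <- a; b$id <- paste0("m-", i); b })
  corp <- zone_corpus(reps)
  for (kind in c("nb", "svm", "crf")) {
    m <- zone_model(corp, "S1", kind = kind, seed = 2)
    pr <- predict(m, corp)
    gold <- as.data.frame(corp)$S1
    expect_identical(pr$label, gold, info = kind)
  }
})

test_that("the baseline reproduces empirical frequencies and seeds", {
  cnt <- cra_sentence_counts$S1
  labels <- rep(cnt$category, cnt$sentences)
  d <- baseline_fit(labels)
  expect_equal(unname(unclass(d)[cnt$category]),
               cnt$sentences / sum(cnt$sentences), tolerance = 1e-12)
  expect_equal(round(unname(unclass(d)[c("OBJ", "METH", "RES", "CON")]),
                     3),
               c(0.269, 0.175, 0.401, 0.155))
  expect_identical(unclass(baseline_fit("RES")), c(RES = 1))
  expect_equal(unname(unclass(baseline_fit(rep(c("A", "B"), 10)))),
               c(0.5, 0.5))
  expect_identical(baseline_predict(d, 50, seed = 9),
                   baseline_predict(d, 50, seed = 9))
  expect_true(all(baseline_predict(baseline_fit("CON"), 10, 1) == "CON"))
  expect_error(baseline_predict(d, -1, 1), "non-negative")
})

test_that("baseline accuracy concentrates on the collision probability", {
  cnt <- cra_sentence_counts$S1
  p <- cnt$sentences / sum(cnt$sentences)
  d <- baseline_fit(rep(cnt$category, cnt$sentences))
  accs <- vapply(1:100, function(s) {
    gold <- baseline_predict(d, 2000, seed = 1000 + s)
    pred <- baseline_predict(d, 2000, seed = 5000 + s)
    mean(gold == pred)
  }, 0)
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - sum(p^2)), 3 * se + 1e-6)
})

test_that("the CRF learns transition structure on sequence toys", {
  # emission-ambiguous middle state, resolvable only by transitions
  corp <- zone_corpus(lapply(1:8, function(i)
    make_abstract(paste0("crf-", i),
                  c("Mice were dosed daily.",
                    "The signal was clear.",
                    "Adduct levels increased."),
                  S1 = c("METH", "METH", "RES"))))
  m <- zone_model(corp, "S1", kind = "crf", seed = 1,
                  features = c("word", "verb"),
                  crf_control = list(maxit = 60, lambda = 0.01))
  pr <- predict(m, corp)
  expect_identical(pr$label, as.data.frame(corp)$S1)
  expect_true(m$fit$Trans["METH", "RES"] > m$fit$Trans["RES", "METH"])
})

test_that("model misuse raises errors", {
  corp <- make_toy_corpus(4)
  expect_error(zone_model(corp, "S1", kind = "nb"), "seed")
  expect_error(zone_model(corp, "S1", kind = "nb", seed = 1,
                          features = "wordz"), "unknown feature group")
  empty <- zone_corpus(list(make_abstract("e", "Unlabeled text here.")))
  expect_error(zone_model(empty, "S1", kind = "nb", seed = 1),
               "empty training set")
})
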