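#' Fit a sentence-level information-structure classifier
#'
#' Trains a classifier that assigns each sentence of an abstract to a
#' category of one annotation scheme. Four model kinds are supported:
#' \describe{
#'   \item{`"nb"`}{Multinomial Naive Bayes over binary presence features,
#'     Laplace add-1 smoothed.}
#'   \item{`"svm"`}{One-vs-rest linear-kernel support vector machine
#'     (margin optimization delegated to \pkg{e1071}/libsvm).}
#'   \item{`"crf"`}{Linear-chain conditional random field over
#'     abstract-level sentence sequences; label transitions replace the
#'     explicit history feature, decoding is global (Viterbi).}
#'   \item{`"baseline"`}{Random sampling of labels from the empirical
#'     training distribution.}
#' }
#' For `"nb"` and `"svm"` with the history family enabled, prediction uses
#' greedy left-to-right decoding: sentence *i* consumes the predicted label
#' of sentence *i - 1* (`START` for the first sentence).
#'
#' @param corpus Training [zone_corpus()]; sentences without a label under
#'   `scheme` are dropped with a warning.
#' @param scheme Scheme id (`"S1"`, `"S2"` or `"S3"`).
#' @param kind Model kind; see Details.
#' @param features Character vector of feature family names (see
#'   [zone_features]); ignored by `"baseline"`, and `"history"` is ignored
#'   by `"crf"` (transitions carry the sequence signal).
#' @param backend Syntactic backend name.
#' @param seed Integer seed; mandatory, used for any stochastic step
#'   (baseline sampling, verb clustering).
#' @param cost SVM cost parameter C.
#' @param verb_classes Optional verb lemma -> class id map for the
#'   verbclass family.
#' @param parses Optional parse cache from [annotate_corpus()] (computed
#'   when missing).
#' @param vocab Optional pre-fitted [fit_vocabulary()]; when supplied it
#'   must have been fitted on training material only.
#' @param instance_cache Optional precomputed feature ids from
#'   [build_instance_cache()], aligned with `corpus`.
#' @param crf_control List of CRF optimizer settings (`maxit`, `lambda`
#'   L2 penalty).
#' @return Object of class `"zone_model"` with `print()`, `summary()`,
#'   `coef()` and `predict()` methods.
#' @examples
#' corp <- generate_corpus(generator_config(n_abstracts = 20, seed = 1))
#' m <- zone_model(corp, "S1", kind = "nb", seed = 1)
#' head(predict(m, corp))
#' @export
zone_model <- function(corpus, scheme, kind = c("svm", "nb", "crf",
                                                "baseline"),
                       features = .feature_groups, backend = "fallback",
                       seed, cost = 1.0, verb_classes = NULL,
                       parses = NULL, vocab = NULL, instance_cache = NULL,
                       crf_control = list(maxit = 100, lambda = 0.01)) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme, c("S1", "S2", "S3"))
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  bad <- setdiff(features, .feature_groups)
  if (length(bad))
    stop("unknown feature group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  labels_all <- unlist(lapply(corpus$abstracts,
                              function(a) a$sentences[[scheme]]))
  if (!length(labels_all) || all(is.na(labels_all)))
    stop("empty training set for scheme ", scheme, call. = FALSE)
  if (anyNA(labels_all))
    warning(sum(is.na(labels_all)),
            " unlabeled sentence(s) dropped from training")
  classes <- intersect(zone_categories(scheme), unique(stats::na.omit(
    labels_all)))

  if (kind == "baseline") {
    fit <- list(dist = baseline_fit(stats::na.omit(labels_all)))
    return(.new_zone_model(scheme, kind, features, seed, NULL, classes,
                           fit, character(), backend, cost))
  }

  if (is.null(parses)) parses <- annotate_corpus(corpus, backend)
  if (is.null(vocab))
    vocab <- fit_vocabulary(corpus, parses, verb_classes, backend)
  feats <- if (kind == "crf") setdiff(features, "history") else features
  built <- .build_instances(corpus, parses, vocab, feats, scheme,
                            cache = instance_cache)
  ids <- unlist(lapply(built, `[[`, "ids"), recursive = FALSE)
  gold <- unlist(lapply(built, `[[`, "gold"))
  keep <- !is.na(gold)
  # the training vocabulary defines the admissible columns; history values
  # the decoder can emit must have columns even if unseen
  hist_ids <- if ("history" %in% feats)
    paste0("hist=", c("START", classes)) else character()
  universe <- sort(unique(c(.allowed_ids(unique(unlist(ids[keep])), vocab),
                            hist_ids)))
  X <- .instance_matrix(ids, universe)
  if (length(hist_ids)) {
    # at training time the history feature is the gold label of the
    # previous sentence (START for the first, or when it is unlabeled)
    row <- 0L
    for (b in built) for (i in seq_along(b$ids)) {
      row <- row + 1L
      prev <- if (i == 1 || is.na(b$gold[i - 1])) "START"
              else b$gold[i - 1]
      col <- match(paste0("hist=", prev), universe)
      if (!is.na(col)) X[row, col] <- 1
    }
  }

  fit <- switch(kind,
    nb = .fit_nb(X[keep, , drop = FALSE], gold[keep], classes),
    svm = .fit_svm_ovr(X[keep, , drop = FALSE], gold[keep], classes, cost),
    crf = .fit_crf(X, built, classes, crf_control))
  .new_zone_model(scheme, kind, feats, seed, vocab, classes, fit,
                  universe, backend, cost)
}

.new_zone_model <- function(scheme, kind, features, seed, vocab, classes,
                            fit, universe, backend, cost) {
  structure(list(scheme = scheme, kind = kind, features = features,
                 seed = seed, vocab = vocab, classes = classes, fit = fit,
                 feature_ids = universe, backend = backend, cost = cost),
            class = "zone_model")
}

# one entry per abstract: list(ids = per-sentence feature id vectors
# (history excluded, vocabulary-unfiltered), gold = labels, wc =
# per-sentence word counts). Vocabulary cutoffs are applied later through
# the model's feature-id universe, so the expensive id assembly can be
# cached across folds (see instance_cache of zone_model).
.build_instances <- function(corpus, parses, vocab, features, scheme,
                             cache = NULL) {
  if (is.null(cache))
    cache <- build_instance_cache(parses, features,
                                  verb_classes = vocab$verb_classes)
  lapply(seq_along(corpus$abstracts), function(k) {
    a <- corpus$abstracts[[k]]
    c(cache[[k]], list(gold = a$sentences[[scheme]], id = a$id))
  })
}

#' Precompute per-sentence feature ids for a parse cache
#'
#' Assembles the (vocabulary-unfiltered) feature ids of every sentence
#' once, so repeated model fits over the same corpus (e.g. the folds of
#' [zone_cv()]) do not re-extract features. Pass the result as
#' `instance_cache` to [zone_model()] / [predict.zone_model()].
#'
#' @param parses Parse cache from [annotate_corpus()].
#' @param features Feature families to extract (history is handled at
#'   decode time and ignored here).
#' @param verb_classes Optional verb lemma -> class map.
#' @return List (per abstract) of lists `ids` (per-sentence feature id
#'   vectors) and `wc` (word counts).
#' @export
build_instance_cache <- function(parses, features = .feature_groups,
                                 verb_classes = NULL) {
  feats <- setdiff(features, "history")
  pv <- .permissive_vocab(verb_classes)
  lapply(parses, function(ps) {
    wc <- vapply(ps, function(p) nrow(p$tokens), 0L)
    ids <- lapply(seq_along(ps), function(i)
      assemble_instance(ps[[i]], pv, groups = feats,
                        sentence_index = i, word_counts = wc))
    list(ids = ids, wc = wc)
  })
}

# restrict observed feature ids to those admitted by a fitted vocabulary
.allowed_ids <- function(observed, vocab) {
  sets <- list(word = vocab$words, bigram = vocab$bigrams, gr = vocab$grs,
               verb = vocab$verbs, subjobj = vocab$subjobj)
  pre <- sub("=.*$", "", observed)
  val <- sub("^[^=]*=", "", observed)
  keep <- rep(TRUE, length(observed))
  for (p in names(sets)) {
    if (is.null(sets[[p]])) next
    sel <- pre == p
    keep[sel] <- val[sel] %in% sets[[p]]
  }
  observed[keep]
}

.instance_matrix <- function(ids, universe) {
  n <- length(ids)
  X <- matrix(0, n, length(universe),
              dimnames = list(NULL, universe))
  for (i in seq_len(n)) {
    hit <- ids[[i]][ids[[i]] %in% universe]
    if (length(hit)) X[i, hit] <- 1
  }
  X
}

# ---- Naive Bayes ------------------------------------------------------------

.fit_nb <- function(X, y, classes) {
  P <- ncol(X)
  counts <- matrix(0, P, length(classes),
                   dimnames = list(colnames(X), classes))
  n_c <- stats::setNames(numeric(length(classes)), classes)
  for (c in classes) {
    sel <- y == c
    n_c[c] <- sum(sel)
    counts[, c] <- colSums(X[sel, , drop = FALSE])
  }
  tot <- colSums(counts)
  loglik <- log(sweep(counts + 1, 2, tot + P, "/"))
  list(log_prior = log(n_c / length(y)), loglik = loglik)
}

# ---- one-vs-rest linear SVM -------------------------------------------------

.fit_svm_ovr <- function(X, y, classes, cost) {
  if (length(classes) == 1)
    return(list(constant = classes))
  # the instance matrix is very sparse (binary presence features);
  # libsvm is far faster on the compressed representation
  Xs <- SparseM::as.matrix.csr(X)
  machines <- lapply(classes, function(c) {
    yy <- factor(ifelse(y == c, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(Xs, yy, kernel = "linear", cost = cost, scale = FALSE,
                    fitted = FALSE)
    w <- drop(crossprod(SparseM::as.matrix(m$SV), m$coefs))  # length P
    b <- -m$rho
    # orient so that larger decision value means "pos"
    dv <- drop(X %*% w) + b
    if (mean(dv[yy == "pos"]) < mean(dv[yy == "neg"])) {
      w <- -w; b <- -b
    }
    list(w = w, b = b)
  })
  W <- vapply(machines, `[[`, numeric(ncol(X)), "w")
  colnames(W) <- classes
  list(W = W, b = vapply(machines, `[[`, 0, "b"))
}

# decision scores, one column per class (larger = more likely)
.score_matrix <- function(model, X) {
  fit <- model$fit
  if (model$kind == "nb") {
    sweep(X %*% fit$loglik, 2, fit$log_prior, "+")
  } else if (model$kind == "svm") {
    if (!is.null(fit$constant)) {
      s <- matrix(0, nrow(X), 1, dimnames = list(NULL, fit$constant))
      return(s)
    }
    sweep(X %*% fit$W, 2, fit$b, "+")
  } else stop("no score matrix for kind ", model$kind)
}

#' Posterior class distribution under a Naive Bayes model
#'
#' @param model A `zone_model` of kind `"nb"`.
#' @param ids Character vector of active feature ids of one sentence.
#' @return Named probability vector over the training classes (sums to 1).
#' @export
nb_posterior <- function(model, ids) {
  stopifnot(model$kind == "nb")
  X <- .instance_matrix(list(ids), model$feature_ids)
  s <- drop(.score_matrix(model, X))
  p <- exp(s - max(s))
  p / sum(p)
}

# ---- baseline ---------------------------------------------------------------

#' Distribution-sampling baseline
#'
#' `baseline_fit()` estimates the empirical category distribution of the
#' training labels; `baseline_predict()` draws i.i.d. labels from it. The
#' expected accuracy of such a sampler against labels drawn from the same
#' distribution is the collision probability `sum(p_i^2)`.
#'
#' @param labels Character vector of training labels.
#' @return `baseline_fit()`: named probability vector (class
#'   `"zone_label_dist"`).
#' @examples
#' d <- baseline_fit(c("RES", "RES", "CON", "OBJ"))
#' baseline_predict(d, 5, seed = 1)
#' @export
baseline_fit <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("no labels", call. = FALSE)
  tab <- table(labels)
  structure(stats::setNames(as.numeric(tab) / length(labels), names(tab)),
            class = "zone_label_dist")
}

#' @rdname baseline_fit
#' @param dist A `zone_label_dist`.
#' @param n Number of labels to draw (>= 0).
#' @param seed Integer seed (reproducible draws).
#' @export
baseline_predict <- function(dist, n, seed) {
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  stopifnot(abs(sum(dist) - 1) < 1e-9)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  sample(names(dist), n, replace = TRUE, prob = as.numeric(dist))
}

# ---- prediction -------------------------------------------------------------

#' Predict sentence categories for abstracts
#'
#' @param object A fitted [zone_model()].
#' @param newdata A [zone_corpus()].
#' @param parses Optional parse cache for `newdata`.
#' @param instance_cache Optional [build_instance_cache()] result for
#'   `newdata`.
#' @param ... Unused.
#' @return Data frame with columns `abstract_id`, `sentence_index`
#'   (0-based) and `label`.
#' @export
predict.zone_model <- function(object, newdata, parses = NULL,
                               instance_cache = NULL, ...) {
  stopifnot(inherits(newdata, "zone_corpus"))
  if (object$kind == "baseline") {
    df <- as.data.frame(newdata)
    df$label <- baseline_predict(object$fit$dist, nrow(df), object$seed)
    return(df[, c("abstract_id", "sentence_index", "label")])
  }
  if (is.null(parses) && is.null(instance_cache))
    parses <- annotate_corpus(newdata, object$backend)
  built <- .build_instances(newdata, parses, object$vocab,
                            object$features, object$scheme,
                            cache = instance_cache)
  res <- lapply(built, function(b) {
    n <- length(b$ids)
    if (n == 0)
      return(data.frame(abstract_id = character(),
                        sentence_index = integer(), label = character()))
    lab <- if (object$kind == "crf") {
      .crf_viterbi(object$fit, .instance_matrix(b$ids, object$feature_ids))
    } else if ("history" %in% object$features) {
      .greedy_decode(object, b$ids)
    } else {
      X <- .instance_matrix(b$ids, object$feature_ids)
      s <- .score_matrix(object, X)
      colnames(s)[max.col(s, ties.method = "first")]
    }
    data.frame(abstract_id = b$id, sentence_index = seq_len(n) - 1L,
               label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.greedy_decode <- function(model, ids) {
  n <- length(ids)
  X <- .instance_matrix(ids, model$feature_ids)
  hist_cols <- match(paste0("hist=", c("START", model$classes)),
                     model$feature_ids)
  names(hist_cols) <- c("START", model$classes)
  lab <- character(n)
  prev <- "START"
  for (i in seq_len(n)) {
    x <- X[i, , drop = FALSE]
    hc <- hist_cols[[prev]]
    if (!is.na(hc)) x[1, hc] <- 1
    s <- .score_matrix(model, x)
    lab[i] <- colnames(s)[which.max(s[1, ])]
    prev <- lab[i]
  }
  lab
}

#' @export
print.zone_model <- function(x, ...) {
  cat(sprintf("Sentence classifier (%s, scheme %s)\n",
              toupper(x$kind), x$scheme))
  cat("classes: ", paste(x$classes, collapse = " "), "\n", sep = "")
  if (x$kind != "baseline")
    cat("features:", paste(x$features, collapse = ", "), "\n",
        "model dimension:", length(x$feature_ids), "feature ids\n")
  invisible(x)
}

#' @export
summary.zone_model <- function(object, ...) {
  print(object)
  if (object$kind == "baseline") {
    cat("training distribution:\n")
    print(round(unclass(object$fit$dist), 3))
    cat(sprintf("expected self-accuracy sum(p^2) = %.3f\n",
                sum(object$fit$dist^2)))
  } else if (!is.null(object$vocab)) print(object$vocab)
  invisible(object)
}

#' @export
coef.zone_model <- function(object, ...) {
  switch(object$kind,
         nb = object$fit$loglik,
         svm = if (is.null(object$fit$constant)) object$fit$W else NULL,
         crf = object$fit$W,
         baseline = unclass(object$fit$dist))
}
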