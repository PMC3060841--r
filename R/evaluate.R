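#' Classification metrics and confusion matrix
#'
#' Accuracy, per-category precision, recall and F-measure (harmonic mean),
#' plus the confusion matrix (rows = predicted, columns = gold). A
#' category that is never predicted (or never gold) gets precision
#' (recall, F) 0 with an explicit `zero_division` flag, mirroring the
#' untrainable-category convention.
#'
#' @param pred,gold Equal-length character vectors of aligned labels.
#' @param categories Category order for the confusion matrix; defaults to
#'   the union of observed labels.
#' @return Object of class `"zone_metrics"`: list with `accuracy`,
#'   `by_category` (data frame `category`, `precision`, `recall`, `f`,
#'   `support`, `zero_division`), and `confusion` (matrix).
#' @examples
#' compute_metrics(c("A", "A", "B"), c("A", "B", "B"))$accuracy
#' @export
compute_metrics <- function(pred, gold, categories = NULL) {
  if (length(pred) != length(gold))
    stop("pred and gold must have equal length", call. = FALSE)
  if (!length(pred)) stop("empty input", call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(c(pred, gold)))
  cm <- table(factor(pred, levels = categories),
              factor(gold, levels = categories))
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm),
               dimnames = dimnames(cm))
  tp <- diag(cm)
  predn <- rowSums(cm)
  goldn <- colSums(cm)
  p <- ifelse(predn > 0, tp / predn, 0)
  r <- ifelse(goldn > 0, tp / goldn, 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  structure(list(
    accuracy = sum(tp) / sum(cm),
    by_category = data.frame(category = categories,
                             precision = unname(p), recall = unname(r),
                             f = unname(f), support = unname(goldn),
                             zero_division = unname(predn == 0 |
                                                      goldn == 0),
                             stringsAsFactors = FALSE),
    confusion = cm), class = "zone_metrics")
}

#' @export
print.zone_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("accuracy = %.*f (n = %d)\n", digits, x$accuracy,
              sum(x$confusion)))
  df <- x$by_category
  df[c("precision", "recall", "f")] <-
    lapply(df[c("precision", "recall", "f")], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Abstract-level k-fold partition
#'
#' Randomly divides the abstracts into `k` folds of approximately the same
#' size (sizes differ by at most one). The fold unit is the abstract, not
#' the sentence, so that history decoding and sequence models never see a
#' test abstract's context at training time.
#'
#' @param corpus A [zone_corpus()].
#' @param k Number of folds.
#' @param seed Integer seed (reproducible partition).
#' @return Integer vector of fold numbers (1..k), one per abstract.
#' @export
kfold_split <- function(corpus, k = 10, seed) {
  n <- length(corpus$abstracts)
  if (n < k) stop("fewer abstracts than folds", call. = FALSE)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Cross-validated evaluation of a classifier
#'
#' Runs abstract-level k-fold cross-validation: each fold is held out once,
#' the model (including its feature vocabulary) is re-fitted on the
#' remaining folds, and predictions on the held-out abstracts are pooled.
#' The pooled score is the micro-average over all test sentences; per-fold
#' metrics and the macro-average of per-category F across folds are also
#' reported.
#'
#' @inheritParams zone_model
#' @param k Number of folds.
#' @param global_vocab Fit the feature vocabulary once on the whole corpus
#'   instead of per training fold (reproduces a corpus-wide cutoff
#'   variant; mildly optimistic).
#' @param ... Passed on to [zone_model()].
#' @return Object of class `"zone_cv"`: list with `pooled`
#'   ([compute_metrics()] over all held-out sentences), `folds` (per-fold
#'   metrics), `fold_of` (fold assignment per abstract), `macro_f`
#'   (per-category mean F across folds where the category had support)
#'   and `spec` (scheme/kind/features/seed).
#' @export
zone_cv <- function(corpus, scheme, kind = "svm",
                    features = .feature_groups, k = 10, seed = 1,
                    backend = "fallback", global_vocab = FALSE,
                    verb_classes = NULL, ...) {
  fold_of <- kfold_split(corpus, k, seed)
  parses <- if (kind == "baseline") NULL else annotate_corpus(corpus,
                                                              backend)
  cache <- if (!is.null(parses))
    build_instance_cache(parses, features, verb_classes) else NULL
  vocab_all <- if (global_vocab)
    fit_vocabulary(corpus, parses, verb_classes, backend) else NULL
  pred_all <- character(); gold_all <- character()
  folds <- vector("list", k)
  gold_df <- as.data.frame(corpus)
  for (f in seq_len(k)) {
    tr_idx <- which(fold_of != f)
    te_idx <- which(fold_of == f)
    train <- zone_corpus(corpus$abstracts[tr_idx])
    test <- zone_corpus(corpus$abstracts[te_idx])
    m <- zone_model(train, scheme, kind = kind, features = features,
                    backend = backend, seed = seed + f,
                    verb_classes = verb_classes,
                    parses = if (!is.null(parses)) parses[tr_idx],
                    vocab = vocab_all,
                    instance_cache = if (!is.null(cache)) cache[tr_idx],
                    ...)
    pr <- predict(m, test,
                  parses = if (!is.null(parses)) parses[te_idx],
                  instance_cache = if (!is.null(cache)) cache[te_idx])
    key <- paste(pr$abstract_id, pr$sentence_index)
    gkey <- paste(gold_df$abstract_id, gold_df$sentence_index)
    gold <- gold_df[[scheme]][match(key, gkey)]
    ok <- !is.na(gold)
    folds[[f]] <- compute_metrics(pr$label[ok], gold[ok],
                                  categories = zone_categories(scheme))
    pred_all <- c(pred_all, pr$label[ok])
    gold_all <- c(gold_all, gold[ok])
  }
  pooled <- compute_metrics(pred_all, gold_all,
                            categories = zone_categories(scheme))
  fmat <- vapply(folds, function(m) {
    f <- m$by_category$f
    f[m$by_category$support == 0] <- NA
    f
  }, numeric(length(zone_categories(scheme))))
  macro_f <- rowMeans(fmat, na.rm = TRUE)
  names(macro_f) <- zone_categories(scheme)
  structure(list(pooled = pooled, folds = folds, fold_of = fold_of,
                 macro_f = macro_f,
                 spec = list(scheme = scheme, kind = kind,
                             features = features, k = k, seed = seed)),
            class = "zone_cv")
}

#' @export
print.zone_cv <- function(x, digits = 3, ...) {
  cat(sprintf("%d-fold cross-validation: %s on scheme %s\n",
              x$spec$k, toupper(x$spec$kind), x$spec$scheme))
  cat(sprintf("pooled accuracy = %.*f\n", digits, x$pooled$accuracy))
  df <- x$pooled$by_category
  df$macro_f <- round(x$macro_f[df$category], digits)
  df[c("precision", "recall", "f")] <-
    lapply(df[c("precision", "recall", "f")], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export an evaluation report
#'
#' Writes the pooled per-category table as TSV and the full report
#' (pooled, per-fold accuracies, fold sizes) as JSON.
#'
#' @param cv A [zone_cv()] result.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report list.
#' @export
write_cv_report <- function(cv, tsv = NULL, json = NULL) {
  tab <- cv$pooled$by_category
  tab$macro_f <- cv$macro_f[tab$category]
  if (!is.null(tsv))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rep <- list(spec = cv$spec, pooled_accuracy = cv$pooled$accuracy,
              fold_accuracy = vapply(cv$folds, `[[`, 0, "accuracy"),
              by_category = tab)
  if (!is.null(json))
    jsonlite::write_json(rep, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(rep)
}
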