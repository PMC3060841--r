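#' Feature families for sentence classification
#'
#' Ten feature families are available, selectable by name for ablation
#' experiments:
#' \describe{
#'   \item{history}{Category of the previous sentence (`START` for the
#'     first sentence); gold at training time, the decoder's own prediction
#'     at test time.}
#'   \item{location}{The abstract is divided into ten equal parts by word
#'     count; the feature is the pair of parts where the sentence begins
#'     and ends.}
#'   \item{word}{All lemmas of the sentence (vocabulary count >= 2).}
#'   \item{bigram}{Adjacent lemma pairs (vocabulary count >= 5).}
#'   \item{verb}{Lemmas of all verb tokens.}
#'   \item{verbclass}{Lexical-semantic class of each verb (60-class verb
#'     clustering; unmapped verbs emit `OTHER`).}
#'   \item{pos}{POS tag of each verb token (tense carrier).}
#'   \item{gr}{Verb-headed grammatical-relation triples
#'     `(relation head dependent)` (vocabulary count >= 2).}
#'   \item{subjobj}{Subject and object lemmas detached from their verbs.}
#'   \item{voice}{Sentence-level voice: `active`, `passive`, `both` or
#'     `none`.}
#' }
#' All families except history and location are binary presence features.
#'
#' @name zone_features
NULL

.feature_groups <- c("history", "location", "word", "bigram", "verb",
                     "verbclass", "pos", "gr", "subjobj", "voice")

#' Fit a feature vocabulary on training material
#'
#' Frequency cutoffs are applied exactly as stated for the method: words
#' and grammatical-relation triples with fewer than 2 occurrences and
#' bigrams with fewer than 5 occurrences in the training corpus are
#' removed. All lexical items are lemmatized.
#'
#' @param corpus Training [zone_corpus()].
#' @param parses Parse cache from [annotate_corpus()] covering the corpus
#'   (computed if missing).
#' @param verb_classes Optional named integer vector mapping verb lemma ->
#'   class id (see [read_verb_classes()] / [cluster_verbs()]), or `NULL`.
#' @param backend Backend used when `parses` is missing.
#' @return Object of class `"zone_vocab"` with character-set elements
#'   `words`, `bigrams`, `grs`, `verbs`, `subjobj`, the `verb_classes`
#'   map, and `fitted_on` (corpus fingerprint).
#' @export
fit_vocabulary <- function(corpus, parses = NULL, verb_classes = NULL,
                           backend = "fallback") {
  if (is.null(parses)) parses <- annotate_corpus(corpus, backend)
  wc <- new.env(); bc <- new.env(); gc_ <- new.env()
  verbs <- character(); subjobj <- character()
  bump <- function(env, keys) for (k in keys)
    assign(k, (if (exists(k, env, inherits = FALSE)) get(k, env) else 0) + 1,
           envir = env)
  for (a in parses) for (p in a) {
    lem <- p$tokens$lemma
    bump(wc, lem)
    if (length(lem) > 1)
      bump(bc, paste(lem[-length(lem)], lem[-1], sep = "_"))
    if (nrow(p$grs))
      bump(gc_, paste(p$grs$relation, p$grs$head_lemma, p$grs$dep_lemma,
                      sep = "|"))
    verbs <- c(verbs, lem[startsWith(p$tokens$pos, "VB")])
    subjobj <- c(subjobj, p$grs$dep_lemma[p$grs$relation %in%
                                            c("ncsubj", "dobj", "iobj",
                                              "obj2")])
  }
  keep <- function(env, thr) {
    keys <- ls(env)
    keys[vapply(keys, get, 0, envir = env) >= thr]
  }
  structure(list(words = sort(keep(wc, 2)),
                 bigrams = sort(keep(bc, 5)),
                 grs = sort(keep(gc_, 2)),
                 verbs = sort(unique(verbs)),
                 subjobj = sort(unique(subjobj)),
                 verb_classes = verb_classes,
                 fitted_on = sprintf("%d abstracts / %d parses",
                                     length(parses),
                                     sum(lengths(parses)))),
            class = "zone_vocab")
}

#' @export
print.zone_vocab <- function(x, ...) {
  cat(sprintf(paste0("Feature vocabulary (%s): %d words, %d bigrams, ",
                     "%d GR triples, %d verbs, %d subj/obj lemmas\n"),
              x$fitted_on, length(x$words), length(x$bigrams),
              length(x$grs), length(x$verbs), length(x$subjobj)))
  invisible(x)
}

#' Location of a sentence within its abstract
#'
#' The abstract is divided into ten equal parts measured by word count;
#' word `w` of `N` belongs to part `ceiling(10 w / N)`. The feature is the
#' pair of parts holding the sentence's first and last word.
#'
#' @param sentence_index 1-based sentence position within the abstract.
#' @param word_counts Integer vector of per-sentence token counts for the
#'   whole abstract, in order.
#' @return Integer vector `c(begin, end)`, each in 1..10.
#' @export
location_feature <- function(sentence_index, word_counts) {
  total <- sum(word_counts)
  if (total < 1) stop("abstract has no words", call. = FALSE)
  first_w <- if (sentence_index > 1)
    sum(word_counts[seq_len(sentence_index - 1)]) + 1 else 1
  nw <- word_counts[sentence_index]
  # a zero-length sentence inherits the position of the preceding word
  last_w <- max(first_w + nw - 1, first_w)
  first_w <- min(first_w, total); last_w <- min(last_w, total)
  c(begin = as.integer(ceiling(10 * first_w / total)),
    end = as.integer(ceiling(10 * last_w / total)))
}

#' History feature value
#'
#' @param prev Category abbreviation of the previous sentence, or
#'   `"START"` for the first sentence of an abstract.
#' @param scheme Scheme id used for validation.
#' @return Single categorical feature id of the form `"hist=<value>"`.
#' @export
history_feature <- function(prev, scheme) {
  if (prev != "START") .check_scheme_label(prev, scheme)
  paste0("hist=", prev)
}

.verb_tokens <- function(parsed) {
  parsed$tokens[startsWith(parsed$tokens$pos, "VB"), , drop = FALSE]
}

#' Lexical feature families of one sentence
#'
#' @param parsed A [parsed_sentence()].
#' @param vocab A fitted [fit_vocabulary()] object.
#' @return Named list of character vectors of feature ids: `word`,
#'   `bigram`, `verb`, `pos` (only in-vocabulary items are emitted; POS
#'   features are the tags of verb tokens).
#' @export
lexical_features <- function(parsed, vocab) {
  lem <- parsed$tokens$lemma
  big <- if (length(lem) > 1)
    paste(lem[-length(lem)], lem[-1], sep = "_") else character()
  vt <- .verb_tokens(parsed)
  list(word = .tag("word=", .filt(unique(lem), vocab$words)),
       bigram = .tag("bigram=", .filt(unique(big), vocab$bigrams)),
       verb = .tag("verb=", .filt(unique(vt$lemma), vocab$verbs)),
       pos = .tag("pos=", unique(vt$pos)))
}

# NULL vocabulary set = no filtering (filtering then happens through the
# model's feature-id universe)
.filt <- function(x, set) if (is.null(set)) x else intersect(x, set)

# paste0 recycles zero-length vectors to the bare prefix; never emit that
.tag <- function(prefix, x) {
  if (length(x)) paste0(prefix, x) else character()
}

.permissive_vocab <- function(verb_classes = NULL) {
  structure(list(words = NULL, bigrams = NULL, grs = NULL, verbs = NULL,
                 subjobj = NULL, verb_classes = verb_classes,
                 fitted_on = "unfiltered"), class = "zone_vocab")
}

#' Verb-class feature
#'
#' @param verb_lemmas Character vector of verb lemmas.
#' @param vocab A fitted vocabulary whose `verb_classes` element maps verb
#'   lemma -> class id; unmapped verbs emit the designated `OTHER` class.
#' @return Character vector of `"vclass=<id>"` feature ids.
#' @export
verb_class_feature <- function(verb_lemmas, vocab) {
  if (!length(verb_lemmas)) return(character())
  cls <- vocab$verb_classes
  ids <- vapply(verb_lemmas, function(v) {
    if (!is.null(cls) && v %in% names(cls)) as.character(cls[[v]])
    else "OTHER"
  }, "")
  .tag("vclass=", unique(ids))
}

#' Grammatical-relation feature families of one sentence
#'
#' @param parsed A [parsed_sentence()].
#' @param vocab A fitted vocabulary.
#' @return Named list: `gr` (in-vocabulary relation triples), `subjobj`
#'   (subject/object dependent lemmas detached from their verbs), `voice`
#'   (one of `voice=active|passive|both|none`).
#' @export
gr_features <- function(parsed, vocab) {
  grs <- parsed$grs
  triples <- if (nrow(grs))
    paste(grs$relation, grs$head_lemma, grs$dep_lemma, sep = "|")
  else character()
  so <- if (nrow(grs)) unique(grs$dep_lemma) else character()
  voice <- detect_voice(parsed)
  vv <- if (!length(voice)) "none"
        else if (all(voice == "active")) "active"
        else if (all(voice == "passive")) "passive"
        else "both"
  list(gr = .tag("gr=", .filt(unique(triples), vocab$grs)),
       subjobj = .tag("subjobj=", .filt(so, vocab$subjobj)),
       voice = paste0("voice=", vv))
}

#' Assemble the sparse feature vector of one sentence
#'
#' @param parsed A [parsed_sentence()].
#' @param vocab A fitted vocabulary.
#' @param groups Subset of the ten family names (see [zone_features]).
#' @param prev Previous-sentence category (or `"START"`); required when
#'   `"history"` is requested.
#' @param scheme Scheme id (history validation).
#' @param sentence_index,word_counts Sentence position and per-sentence
#'   word counts of the abstract; required when `"location"` is requested.
#' @return Character vector of active (binary) feature ids; the empty
#'   vector is the valid degenerate instance.
#' @export
assemble_instance <- function(parsed, vocab, groups = .feature_groups,
                              prev = "START", scheme = "S1",
                              sentence_index = NULL, word_counts = NULL) {
  bad <- setdiff(groups, .feature_groups)
  if (length(bad))
    stop("unknown feature group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- character()
  lex <- NULL; grf <- NULL
  if (any(c("word", "bigram", "verb", "pos") %in% groups))
    lex <- lexical_features(parsed, vocab)
  if (any(c("gr", "subjobj", "voice") %in% groups))
    grf <- gr_features(parsed, vocab)
  for (g in groups) {
    out <- c(out, switch(g,
      history = history_feature(prev, scheme),
      location = {
        if (is.null(sentence_index) || is.null(word_counts))
          stop("location feature needs sentence_index and word_counts",
               call. = FALSE)
        loc <- location_feature(sentence_index, word_counts)
        c(paste0("locb=", loc[["begin"]]), paste0("loce=", loc[["end"]]))
      },
      word = lex$word, bigram = lex$bigram, verb = lex$verb, pos = lex$pos,
      verbclass = verb_class_feature(unique(.verb_tokens(parsed)$lemma),
                                     vocab),
      gr = grf$gr, subjobj = grf$subjobj, voice = grf$voice))
  }
  unique(out)
}

#' Verb-class tables
#'
#' `read_verb_classes()` loads a two-column TSV (`verb`, `class`, 1-based
#' ids, at most 60 classes). `cluster_verbs()` is a simple stand-in
#' clusterer when no table is available: deterministic k-means (fixed
#' seed) over verb co-occurrence count vectors from the training corpus.
#'
#' @param path Path to the TSV file.
#' @return Named integer vector, verb lemma -> class id.
#' @export
read_verb_classes <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("verb", "class"))
  if (!nrow(tab) || anyNA(tab$class) || !is.numeric(tab$class))
    stop("malformed verb-class table: expected <verb>\\t<class id>",
         call. = FALSE)
  cls <- as.integer(tab$class)
  if (any(cls < 1) || length(unique(cls)) > 60)
    stop("verb-class ids must be 1-based with at most 60 classes",
         call. = FALSE)
  stats::setNames(cls, tab$verb)
}

#' @rdname read_verb_classes
#' @param parses Parse cache from [annotate_corpus()].
#' @param k Number of clusters (capped at the number of distinct verbs).
#' @param seed RNG seed for the k-means initialization.
#' @export
cluster_verbs <- function(parses, k = 60, seed = 1) {
  verbs <- character(); ctx <- list()
  for (a in parses) for (p in a) {
    vl <- unique(p$tokens$lemma[startsWith(p$tokens$pos, "VB")])
    for (v in vl) ctx[[v]] <- c(ctx[[v]], setdiff(p$tokens$lemma, v))
  }
  verbs <- names(ctx)
  if (!length(verbs)) return(stats::setNames(integer(), character()))
  vocab <- sort(unique(unlist(ctx)))
  m <- matrix(0, length(verbs), length(vocab),
              dimnames = list(verbs, vocab))
  for (v in verbs) {
    tab <- table(ctx[[v]])
    m[v, names(tab)] <- as.numeric(tab)
  }
  k <- min(k, length(verbs))
  if (k == length(verbs))
    return(stats::setNames(seq_along(verbs), verbs))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  fit <- stats::kmeans(m, centers = k, nstart = 3, iter.max = 50)
  stats::setNames(as.integer(fit$cluster), verbs)
}

.save_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
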