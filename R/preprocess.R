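#' Sentence boundary detection
#'
#' Rule-based splitter: a sentence ends at `.`, `!` or `?` followed by
#' whitespace, unless the period terminates a known abbreviation or sits
#' between two digits (decimal numbers, section references). Returned spans
#' are 0-based half-open character offsets; they are ordered,
#' non-overlapping and jointly cover every non-whitespace character.
#'
#' @param text A single string (possibly empty).
#' @return Data frame with integer columns `start` and `end`; zero rows for
#'   empty or all-whitespace input.
#' @examples
#' split_sentences("Mice were dosed. Tumors formed.")
#' @export
split_sentences <- function(text) {
  empty <- data.frame(start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  is_ws <- grepl("^\\s$", chars)
  boundaries <- integer()
  for (i in seq_len(n)) {
    if (!chars[i] %in% c(".", "!", "?")) next
    if (i < n && !is_ws[i + 1]) next              # no whitespace follows
    if (chars[i] == ".") {
      # no split between digits (defensive; decimals rarely precede space)
      nxt <- i + 1
      while (nxt <= n && is_ws[nxt]) nxt <- nxt + 1
      if (i > 1 && grepl("[0-9]", chars[i - 1]) && nxt <= n &&
          grepl("[0-9]", chars[nxt])) next
      # abbreviation check on the word ending at the period
      j <- i - 1
      while (j >= 1 && !is_ws[j]) j <- j - 1
      word <- tolower(paste(chars[(j + 1):i], collapse = ""))
      if (word %in% .abbreviations) next
    }
    boundaries <- c(boundaries, i)
  }
  starts <- integer(); ends <- integer()
  cur <- 1
  for (b in c(boundaries, n)) {
    while (cur <= b && is_ws[cur]) cur <- cur + 1
    if (cur > b) next
    e <- b
    while (e >= cur && is_ws[e]) e <- e - 1
    starts <- c(starts, cur - 1L)
    ends <- c(ends, e)
    cur <- b + 1
  }
  if (!length(starts)) return(empty)
  data.frame(start = starts, end = as.integer(ends))
}

.abbreviations <- c("e.g.", "i.e.", "al.", "fig.", "figs.", "vs.", "no.",
                    "approx.", "ca.", "cf.", "etc.", "resp.", "dr.",
                    "sp.", "spp.", "wt.", "mol.")

#' Biomedicine-aware tokenization
#'
#' Splits a sentence on whitespace, then detaches leading and trailing
#' punctuation from each token while keeping token-internal hyphens,
#' commas and brackets intact, so that systematic chemical names such as
#' `2-amino-3,8-diethylimidazo[4,5-f]quinoxaline` survive as one token.
#'
#' @param sentence A single string.
#' @return Character vector of surface tokens (empty for empty input).
#' @examples
#' tokenize_sentence("DNA damage (p53) increased.")
#' @export
tokenize_sentence <- function(sentence) {
  if (is.na(sentence) || !nzchar(trimws(sentence))) return(character())
  raw <- strsplit(trimws(sentence), "\\s+")[[1]]
  out <- character()
  lead <- c("(", "[", "{", "\"", "'")
  trail <- c(".", ",", ";", ":", "!", "?", ")", "]", "}", "\"", "'", "%")
  for (tok in raw) {
    pre <- character(); post <- character()
    while (nchar(tok) > 1 && substr(tok, 1, 1) %in% lead) {
      pre <- c(pre, substr(tok, 1, 1))
      tok <- substr(tok, 2, nchar(tok))
    }
    while (nchar(tok) > 1) {
      ch <- substr(tok, nchar(tok), nchar(tok))
      if (!ch %in% trail) break
      open <- c(")" = "(", "]" = "[", "}" = "{")[ch]
      if (!is.na(open) &&
          grepl(open, substr(tok, 1, nchar(tok) - 1), fixed = TRUE)) break
      post <- c(ch, post)
      tok <- substr(tok, 1, nchar(tok) - 1)
    }
    out <- c(out, pre, tok, post)
  }
  out
}

# ---- syntactic annotation backends -----------------------------------------

.backend_registry <- new.env(parent = emptyenv())

#' Syntactic backend registry
#'
#' Syntactic annotation (POS tags, lemmas, verb-centric grammatical
#' relations, voice) is produced by a pluggable backend. A backend is a
#' function taking a character vector of surface tokens and returning a
#' [parsed_sentence()]. Backends emitting other dependency inventories must
#' map them onto the verb-centric relations `ncsubj`, `dobj`, `iobj`,
#' `obj2`, with the `"obj"` marker on a subject relation signalling passive
#' voice. The built-in `"fallback"` backend (lexicon+suffix tagger,
#' rule-based lemmatizer, heuristic relation extractor) requires no
#' external tools.
#'
#' @param name Backend name.
#' @param fun Backend function (`function(tokens) -> parsed_sentence`).
#' @export
register_backend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .backend_registry)
  invisible(name)
}

#' @rdname register_backend
#' @export
list_backends <- function() sort(ls(.backend_registry))

#' Parsed sentence container
#'
#' @param tokens Data frame with columns `surface`, `lemma`, `pos`,
#'   `index` (1-based, contiguous).
#' @param grs Data frame of verb-headed grammatical relations with columns
#'   `relation` (one of `ncsubj`, `dobj`, `iobj`, `obj2`), `head_lemma`,
#'   `head_index`, `dep_lemma`, `dep_index`, `marker` (`NA` or `"obj"`).
#' @param verb_voice Named character vector, verb token index ->
#'   `"active"`/`"passive"`.
#' @return Object of class `"parsed_sentence"`.
#' @export
parsed_sentence <- function(tokens, grs = .empty_grs(), verb_voice = NULL) {
  stopifnot(all(c("surface", "lemma", "pos", "index") %in% names(tokens)))
  if (nrow(tokens) && !identical(tokens$index, seq_len(nrow(tokens))))
    stop("token indices must be contiguous from 1", call. = FALSE)
  if (nrow(grs)) {
    if (!all(grs$relation %in% c("ncsubj", "dobj", "iobj", "obj2")))
      stop("unknown grammatical relation", call. = FALSE)
    if (any(grs$head_index > nrow(tokens)) ||
        any(grs$dep_index > nrow(tokens)))
      stop("grammatical relation endpoint out of range", call. = FALSE)
  }
  if (is.null(verb_voice))
    verb_voice <- stats::setNames(character(), character())
  structure(list(tokens = tokens, grs = grs, verb_voice = verb_voice),
            class = "parsed_sentence")
}

.empty_grs <- function() {
  data.frame(relation = character(), head_lemma = character(),
              head_index = integer(), dep_lemma = character(),
              dep_index = integer(), marker = character(),
              stringsAsFactors = FALSE)
}

#' @export
print.parsed_sentence <- function(x, ...) {
  cat(sprintf("Parsed sentence: %d tokens, %d relations\n",
              nrow(x$tokens), nrow(x$grs)))
  if (nrow(x$grs))
    cat(paste(sprintf("  (%s %s_%d %s_%d%s)", x$grs$relation,
                      x$grs$head_lemma, x$grs$head_index, x$grs$dep_lemma,
                      x$grs$dep_index,
                      ifelse(is.na(x$grs$marker), "",
                             paste0(" ", x$grs$marker))),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Annotate a tokenized sentence
#'
#' @param tokens Character vector of surface tokens (from
#'   [tokenize_sentence()]).
#' @param backend Backend name; see [register_backend()].
#' @return A [parsed_sentence()]. Deterministic for a fixed backend and
#'   input; only verb-headed relations are retained.
#' @export
annotate_syntax <- function(tokens, backend = "fallback") {
  if (!exists(backend, envir = .backend_registry, inherits = FALSE))
    stop(sprintf("syntactic backend '%s' is not registered", backend),
         call. = FALSE)
  fun <- get(backend, envir = .backend_registry)
  parsed <- fun(tokens)
  if (!inherits(parsed, "parsed_sentence"))
    stop("backend did not return a parsed_sentence", call. = FALSE)
  parsed
}

#' Voice of each verb from its subject relation
#'
#' A verb whose `ncsubj` relation carries the `"obj"` marker is passive; a
#' verb with an unmarked `ncsubj` is active; verbs without a subject
#' relation are absent from the map. A function of the relations only.
#'
#' @param parsed A [parsed_sentence()].
#' @return Named character vector, verb index -> `"active"`/`"passive"`.
#' @export
detect_voice <- function(parsed) {
  grs <- parsed$grs
  sub <- grs[grs$relation == "ncsubj", , drop = FALSE]
  if (!nrow(sub)) return(stats::setNames(character(), character()))
  voice <- ifelse(!is.na(sub$marker) & sub$marker == "obj",
                  "passive", "active")
  # one voice per verb; a marked subject wins if a verb has several
  out <- tapply(voice, sub$head_index,
                function(v) if (any(v == "passive")) "passive" else "active")
  stats::setNames(as.character(out), names(out))
}

# ---- built-in fallback backend ---------------------------------------------

.be_forms <- c("is", "are", "was", "were", "be", "been", "being", "am")

.verb_lexicon <- c(
  "measure", "inject", "treat", "expose", "dose", "administer", "examine",
  "investigate", "analyze", "analyse", "assay", "assess", "perform",
  "conduct", "conclude", "suggest", "indicate", "observe", "detect",
  "increase", "decrease", "reduce", "induce", "inhibit", "enhance",
  "demonstrate", "report", "show", "find", "study", "compare", "evaluate",
  "determine", "test", "give", "use", "reveal", "confirm", "hypothesize",
  "postulate", "propose", "predict", "aim", "seek", "focus", "address",
  "remain", "require", "simulate", "model", "assume", "estimate", "apply",
  "collect", "record", "note", "quantify", "obtain", "occur", "support",
  "establish", "describe", "identify", "cause", "form", "develop",
  "associate", "correlate", "need", "involve", "mediate", "affect",
  "elevate", "alter", "lack", "warrant", "highlight", "implicate",
  "sacrifice", "randomize", "incubate", "culture", "stain", "monitor")

.irregular_lemmas <- c(
  is = "be", are = "be", was = "be", were = "be", been = "be", being = "be",
  am = "be", gave = "give", given = "give", found = "find", shown = "show",
  showed = "show", did = "do", done = "do", does = "do", made = "make",
  making = "make", has = "have", had = "have", having = "have",
  mice = "mouse", women = "woman", men = "man", analyses = "analysis",
  hypotheses = "hypothesis", took = "take", taken = "take")

.undouble <- function(w) {
  n <- nchar(w)
  if (n >= 2 && substr(w, n, n) == substr(w, n - 1, n - 1))
    substr(w, 1, n - 1) else w
}

#' Rule-based lemmatizer of the fallback backend
#'
#' @param word Surface token (any case).
#' @return Lower-cased lemma.
#' @export
lemmatize <- function(word) {
  w <- tolower(word)
  if (w %in% names(.irregular_lemmas)) return(unname(.irregular_lemmas[w]))
  if (grepl("[0-9\\[\\]]", w) || nchar(w) <= 3) return(w)
  try_lex <- function(cands) {
    hit <- cands[cands %in% .verb_lexicon]
    if (length(hit)) hit[1] else NA_character_
  }
  if (grepl("ied$", w)) {
    cand <- try_lex(sub("ied$", "y", w))
    return(if (!is.na(cand)) cand else sub("ied$", "y", w))
  }
  if (grepl("ed$", w)) {
    cand <- try_lex(c(sub("d$", "", w), sub("ed$", "", w),
                      .undouble(sub("ed$", "", w))))
    return(if (!is.na(cand)) cand else sub("ed$", "", w))
  }
  if (grepl("ing$", w)) {
    stem <- sub("ing$", "", w)
    cand <- try_lex(c(stem, paste0(stem, "e"), .undouble(stem)))
    return(if (!is.na(cand)) cand else stem)
  }
  if (grepl("ies$", w)) return(sub("ies$", "y", w))
  if (grepl("es$", w)) {
    cand <- try_lex(c(sub("s$", "", w), sub("es$", "", w)))
    if (!is.na(cand)) return(cand)
    return(if (grepl("(x|z|ch|sh|ss)es$", w)) sub("es$", "", w)
           else sub("s$", "", w))
  }
  if (grepl("[^su]s$", w)) return(sub("s$", "", w))
  w
}

.tag_tokens <- function(tokens) {
  n <- length(tokens)
  lower <- tolower(tokens)
  lemma <- vapply(tokens, lemmatize, "", USE.NAMES = FALSE)
  pos <- rep("NN", n)
  dets <- c("the", "a", "an", "this", "these", "those", "that", "each",
            "all", "both", "no")
  preps <- c("of", "in", "on", "with", "by", "for", "to", "from", "at",
             "into", "after", "during", "between", "against", "via",
             "within", "than")
  prons <- c("we", "it", "they", "i", "he", "she", "our", "its", "their")
  advs <- c("significantly", "markedly", "strongly", "not", "also",
            "previously", "respectively", "here", "however", "clearly",
            "further", "then", "thus")
  for (i in seq_len(n)) {
    w <- lower[i]
    if (grepl("^[[:punct:]]+$", w)) pos[i] <- "PUNCT"
    else if (grepl("^[0-9.,/%-]+$", w)) pos[i] <- "CD"
    else if (w %in% dets) pos[i] <- "DT"
    else if (w %in% prons) pos[i] <- "PRP"
    else if (w %in% preps) pos[i] <- "IN"
    else if (w %in% c("and", "or", "but", "whereas", "while")) pos[i] <- "CC"
    else if (w %in% advs) pos[i] <- "RB"
    else if (w %in% c("may", "might", "can", "could", "should", "would",
                      "must", "will")) pos[i] <- "MD"
    else if (w %in% c("is", "are", "am")) pos[i] <- "VBZ"
    else if (w %in% c("was", "were")) pos[i] <- "VBD"
    else if (w %in% c("been")) pos[i] <- "VBN"
    else if (w %in% c("be")) pos[i] <- "VB"
    else if (w %in% c("being")) pos[i] <- "VBG"
    else if (lemma[i] %in% .verb_lexicon) {
      if (grepl("(ed|en)$", w)) pos[i] <- "VBD"
      else if (grepl("ing$", w)) pos[i] <- "VBG"
      else if (grepl("s$", w) && lemma[i] != w) pos[i] <- "VBZ"
      else pos[i] <- "VBP"
    }
  }
  # participle context: -ed verb form preceded (within 2 tokens) by a
  # be-form or "been" is a past participle
  for (i in seq_len(n)) {
    if (pos[i] == "VBD" && grepl("(ed|en|wn)$", lower[i])) {
      back <- max(1, i - 3):max(1, i - 1)
      if (i > 1 && any(lower[back] %in% .be_forms)) pos[i] <- "VBN"
    }
  }
  data.frame(surface = tokens, lemma = lemma, pos = pos,
             index = seq_len(n), stringsAsFactors = FALSE)
}

.fallback_backend <- function(tokens) {
  if (!length(tokens))
    return(parsed_sentence(.tag_tokens(character())))
  tok <- .tag_tokens(tokens)
  n <- nrow(tok)
  is_verb <- startsWith(tok$pos, "VB")
  nounish <- tok$pos %in% c("NN", "PRP", "CD")
  grs <- .empty_grs()
  add_gr <- function(rel, h, d, marker = NA_character_) {
    rbind(grs, data.frame(relation = rel, head_lemma = tok$lemma[h],
                          head_index = h, dep_lemma = tok$lemma[d],
                          dep_index = d, marker = marker,
                          stringsAsFactors = FALSE))
  }
  verb_idx <- which(is_verb)
  for (v in verb_idx) {
    # skip auxiliary be-forms that support a following participle
    if (tolower(tok$surface[v]) %in% .be_forms) {
      ahead <- (v + 1):min(n, v + 3)
      if (v < n && any(tok$pos[ahead] == "VBN")) next
    }
    passive <- FALSE
    if (tok$pos[v] == "VBN") {
      back <- max(1, v - 3):max(1, v - 1)
      passive <- v > 1 && any(tolower(tok$surface[back]) %in% .be_forms)
    }
    # subject: nearest nounish token before the verb (and before its
    # auxiliary), with no other verb in between
    lo <- v - 1
    while (lo >= 1 && (tolower(tok$surface[lo]) %in% .be_forms ||
                       tok$pos[lo] %in% c("RB", "MD"))) lo <- lo - 1
    subj <- NA_integer_
    for (j in rev(seq_len(max(lo, 0)))) {
      if (is_verb[j] && !tolower(tok$surface[j]) %in% .be_forms) break
      if (nounish[j]) { subj <- j; break }
    }
    if (!is.na(subj))
      grs <- add_gr("ncsubj", v, subj,
                    marker = if (passive) "obj" else NA_character_)
    # direct object: first nounish token after the verb before a verb,
    # conjunction or clause boundary (passive verbs take no dobj here)
    if (!passive && v < n) {
      for (j in (v + 1):n) {
        if (is_verb[j] || tok$pos[j] %in% c("CC", "PUNCT") ||
            tolower(tok$surface[j]) == "that") break
        if (tok$pos[j] == "IN") break
        if (nounish[j] && tok$pos[j] != "PRP") {
          # take the last noun of the contiguous noun group (head noun)
          k <- j
          while (k < n && nounish[k + 1] && tok$pos[k + 1] != "PRP")
            k <- k + 1
          grs <- add_gr("dobj", v, k)
          break
        }
      }
    }
  }
  ps <- parsed_sentence(tok, grs)
  ps$verb_voice <- detect_voice(ps)
  ps
}

#' Parse every sentence of a corpus
#'
#' @param corpus A [zone_corpus()].
#' @param backend Backend name.
#' @return Nested list: per abstract (named by id), a list of
#'   [parsed_sentence()] objects, one per sentence.
#' @export
annotate_corpus <- function(corpus, backend = "fallback") {
  out <- lapply(corpus$abstracts, function(a)
    lapply(sentence_text(a), function(s)
      annotate_syntax(tokenize_sentence(s), backend = backend)))
  names(out) <- vapply(corpus$abstracts, `[[`, "", "id")
  out
}
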