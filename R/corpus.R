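#' Annotated abstract corpora
#'
#' A `zone_corpus` is an ordered collection of abstracts, each carrying its
#' raw text, sentence spans (0-based, half-open character offsets) and a
#' partial map from scheme id to category label per sentence. Corpora
#' round-trip losslessly through [write_corpus()] / [read_corpus()].
#'
#' @param abstracts List of [zone_abstract()] objects.
#' @param provenance Free-text metadata string.
#' @return An object of class `"zone_corpus"`.
#' @export
zone_corpus <- function(abstracts = list(), provenance = "") {
  x <- structure(list(abstracts = abstracts, provenance = provenance),
                 class = "zone_corpus")
  validate_corpus(x)
  x
}

.chemicals <- c("1,3-Butadiene", "Benzo(a)pyrene", "Chloroform",
                "Diethylnitrosamine", "Diethylstilbestrol", "Fumonisin B1",
                "Phenobarbital", "Styrene")

#' @rdname zone_corpus
#' @param id Document identifier, unique within a corpus.
#' @param text Raw abstract text.
#' @param sentences Data frame with integer columns `start`, `end`
#'   (0-based half-open character offsets into `text`) and optional
#'   character columns `S1`, `S2`, `S3` holding category abbreviations
#'   (`NA` for unlabeled).
#' @param chemical Optional chemical tag (one of the eight study
#'   chemicals), or `NULL`.
#' @export
zone_abstract <- function(id, text, sentences = NULL, chemical = NULL) {
  if (is.null(sentences))
    sentences <- data.frame(start = integer(), end = integer())
  for (s in c("S1", "S2", "S3"))
    if (is.null(sentences[[s]])) sentences[[s]] <- rep(NA_character_,
                                                       nrow(sentences))
  sentences <- sentences[, c("start", "end", "S1", "S2", "S3"), drop = FALSE]
  rownames(sentences) <- NULL
  structure(list(id = as.character(id),
                 chemical = if (is.null(chemical) || is.na(chemical)) NULL
                            else as.character(chemical),
                 text = text, sentences = sentences),
            class = "zone_abstract")
}

.validate_abstract <- function(a) {
  s <- a$sentences
  n <- nrow(s)
  if (n > 0) {
    if (any(s$start < 0) || any(s$end > nchar(a$text)) ||
        any(s$end <= s$start))
      stop(sprintf("abstract '%s': sentence spans out of bounds", a$id),
           call. = FALSE)
    if (n > 1 && any(s$start[-1] < s$end[-n]))
      stop(sprintf("abstract '%s': sentence spans overlap or are unordered",
                   a$id), call. = FALSE)
    for (sch in c("S1", "S2", "S3")) {
      lab <- s[[sch]]
      bad <- !is.na(lab) & !lab %in% .scheme_tables[[sch]]$abbrev
      if (any(bad))
        stop(sprintf(
          "abstract '%s', sentence %d: '%s' is not a category of scheme %s",
          a$id, which(bad)[1] - 1L, lab[which(bad)[1]], sch), call. = FALSE)
    }
  }
  if (!is.null(a$chemical) && !a$chemical %in% .chemicals)
    stop(sprintf("abstract '%s': unknown chemical tag '%s'", a$id,
                 a$chemical), call. = FALSE)
  invisible(a)
}

#' @rdname zone_corpus
#' @param x A `zone_corpus`.
#' @export
validate_corpus <- function(x) {
  stopifnot(inherits(x, "zone_corpus"))
  ids <- vapply(x$abstracts, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate abstract ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (a in x$abstracts) .validate_abstract(a)
  invisible(x)
}

#' @export
print.zone_corpus <- function(x, ...) {
  ns <- sum(vapply(x$abstracts, function(a) nrow(a$sentences), 0L))
  cat(sprintf("Annotated corpus: %d abstracts, %d sentences\n",
              length(x$abstracts), ns))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.zone_corpus <- function(x) length(x$abstracts)

#' Sentence text of an abstract
#'
#' @param abstract A [zone_abstract()].
#' @param i Optional 1-based sentence indices; default all.
#' @return Character vector of sentence strings.
#' @export
sentence_text <- function(abstract, i = seq_len(nrow(abstract$sentences))) {
  s <- abstract$sentences[i, , drop = FALSE]
  substring(abstract$text, s$start + 1L, s$end)
}

#' Flatten a corpus to one row per sentence
#'
#' @param x A `zone_corpus`.
#' @param row.names,optional,... Ignored (data-frame method signature).
#' @return Data frame with columns `abstract_id`, `sentence_index`
#'   (0-based), `S1`, `S2`, `S3`, `text`.
#' @export
as.data.frame.zone_corpus <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  rows <- lapply(x$abstracts, function(a) {
    n <- nrow(a$sentences)
    if (n == 0) return(NULL)
    data.frame(abstract_id = a$id, sentence_index = seq_len(n) - 1L,
               S1 = a$sentences$S1, S2 = a$sentences$S2, S3 = a$sentences$S3,
               text = sentence_text(a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(abstract_id = character(), sentence_index = integer(),
                      S1 = character(), S2 = character(), S3 = character(),
                      text = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read and write annotated corpora
#'
#' The native format is JSON Lines, one abstract per line:
#' \preformatted{
#' {"id": str, "chemical": str|null, "text": str,
#'  "sentences": [{"start": int, "end": int,
#'                 "labels": {"S1": str?, "S2": str?, "S3": str?}}]}
#' }
#' A flat TSV dialect (one sentence per row: `abstract_id`,
#' `sentence_index`, `label`, `sentence_text`) is provided for
#' sequence-labeling toolchains; it carries a single scheme and
#' reconstructs text by joining sentences with one space, so only the JSONL
#' round trip is lossless.
#'
#' @param path File path.
#' @param fmt `"jsonl"` or `"tsv"`.
#' @param scheme Scheme id carried by the TSV dialect (ignored for JSONL).
#' @return `read_corpus()` returns a `zone_corpus`; `write_corpus()`
#'   returns `path` invisibly.
#' @export
read_corpus <- function(path, fmt = c("jsonl", "tsv"), scheme = "S1") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (fmt == "jsonl") .read_jsonl(path) else .read_tsv(path, scheme)
}

.read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  abstracts <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[k], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("parse error at line %d: %s", k,
                                   conditionMessage(e)), call. = FALSE))
    if (is.null(rec$id) || is.null(rec$text))
      stop(sprintf("parse error at line %d: missing 'id' or 'text'", k),
           call. = FALSE)
    sent <- rec$sentences
    sdf <- data.frame(
      start = vapply(sent, function(s) as.integer(s$start), 0L),
      end = vapply(sent, function(s) as.integer(s$end), 0L))
    for (sch in c("S1", "S2", "S3"))
      sdf[[sch]] <- vapply(sent, function(s) {
        v <- s$labels[[sch]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, "")
    chem <- rec$chemical
    if (is.list(chem) || length(chem) == 0) chem <- NULL
    abstracts[[k]] <- zone_abstract(rec$id, rec$text, sdf,
                                    chemical = chem)
  }
  zone_corpus(abstracts, provenance = sprintf("read from %s", path))
}

.read_tsv <- function(path, scheme) {
  scheme <- match.arg(scheme, c("S1", "S2", "S3"))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  need <- c("abstract_id", "sentence_index", "label", "sentence_text")
  if (!all(need %in% names(tab)))
    stop("TSV corpus must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  abstracts <- lapply(split(tab, factor(tab$abstract_id,
                                        levels = unique(tab$abstract_id))),
                      function(g) {
    g <- g[order(g$sentence_index), , drop = FALSE]
    txt <- paste(g$sentence_text, collapse = " ")
    ends <- cumsum(nchar(g$sentence_text) + 1L) - 1L
    starts <- c(0L, ends[-length(ends)] + 1L)
    sdf <- data.frame(start = starts, end = ends)
    sdf[[scheme]] <- ifelse(is.na(g$label) | g$label == "", NA_character_,
                            g$label)
    zone_abstract(g$abstract_id[1], txt, sdf)
  })
  zone_corpus(unname(abstracts), provenance = sprintf("read from %s", path))
}

#' @rdname read_corpus
#' @param corpus A `zone_corpus`.
#' @export
write_corpus <- function(corpus, path, fmt = c("jsonl", "tsv"),
                         scheme = "S1") {
  fmt <- match.arg(fmt)
  validate_corpus(corpus)
  if (fmt == "jsonl") {
    lines <- vapply(corpus$abstracts, function(a) {
      sent <- lapply(seq_len(nrow(a$sentences)), function(i) {
        labs <- list()
        for (sch in c("S1", "S2", "S3")) {
          v <- a$sentences[[sch]][i]
          if (!is.na(v)) labs[[sch]] <- jsonlite::unbox(v)
        }
        list(start = jsonlite::unbox(a$sentences$start[i]),
             end = jsonlite::unbox(a$sentences$end[i]),
             labels = labs)
      })
      jsonlite::toJSON(list(id = jsonlite::unbox(a$id),
                            chemical = jsonlite::unbox(
                              if (is.null(a$chemical)) NA_character_
                              else a$chemical),
                            text = jsonlite::unbox(a$text),
                            sentences = sent),
                       null = "null", na = "null")
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    scheme <- match.arg(scheme, c("S1", "S2", "S3"))
    df <- as.data.frame(corpus)
    out <- data.frame(abstract_id = df$abstract_id,
                      sentence_index = df$sentence_index,
                      label = df[[scheme]], sentence_text = df$text,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Per-category corpus distribution
#'
#' Tallies words and sentences per category of one scheme, mirroring the
#' standard corpus-distribution summary (words, sentences, and the fraction
#' of labeled sentences per category). Words are counted with the package
#' tokenizer ([tokenize_sentence()]), consistent with the location feature.
#'
#' @param corpus A `zone_corpus`.
#' @param scheme Scheme id.
#' @return Data frame with one row per category: `category`, `words`,
#'   `sentences`, `fraction` (of labeled sentences; `NaN` when no sentence
#'   is labeled). Attribute `"unlabeled"` counts sentences without a label
#'   under the scheme.
#' @export
corpus_stats <- function(corpus, scheme) {
  scheme <- match.arg(scheme, c("S1", "S2", "S3"))
  cats <- zone_categories(scheme)
  words <- stats::setNames(numeric(length(cats)), cats)
  sents <- stats::setNames(integer(length(cats)), cats)
  unlabeled <- 0L
  for (a in corpus$abstracts) {
    lab <- a$sentences[[scheme]]
    if (!nrow(a$sentences)) next
    wc <- vapply(sentence_text(a),
                 function(s) length(tokenize_sentence(s)), 0L,
                 USE.NAMES = FALSE)
    unlabeled <- unlabeled + sum(is.na(lab))
    for (cat in unique(lab[!is.na(lab)])) {
      sel <- !is.na(lab) & lab == cat
      words[cat] <- words[cat] + sum(wc[sel])
      sents[cat] <- sents[cat] + sum(sel)
    }
  }
  total <- sum(sents)
  data.frame(category = cats, words = unname(words),
             sentences = unname(sents),
             fraction = if (total > 0) unname(sents) / total
                        else rep(NaN, length(cats)),
             stringsAsFactors = FALSE) |>
    structure(unlabeled = unlabeled)
}
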