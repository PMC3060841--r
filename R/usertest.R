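#' Read an expert reading-test timing log
#'
#' The log is a CSV with mandatory header
#' `expert,group,abstract_id,question,seconds,answer`: one row per
#' (expert, abstract, question) with the seconds the expert needed to
#' answer and the answer given. Groups identify the annotation condition:
#' `S0` (unannotated), `S1`/`S3` (manual annotations) and `S1'`/`S3'`
#' (automatic annotations).
#'
#' @param path CSV file path.
#' @return Data frame of validated timing records.
#' @export
read_timing_log <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert", "group", "abstract_id", "question", "seconds",
            "answer")
  if (!all(need %in% names(rec)))
    stop("timing log must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  validate_timing(rec)
}

.ut_groups <- c("S0", "S1", "S3", "S1'", "S3'")
.ut_questions <- c("Q1", "Q2", "Q3a", "Q3b", "Q3c", "Q4", "Q5")

#' @rdname read_timing_log
#' @param records Data frame of timing records.
#' @export
validate_timing <- function(records) {
  if (!all(records$group %in% .ut_groups))
    stop("unknown group(s): ",
         paste(setdiff(unique(records$group), .ut_groups), collapse = ", "),
         call. = FALSE)
  if (!all(records$question %in% .ut_questions))
    stop("unknown question(s): ",
         paste(setdiff(unique(records$question), .ut_questions),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(records$seconds)) || any(records$seconds <= 0))
    stop("seconds must be positive", call. = FALSE)
  records
}

#' Mean answering times per expert, group and question
#'
#' Arithmetic mean seconds per (expert, group, question) cell, plus a
#' `TOTAL` pseudo-question per (expert, group): the sum of the
#' per-question means (equivalently, the mean per-abstract total when
#' every abstract has all questions).
#'
#' @param records Timing records (see [read_timing_log()]).
#' @return Data frame with columns `expert`, `group`, `question`
#'   (including `"TOTAL"`), `mean_seconds`, `n`.
#' @export
mean_times <- function(records) {
  validate_timing(records)
  agg <- stats::aggregate(seconds ~ expert + group + question,
                          data = records, FUN = mean)
  cnt <- stats::aggregate(seconds ~ expert + group + question,
                          data = records, FUN = length)
  agg$n <- cnt$seconds
  names(agg)[names(agg) == "seconds"] <- "mean_seconds"
  tot <- stats::aggregate(mean_seconds ~ expert + group, data = agg,
                          FUN = sum)
  tot$question <- "TOTAL"
  ntot <- stats::aggregate(n ~ expert + group, data = agg, FUN = max)
  tot$n <- ntot$n
  out <- rbind(agg[, c("expert", "group", "question", "mean_seconds",
                       "n")],
               tot[, c("expert", "group", "question", "mean_seconds",
                       "n")])
  out[order(out$expert, out$group,
            match(out$question, c(.ut_questions, "TOTAL"))), ] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Percentage of time saved with annotated abstracts
#'
#' `round(100 (1 - t_annotated / t_unannotated))` to the nearest whole
#' percent; negative savings (slower with annotations) are allowed.
#'
#' @param t_annotated,t_unannotated Mean seconds with and without
#'   annotations (`t_unannotated > 0`).
#' @return Integer percentage.
#' @examples
#' percent_saving(58.2, 69.5)  # 16
#' @export
percent_saving <- function(t_annotated, t_unannotated) {
  if (any(t_unannotated <= 0))
    stop("unannotated baseline time must be positive", call. = FALSE)
  as.integer(round(100 * (1 - t_annotated / t_unannotated)))
}

#' Mann-Whitney U test for two reading-time samples
#'
#' Two-sided test of whether two independent samples of durations come
#' from the same distribution. For small samples (`n + m <= 12`) the
#' p-value is exact, by full enumeration of all label assignments of the
#' pooled sample (valid under ties); otherwise a tie-corrected normal
#' approximation with continuity correction is used. `U` is reported for
#' `sample_a` (number of (a, b) pairs with a > b, ties counting 1/2).
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @param method `"auto"` (exact when `n + m <= 12`), or force
#'   `"exact"` / `"normal"`.
#' @return Object of class `"zone_utest"`: list with `U`, `p`, `method`
#'   (`"exact"` or `"normal-approximation"`), `n`, `m`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(sample_a); m <- length(sample_b)
  u_stat <- function(a, b) {
    sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b), 0))
  }
  U <- u_stat(sample_a, sample_b)
  use_exact <- switch(method, auto = n + m <= 12, exact = TRUE,
                      normal = FALSE)
  if (use_exact) {
    pool <- c(sample_a, sample_b)
    picks <- utils::combn(n + m, n)
    us <- apply(picks, 2, function(ix) u_stat(pool[ix], pool[-ix]))
    center <- n * m / 2
    p <- mean(abs(us - center) >= abs(U - center) - 1e-12)
    method <- "exact"
  } else {
    N <- n + m
    ties <- table(c(sample_a, sample_b))
    tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * (N + 1 - tie_corr)
    z <- (abs(U - n * m / 2) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal-approximation"
  }
  structure(list(U = U, p = p, method = method, n = n, m = m),
            class = "zone_utest")
}

#' @export
print.zone_utest <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, m = %d), two-sided p = %.4g [%s]\n",
              x$U, x$n, x$m, x$p, x$method))
  invisible(x)
}

#' Pairwise significance table for all group comparisons
#'
#' For each expert and each pair of annotation conditions, runs
#' [mann_whitney_u()] on the per-question (or per-abstract total)
#' durations and tabulates the two-sided p-values.
#'
#' @param records Timing records.
#' @param pairs List of `c(group_a, group_b)` comparisons; defaults to
#'   the eight standard condition contrasts.
#' @param per `"question"` compares per-question samples per question
#'   column; `"abstract"` compares per-abstract total times.
#' @return Data frame with columns `comparison`, `expert`, one column per
#'   question (or `TOTAL`), holding p-values.
#' @export
utest_table <- function(records, pairs = NULL,
                        per = c("question", "abstract")) {
  per <- match.arg(per)
  validate_timing(records)
  if (is.null(pairs))
    pairs <- list(c("S0", "S1"), c("S0", "S3"), c("S1", "S3"),
                  c("S1", "S1'"), c("S3", "S3'"), c("S0", "S1'"),
                  c("S0", "S3'"), c("S1'", "S3'"))
  rows <- list()
  for (pr in pairs) for (ex in sort(unique(records$expert))) {
    sub <- records[records$expert == ex, ]
    a <- sub[sub$group == pr[1], ]; b <- sub[sub$group == pr[2], ]
    if (!nrow(a) || !nrow(b)) next
    totals <- function(d) tapply(d$seconds, d$abstract_id, sum)
    cells <- if (per == "abstract") {
      list(TOTAL = mann_whitney_u(totals(a), totals(b))$p)
    } else {
      ps <- lapply(.ut_questions, function(q) {
        aa <- a$seconds[a$question == q]; bb <- b$seconds[b$question == q]
        if (length(aa) && length(bb)) mann_whitney_u(aa, bb)$p else NA
      })
      names(ps) <- .ut_questions
      ps$TOTAL <- mann_whitney_u(totals(a), totals(b))$p
      ps
    }
    rows[[length(rows) + 1]] <-
      cbind(data.frame(comparison = paste(pr[1], "vs", pr[2]),
                       expert = ex, stringsAsFactors = FALSE),
            as.data.frame(cells, check.names = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Answer agreement with a reference expert
#'
#' Percentage of (abstract, question) pairs where an expert's answer
#' matches the reference expert's answer, per annotation condition.
#' Matching is case- and whitespace-folded string equality.
#'
#' @param records Timing records (with answers).
#' @param reference_expert Expert id whose answers are the reference.
#' @param groups Annotation conditions of the compared experts' records
#'   (the reference expert's answers are taken from any condition).
#' @return Data frame with columns `expert`, `group`, `agreement`
#'   (percent), `n_pairs`.
#' @export
answer_agreement <- function(records, reference_expert,
                             groups = c("S1'", "S3'")) {
  validate_timing(records)
  norm <- function(s) gsub("\\s+", " ", trimws(tolower(s)))
  ref <- records[records$expert == reference_expert, ]
  if (!nrow(ref)) stop("no records for reference expert", call. = FALSE)
  ref_key <- paste(ref$abstract_id, ref$question)
  rows <- list()
  for (ex in setdiff(sort(unique(records$expert)), reference_expert)) {
    for (g in groups) {
      sub <- records[records$expert == ex & records$group == g, ]
      key <- paste(sub$abstract_id, sub$question)
      hit <- match(key, ref_key)
      ok <- !is.na(hit)
      if (!any(ok)) next
      agree <- norm(sub$answer[ok]) == norm(ref$answer[hit[ok]])
      rows[[length(rows) + 1]] <-
        data.frame(expert = ex, group = g,
                   agreement = 100 * mean(agree), n_pairs = sum(ok),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no overlapping (abstract, question) pairs",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
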