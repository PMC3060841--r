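#' Labeled contingency table
#'
#' Builds the count matrix shared by the agreement, association and
#' subsumption statistics: rows index the first labeling (scheme A or
#' annotator 1), columns the second.
#'
#' @param a,b Equal-length character vectors of parallel labels.
#' @param row_levels,col_levels Optional label orders.
#' @return Integer matrix with dimnames.
#' @export
contingency_table <- function(a, b, row_levels = NULL, col_levels = NULL) {
  if (length(a) != length(b))
    stop("labelings must cover the same items", call. = FALSE)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (is.null(row_levels)) row_levels <- sort(unique(a))
  if (is.null(col_levels)) col_levels <- sort(unique(b))
  tab <- table(factor(a, levels = row_levels),
               factor(b, levels = col_levels))
  matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
}

#' @rdname contingency_table
#' @param corpus A [zone_corpus()] with parallel labels.
#' @param scheme_a,scheme_b Scheme ids; rows are `scheme_a` categories.
#' @export
scheme_table <- function(corpus, scheme_a, scheme_b) {
  df <- as.data.frame(corpus)
  contingency_table(df[[scheme_a]], df[[scheme_b]],
                    row_levels = zone_categories(scheme_a),
                    col_levels = zone_categories(scheme_b))
}

#' Cohen's kappa from a square contingency table
#'
#' Chance-corrected inter-annotator agreement: observed agreement `P_a`
#' (diagonal fraction) corrected for the chance agreement `P_e` implied by
#' the marginal products, `kappa = (P_a - P_e) / (1 - P_e)`.
#'
#' @param table Square count matrix (annotator 1 rows, annotator 2
#'   columns, identical category order).
#' @return Object of class `"zone_kappa"`: list with `P_a`, `P_e`,
#'   `kappa`, `n`.
#' @examples
#' cohen_kappa(matrix(c(45, 15, 5, 35), 2))$kappa  # 0.6
#' @export
cohen_kappa <- function(table) {
  if (nrow(table) != ncol(table))
    stop("kappa requires a square table", call. = FALSE)
  N <- sum(table)
  if (N <= 0) stop("empty table", call. = FALSE)
  P_a <- sum(diag(table)) / N
  P_e <- sum(rowSums(table) * colSums(table)) / N^2
  if (P_e >= 1)
    stop("chance agreement is 1; kappa undefined", call. = FALSE)
  structure(list(P_a = P_a, P_e = P_e, kappa = (P_a - P_e) / (1 - P_e),
                 n = N), class = "zone_kappa")
}

#' @export
print.zone_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.2f (P_a = %.3f, P_e = %.3f, n = %d)\n",
              x$kappa, x$P_a, x$P_e, x$n))
  invisible(x)
}

#' Mean pairwise kappa over several annotators
#'
#' @param annotations List of >= 2 equal-length label vectors covering the
#'   same items.
#' @param levels Optional category order (defaults to the union observed).
#' @return List with `mean` (unweighted mean kappa over all pairs) and
#'   `pairs` (data frame `a`, `b`, `kappa`).
#' @export
average_pairwise_kappa <- function(annotations, levels = NULL) {
  if (length(annotations) < 2)
    stop("need at least two annotators", call. = FALSE)
  lens <- lengths(annotations)
  if (length(unique(lens)) != 1)
    stop("labelings must cover the same items", call. = FALSE)
  if (is.null(levels)) levels <- sort(unique(unlist(annotations)))
  idx <- utils::combn(length(annotations), 2)
  pairs <- apply(idx, 2, function(ij) {
    tab <- contingency_table(annotations[[ij[1]]], annotations[[ij[2]]],
                             row_levels = levels, col_levels = levels)
    cohen_kappa(tab)$kappa
  })
  list(mean = mean(pairs),
       pairs = data.frame(a = idx[1, ], b = idx[2, ], kappa = pairs))
}

#' Chi-squared association statistics
#'
#' Pearson and likelihood-ratio chi-squared for a two-way table with
#' expected counts from the marginal products. Zero-observed cells
#' contribute 0 to the likelihood-ratio sum (limit convention); a
#' degenerate table (single row or column) has `df = 0` and statistics 0.
#'
#' @param table Count matrix.
#' @return List with `pearson`, `likelihood_ratio`, `df`.
#' @export
chi2_stats <- function(table) {
  N <- sum(table)
  if (N <= 0) stop("empty table", call. = FALSE)
  r <- nrow(table); c <- ncol(table)
  if (r < 2 || c < 2)
    return(list(pearson = 0, likelihood_ratio = 0, df = 0L))
  E <- outer(rowSums(table), colSums(table)) / N
  ok <- E > 0
  pearson <- sum((table[ok] - E[ok])^2 / E[ok])
  O <- table[ok]
  lr_terms <- ifelse(O > 0, O * log(O / E[ok]), 0)
  list(pearson = pearson, likelihood_ratio = 2 * sum(lr_terms),
       df = as.integer((r - 1) * (c - 1)))
}

#' Association coefficients from chi-squared
#'
#' Contingency coefficient `C = sqrt(chi2 / (chi2 + N))` and Cramer's
#' `V = sqrt(chi2 / (N (min(r, c) - 1)))`.
#'
#' @param chi2 Pearson chi-squared statistic (>= 0).
#' @param N Total count.
#' @param r,c Table dimensions (`min(r, c) >= 2` for V).
#' @return List with `contingency_coefficient`, `cramers_v`.
#' @export
assoc_coefficients <- function(chi2, N, r, c) {
  stopifnot(chi2 >= 0, N > 0)
  if (min(r, c) < 2)
    stop("Cramer's V needs at least a 2x2 table", call. = FALSE)
  list(contingency_coefficient = sqrt(chi2 / (chi2 + N)),
       cramers_v = sqrt(chi2 / (N * (min(r, c) - 1))))
}

#' Goodman-Kruskal lambda
#'
#' Proportional reduction in error when predicting one categorical
#' variable from the other: `lambda = (sum_k max_k - max_marginal) /
#' (N - max_marginal)`, 0 when the predicted marginal is concentrated in
#' one category.
#'
#' @param table Count matrix (rows = variable A, columns = variable B).
#' @param direction `"col_given_row"` predicts columns knowing rows;
#'   `"row_given_col"` the reverse.
#' @return Numeric lambda in \[0, 1\].
#' @examples
#' gk_lambda(matrix(c(30, 5, 10, 55), 2), "col_given_row")
#' @export
gk_lambda <- function(table, direction = c("col_given_row",
                                           "row_given_col")) {
  direction <- match.arg(direction)
  N <- sum(table)
  if (N <= 0) stop("empty table", call. = FALSE)
  if (direction == "row_given_col") table <- t(table)
  within_max <- sum(apply(table, 1, max))
  marg_max <- max(colSums(table))
  if (marg_max == N) return(0)
  (within_max - marg_max) / (N - marg_max)
}

#' Full pairwise association summary for two schemes
#'
#' @param table Count matrix (scheme A rows, scheme B columns).
#' @return Object of class `"zone_assoc"`: `chi2_pearson`,
#'   `chi2_likelihood_ratio`, `df`, `contingency_coefficient`,
#'   `cramers_v`, `lambda_col_given_row` (predict B knowing A),
#'   `lambda_row_given_col`, `n`.
#' @export
scheme_association <- function(table) {
  ch <- chi2_stats(table)
  co <- assoc_coefficients(ch$pearson, sum(table), nrow(table),
                           ncol(table))
  structure(list(chi2_pearson = ch$pearson,
                 chi2_likelihood_ratio = ch$likelihood_ratio, df = ch$df,
                 contingency_coefficient = co$contingency_coefficient,
                 cramers_v = co$cramers_v,
                 lambda_col_given_row = gk_lambda(table, "col_given_row"),
                 lambda_row_given_col = gk_lambda(table, "row_given_col"),
                 n = sum(table)), class = "zone_assoc")
}

#' @export
print.zone_assoc <- function(x, ...) {
  cat(sprintf("Pearson X2 = %.1f, LR X2 = %.1f, df = %d (n = %d)\n",
              x$chi2_pearson, x$chi2_likelihood_ratio, x$df, x$n))
  cat(sprintf("C = %.3f, Cramer's V = %.3f\n", x$contingency_coefficient,
              x$cramers_v))
  cat(sprintf("lambda(B|A) = %.3f, lambda(A|B) = %.3f\n",
              x$lambda_col_given_row, x$lambda_row_given_col))
  invisible(x)
}

#' Row- or column-normalized mapping proportions
#'
#' How each category of one scheme distributes over the categories of the
#' other, in percent. Empty rows (columns) are flagged with `NaN`.
#'
#' @param table Count matrix.
#' @param direction `"row"` normalizes each row to 100; `"col"` each
#'   column.
#' @return Numeric matrix of percentages.
#' @export
mapping_proportions <- function(table, direction = c("row", "col")) {
  direction <- match.arg(direction)
  if (sum(table) <= 0) stop("empty table", call. = FALSE)
  if (direction == "row") {
    sweep(table, 1, rowSums(table), "/") * 100
  } else {
    sweep(table, 2, colSums(table), "/") * 100
  }
}

#' Fault-tolerant subsumption check between categories
#'
#' Category `X` of the row scheme is subsumed by the target set `Ys` of
#' the column scheme when at most a tolerance fraction `T_k` of X's
#' instances carry a column label outside `Ys`: the statistic `T` is the
#' (optionally weighted) out-of-target fraction of X's row, and the
#' relation holds iff `T <= T_k`.
#'
#' @param table Count matrix (source scheme rows, target scheme columns).
#' @param X Source row label.
#' @param Ys Character vector of target column labels (union target).
#' @param t_k Fault-tolerance threshold (default 0.1: at most 10\% of
#'   instances may fall in other categories).
#' @param weights Optional non-negative per-column instance weights
#'   (named), generalizing the unit-weight default.
#' @return Object of class `"zone_subsume"`: list with `X`, `Ys`, `T`,
#'   `t_k`, `holds`.
#' @export
subsumption_check <- function(table, X, Ys, t_k = 0.1, weights = NULL) {
  if (!X %in% rownames(table)) stop("unknown source category ", X,
                                    call. = FALSE)
  if (!all(Ys %in% colnames(table)))
    stop("unknown target category ",
         paste(setdiff(Ys, colnames(table)), collapse = ", "),
         call. = FALSE)
  row <- table[X, ]
  if (!is.null(weights)) {
    w <- rep(1, length(row)); names(w) <- colnames(table)
    w[names(weights)] <- weights
    row <- row * w
  }
  tot <- sum(row)
  if (tot <= 0) stop("empty row for category ", X, call. = FALSE)
  T_stat <- 1 - sum(row[Ys]) / tot
  structure(list(X = X, Ys = Ys, T = T_stat, t_k = t_k,
                 holds = T_stat <= t_k), class = "zone_subsume")
}

#' @export
print.zone_subsume <- function(x, ...) {
  cat(sprintf("%s %s {%s}: T = %.3f %s T_k = %.2f\n", x$X,
              if (x$holds) "subsumed by" else "not subsumed by",
              paste(x$Ys, collapse = ", "), x$T,
              if (x$holds) "<=" else ">", x$t_k))
  invisible(x)
}

#' Subsumption relations between all scheme pairs of a corpus
#'
#' For every ordered pair of schemes (finer source, coarser target) and
#' every source category, finds the minimal union of target categories
#' subsuming it: targets are added greedily by descending mapping
#' proportion until the out-of-target fraction drops to `T_k` (or all
#' targets are used).
#'
#' @param corpus A [zone_corpus()] with every sentence labeled in all
#'   three schemes.
#' @param t_k Fault-tolerance threshold.
#' @param pairs List of `c(source, target)` scheme pairs; defaults to
#'   S3->S2, S3->S1 and S2->S1.
#' @return Data frame with columns `source_scheme`, `source`,
#'   `target_scheme`, `targets` (comma-joined, in greedy order), `T`,
#'   `holds`.
#' @export
subsumption_graph <- function(corpus, t_k = 0.1,
                              pairs = list(c("S3", "S2"), c("S3", "S1"),
                                           c("S2", "S1"))) {
  df <- as.data.frame(corpus)
  for (sch in unique(unlist(pairs)))
    if (anyNA(df[[sch]]))
      stop("corpus has sentences unlabeled under ", sch, call. = FALSE)
  rows <- list()
  for (pr in pairs) {
    tab <- scheme_table(corpus, pr[1], pr[2])
    for (X in rownames(tab)) {
      if (sum(tab[X, ]) == 0) next
      ord <- names(sort(tab[X, ], decreasing = TRUE))
      chosen <- character(); res <- NULL
      for (y in ord) {
        chosen <- c(chosen, y)
        res <- subsumption_check(tab, X, chosen, t_k)
        if (res$holds) break
      }
      rows[[length(rows) + 1]] <- data.frame(
        source_scheme = pr[1], source = X, target_scheme = pr[2],
        targets = paste(chosen, collapse = ","), T = res$T,
        holds = res$holds, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
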