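# Shared fixtures built in code.

fixture_path <- function() {
  system.file("extdata", "fixture_corpus.jsonl", package = "rhetzone")
}

# small labeled abstract from explicit sentences
make_abstract <- function(id, sents, S1 = NULL, S2 = NULL, S3 = NULL,
                          chemical = NULL) {
  text <- paste(sents, collapse = " ")
  ends <- cumsum(nchar(sents) + 1L) - 1L
  starts <- c(0L, utils::head(ends, -1) + 1L)
  sdf <- data.frame(start = starts, end = ends)
  if (!is.null(S1)) sdf$S1 <- S1
  if (!is.null(S2)) sdf$S2 <- S2
  if (!is.null(S3)) sdf$S3 <- S3
  zone_abstract(id, text, sdf, chemical = chemical)
}

# tiny separable training corpus: two S1 categories with disjoint cue words
make_toy_corpus <- function(n_abstracts = 6) {
  abstracts <- lapply(seq_len(n_abstracts), function(i) {
    make_abstract(sprintf("toy-%02d", i),
                  c("Mice were dosed with styrene daily.",
                    "Adduct levels increased significantly.",
                    "We conclude that styrene is genotoxic."),
                  S1 = c("METH", "RES", "CON"))
  })
  zone_corpus(abstracts)
}

# random small contingency table (possibly with empty margins avoided)
random_table <- function(nr, nc, max_count = 20) {
  m <- matrix(sample(0:max_count, nr * nc, replace = TRUE), nr, nc)
  # ensure positive total and no empty rows/cols for the statistics
  m[cbind(seq_len(nr), sample(nc, nr, replace = TRUE))] <-
    m[cbind(seq_len(nr), sample(nc, nr, replace = TRUE))] + 1
  dimnames(m) <- list(paste0("r", seq_len(nr)), paste0("c", seq_len(nc)))
  m
}

# independent brute-force statistics used as oracles
oracle_kappa <- function(m) {
  N <- sum(m)
  pa <- 0
  for (i in seq_len(nrow(m))) pa <- pa + m[i, i]
  pa <- pa / N
  pe <- 0
  for (i in seq_len(nrow(m))) pe <- pe + sum(m[i, ]) * sum(m[, i])
  pe <- pe / N^2
  (pa - pe) / (1 - pe)
}

oracle_pearson_chi2 <- function(m) {
  N <- sum(m)
  out <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- sum(m[i, ]) * sum(m[, j]) / N
    if (e > 0) out <- out + (m[i, j] - e)^2 / e
  }
  out
}

oracle_lr_chi2 <- function(m) {
  N <- sum(m)
  out <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- sum(m[i, ]) * sum(m[, j]) / N
    if (m[i, j] > 0 && e > 0) out <- out + m[i, j] * log(m[i, j] / e)
  }
  2 * out
}

oracle_lambda_col_given_row <- function(m) {
  N <- sum(m)
  within <- 0
  for (i in seq_len(nrow(m))) within <- within + max(m[i, ])
  marg <- max(colSums(m))
  if (marg == N) return(0)
  (within - marg) / (N - marg)
}

# exact Mann-Whitney p by enumeration, written independently of the package
oracle_mw_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pool <- c(a, b)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_of(a, b)
  ctr <- n * m / 2
  picks <- utils::combn(n + m, n)
  hits <- 0
  for (k in seq_len(ncol(picks))) {
    u <- u_of(pool[picks[, k]], pool[-picks[, k]])
    if (abs(u - ctr) >= abs(obs - ctr) - 1e-12) hits <- hits + 1
  }
  hits / ncol(picks)
}
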