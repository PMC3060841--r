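test_that("kappa matches hand formulas and reference tables", {
  k <- cohen_kappa(matrix(c(45, 15, 5, 35), 2))
  expect_equal(k$P_a, 0.80)
  expect_equal(k$P_e, 0.50)
  expect_equal(k$kappa, 0.60)
  # diagonal table: perfect agreement
  expect_equal(cohen_kappa(diag(c(3, 7, 9)))$kappa, 1)
  # published 4x4 annotator table: formula on the printed counts
  expect_equal(round(cohen_kappa(cra_agreement_tables$S1)$kappa, 2), 0.82)
  expect_equal(sum(cra_agreement_tables$S1), 2740)
  expect_error(cohen_kappa(matrix(1:6, 2)), "square")
})

test_that("kappa agrees with a brute-force oracle on random tables", {
  set.seed(23)
  for (rep in 1:250) {
    d <- sample(2:5, 1)
    m <- random_table(d, d)
    if (sum(rowSums(m) * colSums(m)) / sum(m)^2 >= 1) next
    expect_equal(cohen_kappa(m)$kappa, oracle_kappa(m),
                 tolerance = 1e-9)
  }
})

test_that("kappa is invariant under simultaneous permutation", {
  set.seed(29)
  m <- random_table(4, 4)
  perm <- sample(4)
  expect_equal(cohen_kappa(m[perm, perm])$kappa, cohen_kappa(m)$kappa,
               tolerance = 1e-12)
})

test_that("average pairwise kappa reduces to the pair statistic", {
  x <- rep(c("A", "B"), c(6, 4))
  expect_equal(average_pairwise_kappa(list(x, x, x))$mean, 1)
  # two labelings realizing the [[45,5],[15,35]] table
  a1 <- rep(c("A", "B"), c(50, 50))
  a2 <- c(rep("A", 45), rep("B", 5), rep("A", 15), rep("B", 35))
  expect_equal(average_pairwise_kappa(list(a1, a2))$mean, 0.6)
  # three labelings with pair kappas 1.0, 0.6, 0.6
  res <- average_pairwise_kappa(list(a1, a1, a2))
  expect_equal(res$mean, (1 + 0.6 + 0.6) / 3, tolerance = 1e-12)
  expect_error(average_pairwise_kappa(list(a1)), "two annotators")
  expect_error(average_pairwise_kappa(list(a1, a2[-1])), "same items")
})

test_that("chi-squared statistics match hand and library values", {
  m <- matrix(c(10, 0, 0, 10), 2)
  ch <- chi2_stats(m)
  expect_equal(ch$pearson, 20)
  expect_equal(ch$df, 1L)
  expect_equal(ch$likelihood_ratio, 2 * 20 * log(2), tolerance = 1e-12)
  # independence: identical row distributions
  ind <- matrix(c(6, 12, 4, 8, 10, 20), 2)
  expect_equal(chi2_stats(ind)$pearson, 0, tolerance = 1e-12)
  expect_equal(chi2_stats(ind)$likelihood_ratio, 0, tolerance = 1e-12)
  # degenerate single-column table
  expect_equal(chi2_stats(matrix(c(3, 4), 2, 1))$df, 0L)
  # library cross-check on random 5x7 tables
  set.seed(31)
  for (rep in 1:30) {
    m <- random_table(5, 7)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(chi2_stats(m)$pearson, unname(ref$statistic),
                 tolerance = 1e-9)
    expect_equal(chi2_stats(m)$likelihood_ratio, oracle_lr_chi2(m),
                 tolerance = 1e-9)
  }
})

test_that("association coefficients follow their closed forms", {
  co <- assoc_coefficients(20, 20, 2, 2)
  expect_equal(co$contingency_coefficient, sqrt(0.5))
  expect_equal(co$cramers_v, 1)
  z <- assoc_coefficients(0, 50, 3, 4)
  expect_equal(z$contingency_coefficient, 0)
  expect_equal(z$cramers_v, 0)
  expect_error(assoc_coefficients(5, 10, 1, 4), "2x2")
})

test_that("lambda matches the hand example and brute force", {
  m <- matrix(c(30, 5, 10, 55), 2)
  expect_equal(gk_lambda(m, "col_given_row"), (85 - 65) / (100 - 65))
  ident <- matrix(c(10, 20, 5, 10), 2)  # proportional rows
  expect_equal(gk_lambda(ident, "col_given_row"), 0)
  set.seed(37)
  for (rep in 1:250) {
    m <- random_table(sample(2:5, 1), sample(2:5, 1))
    expect_equal(gk_lambda(m, "col_given_row"),
                 oracle_lambda_col_given_row(m), tolerance = 1e-9)
    expect_equal(gk_lambda(m, "row_given_col"),
                 oracle_lambda_col_given_row(t(m)), tolerance = 1e-9)
  }
})

test_that("mapping proportions normalize rows to 100", {
  m <- matrix(c(96, 0, 4, 50), 2,
              dimnames = list(c("X", "Y"), c("P", "Q")))
  mp <- mapping_proportions(m)
  expect_equal(unname(mp["X", ]), c(96, 4))
  expect_equal(rowSums(mp), c(X = 100, Y = 100))
  onehot <- matrix(c(5, 0, 0, 3), 2)
  expect_equal(max(mapping_proportions(onehot)), 100)
})

test_that("subsumption is the out-of-target fraction against T_k", {
  m <- matrix(c(96, 10, 4, 90), 2,
              dimnames = list(c("X", "Z"), c("Y", "W")))
  r <- subsumption_check(m, "X", "Y")
  expect_equal(r$T, 0.04)
  expect_true(r$holds)
  all_in <- subsumption_check(matrix(c(50, 0, 0, 10), 2,
                                     dimnames = list(c("X", "Z"),
                                                     c("Y", "W"))),
                              "X", "Y")
  expect_equal(all_in$T, 0)
  m2 <- matrix(c(85, 0, 15, 10), 2,
               dimnames = list(c("X", "Z"), c("Y", "W")))
  r2 <- subsumption_check(m2, "X", "Y")
  expect_equal(r2$T, 0.15)
  expect_false(r2$holds)
  expect_error(subsumption_check(m, "nope", "Y"), "unknown source")
})

test_that("the subsumption statistic decreases as targets grow", {
  set.seed(43)
  for (rep in 1:30) {
    m <- random_table(3, 5)
    X <- rownames(m)[1]
    ord <- sample(colnames(m))
    ts <- vapply(seq_along(ord), function(k)
      subsumption_check(m, X, ord[seq_len(k)])$T, 0)
    expect_true(all(diff(ts) <= 1e-12))
    expect_equal(ts[length(ts)], 0)
  }
})

test_that("identical labelings give two-way subsumption", {
  m <- diag(c(12, 30, 8))
  dimnames(m) <- list(c("A", "B", "C"), c("A", "B", "C"))
  for (cat in rownames(m)) {
    expect_true(subsumption_check(m, cat, cat)$holds)
    expect_true(subsumption_check(t(m), cat, cat)$holds)
  }
})

test_that("the subsumption graph recovers the generator mapping", {
  corp <- generate_corpus(generator_config(n_abstracts = 200, seed = 51))
  g <- subsumption_graph(corp)
  map <- default_mapping()
  for (cat in zone_categories("S3")) {
    hit <- g[g$source_scheme == "S3" & g$target_scheme == "S2" &
               g$source == cat, ]
    expect_equal(hit$targets, unname(map$S3_S2[cat]))
    expect_true(hit$holds)
  }
  # independent random labels admit no single-target subsumption
  set.seed(52)
  n <- 4000
  tab <- contingency_table(sample(zone_categories("S3"), n, TRUE),
                           sample(zone_categories("S2"), n, TRUE))
  single <- vapply(rownames(tab), function(X)
    any(vapply(colnames(tab), function(Y)
      subsumption_check(tab, X, Y)$holds, TRUE)), TRUE)
  expect_false(any(single))
})

test_that("scheme association is asymmetric in predictive direction", {
  corp <- generate_corpus(generator_config(n_abstracts = 150, seed = 53))
  t13 <- scheme_table(corp, "S1", "S3")
  # the fine scheme predicts the coarse one better than the reverse
  expect_lt(gk_lambda(t13, "col_given_row"),
            gk_lambda(t13, "row_given_col"))
  a <- scheme_association(scheme_table(corp, "S1", "S2"))
  expect_true(a$cramers_v > 0.8)            # deterministic image
  expect_true(a$contingency_coefficient < 1)
  expect_equal(a$df, (4 - 1) * (7 - 1))
})
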