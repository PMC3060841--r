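#' Reference category distribution of the original annotated corpus
#'
#' Per-category word and sentence counts reported for the original
#' 1000-abstract, 7,985-sentence cancer-risk-assessment corpus under each
#' scheme. The corpus itself was never distributed; these published counts
#' serve as inputs, e.g. as the target marginals of the synthetic
#' generator and as the label distribution behind the sampling baseline.
#'
#' @format Named list (`S1`, `S2`, `S3`) of data frames with columns
#'   `category`, `words`, `sentences`.
#' @export
cra_sentence_counts <- list(
  S1 = data.frame(
    category = c("OBJ", "METH", "RES", "CON"),
    words = c(61483, 39163, 89575, 35564),
    sentences = c(2145, 1396, 3203, 1241),
    stringsAsFactors = FALSE),
  S2 = data.frame(
    category = c("BKG", "OBJ", "METH", "RES", "CON", "REL", "FUT"),
    words = c(36828, 23493, 41544, 89538, 30752, 2456, 1174),
    sentences = c(1429, 674, 1473, 3185, 1082, 95, 47),
    stringsAsFactors = FALSE),
  S3 = data.frame(
    category = c("HYP", "MOT", "BKG", "GOAL", "OBJT", "EXP", "MOD",
                 "METH", "OBS", "RES", "CON"),
    words = c(2676, 4277, 28028, 10612, 15894, 22444, 1157, 17982,
              17402, 75951, 29362),
    sentences = c(99, 172, 1088, 294, 474, 805, 41, 637, 744, 2582,
                  1049),
    stringsAsFactors = FALSE))

.agree_matrix <- function(counts, cats) {
  matrix(counts, length(cats), length(cats), byrow = TRUE,
         dimnames = list(linguist = cats, expert = cats))
}

#' Reference inter-annotator confusion matrices
#'
#' Published confusion matrices between the linguist (rows) and the
#' domain expert (columns) on the 300-abstract agreement subset of the
#' original corpus, one per scheme. Input data for the agreement
#' statistics, e.g. `cohen_kappa(cra_agreement_tables$S3)`.
#'
#' @format Named list (`S1`, `S2`, `S3`) of square integer matrices.
#' @export
cra_agreement_tables <- list(
  S1 = .agree_matrix(c(
    632, 29, 9, 4,
    88, 429, 19, 1,
    5, 17, 913, 18,
    11, 4, 158, 403), c("OBJ", "METH", "RES", "CON")),
  S2 = .agree_matrix(c(
    438, 0, 2, 1, 3, 2, 0,
    22, 211, 53, 7, 2, 0, 0,
    5, 17, 431, 16, 0, 1, 0,
    9, 4, 18, 935, 17, 2, 0,
    7, 1, 5, 131, 337, 4, 7,
    2, 0, 0, 11, 13, 24, 0,
    0, 0, 0, 0, 2, 0, 9),
    c("BKG", "OBJ", "METH", "RES", "CON", "REL", "FUT")),
  S3 = .agree_matrix(c(
    16, 0, 12, 1, 0, 0, 0, 0, 0, 0, 5,
    5, 48, 13, 0, 2, 0, 0, 4, 0, 1, 0,
    11, 6, 316, 0, 3, 0, 0, 4, 1, 1, 2,
    2, 4, 4, 87, 80, 7, 0, 10, 0, 0, 0,
    0, 0, 0, 2, 39, 3, 0, 9, 0, 0, 0,
    0, 0, 1, 1, 7, 190, 0, 66, 5, 8, 0,
    0, 0, 3, 1, 4, 7, 5, 13, 0, 2, 1,
    0, 0, 8, 7, 25, 63, 5, 92, 3, 10, 1,
    0, 0, 4, 0, 1, 3, 0, 9, 183, 285, 1,
    0, 0, 3, 0, 0, 2, 3, 8, 53, 466, 10,
    0, 1, 5, 1, 1, 0, 1, 3, 9, 105, 337),
    c("HYP", "MOT", "BKG", "GOAL", "OBJT", "EXP", "MOD", "METH",
      "OBS", "RES", "CON")))

#' Reference mean reading times of the expert user test
#'
#' Published per-question and total mean answering times (seconds) of the
#' three cancer-risk-assessment experts (A, B, C) for each annotation
#' condition: S0 (unannotated), S1/S3 (manually annotated) and S1'/S3'
#' (automatically annotated). Input data for [percent_saving()].
#'
#' @format Data frame with columns `group`, `expert`, `Q1`..`Q5`,
#'   `TOTAL`.
#' @export
cra_user_times <- local({
  rows <- rbind(
    c("S0", "A", 15.3, 9.4, 8.7, 4.4, 8.9, 9.4, 13.3, 69.5),
    c("S0", "B", 27.1, 18.8, 15.5, 8.5, 14.8, 13.5, 18.0, 116.1),
    c("S0", "C", 19.3, 12.0, 17.9, 4.9, 9.6, 18.4, 20.9, 102.9),
    c("S1", "A", 15.3, 7.4, 6.2, 4.2, 5.8, 7.4, 11.9, 58.2),
    c("S1", "B", 17.0, 7.9, 8.5, 4.8, 6.8, 9.9, 13.1, 67.9),
    c("S1", "C", 15.8, 6.4, 8.8, 3.8, 5.8, 12.5, 12.5, 65.6),
    c("S3", "A", 13.1, 7.9, 5.6, 3.9, 5.7, 6.4, 11.9, 54.5),
    c("S3", "B", 15.9, 8.9, 7.2, 4.7, 7.8, 6.1, 12.0, 62.6),
    c("S3", "C", 15.4, 5.9, 8.5, 3.8, 6.9, 11.8, 11.4, 63.7),
    c("S1'", "A", 15.0, 9.4, 6.3, 4.2, 7.1, 7.4, 12.5, 61.8),
    c("S1'", "B", 18.4, 12.4, 9.4, 8.1, 8.2, 6.7, 14.2, 77.5),
    c("S1'", "C", 18.5, 12.3, 13.9, 6.3, 8.6, 12.8, 12.9, 85.3),
    c("S3'", "A", 13.0, 8.3, 6.6, 4.9, 6.5, 6.8, 11.5, 57.6),
    c("S3'", "B", 23.9, 14.5, 11.4, 7.8, 10.1, 7.2, 15.3, 90.2),
    c("S3'", "C", 17.1, 12.0, 15.1, 4.8, 8.3, 11.9, 15.8, 84.9))
  df <- data.frame(group = rows[, 1], expert = rows[, 2],
                   stringsAsFactors = FALSE)
  qs <- c("Q1", "Q2", "Q3a", "Q3b", "Q3c", "Q4", "Q5", "TOTAL")
  for (j in seq_along(qs)) df[[qs[j]]] <- as.numeric(rows[, j + 2])
  df
})
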