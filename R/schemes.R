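#' Annotation scheme registry
#'
#' Three sentence-level information-structure schemes of increasing
#' granularity are supported:
#' \describe{
#'   \item{S1}{Section names: the 4-way division of structured abstracts
#'     into Objective, Method, Result and Conclusion.}
#'   \item{S2}{Argumentative zoning: 7 categories tracking the rhetorical
#'     progression of the scientific argument.}
#'   \item{S3}{Core scientific concepts: 11 concept-driven categories
#'     viewing a paper as the record of a scientific investigation.}
#' }
#'
#' @param id Scheme identifier, one of `"S1"`, `"S2"`, `"S3"`.
#' @return For `zone_scheme()`, an object of class `"zone_scheme"`: a list
#'   with elements `id` and `categories` (a data frame with columns
#'   `abbrev`, `name`, `description`). For `zone_categories()`, the
#'   character vector of category abbreviations in canonical order.
#' @examples
#' zone_scheme("S1")
#' zone_categories("S3")
#' @export
zone_scheme <- function(id) {
  id <- match.arg(id, c("S1", "S2", "S3"))
  structure(list(id = id, categories = .scheme_tables[[id]]),
            class = "zone_scheme")
}

#' @rdname zone_scheme
#' @export
zone_categories <- function(id) {
  zone_scheme(id)$categories$abbrev
}

#' @export
print.zone_scheme <- function(x, ...) {
  cat(sprintf("Annotation scheme %s (%d categories)\n",
              x$id, nrow(x$categories)))
  cat(paste0("  ", format(x$categories$abbrev, width = 5),
             x$categories$name, collapse = "\n"), "\n")
  invisible(x)
}

.cat_df <- function(abbrev, name, description) {
  data.frame(abbrev = abbrev, name = name, description = description,
             stringsAsFactors = FALSE)
}

.scheme_tables <- list(
  S1 = .cat_df(
    c("OBJ", "METH", "RES", "CON"),
    c("Objective", "Method", "Result", "Conclusion"),
    c("The background and the aim of the research",
      "The way to achieve the goal",
      "The principle findings",
      "Analysis, discussion and the main conclusions")),
  S2 = .cat_df(
    c("BKG", "OBJ", "METH", "RES", "CON", "REL", "FUT"),
    c("Background", "Objective", "Method", "Result", "Conclusion",
      "Related work", "Future work"),
    c("Circumstances pertaining to the current work",
      "A thing aimed at or sought, a target or goal",
      "A way of doing research according to a defined plan",
      "The effect, consequence or outcome of an experiment",
      "A judgment or statement arrived at by reasoning",
      "A comparison between the current work and related work",
      "Work that needs to be done in the future")),
  S3 = .cat_df(
    c("HYP", "MOT", "BKG", "GOAL", "OBJT", "EXP", "MOD", "METH",
      "OBS", "RES", "CON"),
    c("Hypothesis", "Motivation", "Background", "Goal", "Object",
      "Experiment", "Model", "Method", "Observation", "Result",
      "Conclusion"),
    c("A statement not yet confirmed rather than a factual statement",
      "The reason for carrying out the investigation",
      "Generally accepted background knowledge and previous work",
      "The target state of the investigation",
      "An entity which is a product or main theme of the investigation",
      "Experiment details",
      "A statement about a theoretical model or framework",
      "The means by which the authors seek to achieve a goal",
      "The data/phenomena recorded within an investigation",
      "Factual statements about the outputs of an investigation",
      "Statements inferred from observations and results"))
)

.check_scheme_label <- function(label, scheme_id) {
  if (!label %in% .scheme_tables[[scheme_id]]$abbrev)
    stop(sprintf("'%s' is not a category of scheme %s", label, scheme_id),
         call. = FALSE)
  label
}

# question -> category mapping used by the expert reading test; one row per
# (question, scheme), dominant = categories highlighted in the test.
.question_map <- list(
  S1 = list(
    Q1  = list(dominant = "OBJ",           possible = "OBJ"),
    Q2  = list(dominant = "METH",          possible = c("METH", "RES")),
    Q3a = list(dominant = "METH",          possible = c("METH", "RES")),
    Q3b = list(dominant = "METH",          possible = c("METH", "RES")),
    Q3c = list(dominant = "RES",           possible = c("METH", "RES")),
    Q4  = list(dominant = "RES",           possible = c("RES", "CON")),
    Q5  = list(dominant = "CON",           possible = "CON")),
  S3 = list(
    Q1  = list(dominant = c("GOAL", "OBJT"), literal = c("GOAL", "OBJ"),
               possible = c("GOAL", "OBJT")),
    Q2  = list(dominant = c("METH", "EXP"),
               possible = c("METH", "EXP", "MOD", "OBS", "RES")),
    Q3a = list(dominant = "EXP",
               possible = c("METH", "EXP", "MOD", "OBS", "RES")),
    Q3b = list(dominant = "EXP",
               possible = c("METH", "EXP", "MOD", "OBS", "RES")),
    Q3c = list(dominant = "OBS",
               possible = c("METH", "EXP", "MOD", "OBS", "RES")),
    Q4  = list(dominant = "OBS",           possible = c("OBS", "RES", "CON")),
    Q5  = list(dominant = "CON",           possible = "CON"))
)

#' Dominant scheme categories per reading-test question
#'
#' The expert reading test asks seven questions about each abstract (aim of
#' the study, study type, exposure length, group size, endpoints, positive
#' results, author conclusions). For each question 1-2 dominant categories
#' of the coarse (S1) or fine-grained (S3) scheme nearly always contain the
#' answer; these are the categories highlighted during the test.
#'
#' The published mapping lists one dominant S3 entry for Q1 using an
#' abbreviation that does not belong to S3 ("OBJ"); the registry corrects it
#' to `OBJT` (consistent with the possible-category column). Set
#' `literal = TRUE` to obtain the uncorrected value.
#'
#' @param question One of `"Q1"`, `"Q2"`, `"Q3a"`, `"Q3b"`, `"Q3c"`,
#'   `"Q4"`, `"Q5"`.
#' @param scheme `"S1"` or `"S3"` (the two schemes used in the test).
#' @param literal Return the mapping exactly as published, including the
#'   Q1/S3 typo.
#' @return Character vector of category abbreviations.
#' @examples
#' dominant_categories("Q5", "S1")
#' dominant_categories("Q2", "S3")
#' @export
dominant_categories <- function(question, scheme, literal = FALSE) {
  scheme <- match.arg(scheme, c("S1", "S3"))
  if (!question %in% names(.question_map[[scheme]]))
    stop(sprintf("unknown question id '%s'", question), call. = FALSE)
  entry <- .question_map[[scheme]][[question]]
  if (literal && !is.null(entry$literal)) entry$literal else entry$dominant
}

#' @rdname dominant_categories
#' @export
possible_categories <- function(question, scheme) {
  scheme <- match.arg(scheme, c("S1", "S3"))
  if (!question %in% names(.question_map[[scheme]]))
    stop(sprintf("unknown question id '%s'", question), call. = FALSE)
  .question_map[[scheme]][[question]]$possible
}
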