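#' Read a hazard occurrence table
#'
#' Reads concentration measurements for hazard--food pairs from a delimited
#' text file (CSV or TSV, header row required). Each row is one analytical
#' result: an exact value above the limit of quantification (LOQ), an
#' interval-censored result between the limit of detection (LOD) and the LOQ,
#' or a non-detect below the LOD. The censoring state is carried in a
#' dedicated `censor` column (`"exact"`, `"interval"`, `"nd"`) rather than by
#' sentinel values, so a reported value can never be confused with a limit.
#'
#' @param path Path to a CSV/TSV file with columns `hazard`, `food`, `value`,
#'   `censor`, `lod`, `loq`, `unit`. `value` must be blank unless
#'   `censor == "exact"`.
#' @return A tibble with one validated row per measurement; columns as above
#'   with `censor` a factor with levels `exact`, `interval`, `nd`.
#' @details Estimating a concentration distribution requires at least some
#'   exact values above LOQ, so a hazard--food pair with no exact record is a
#'   hard error, as is an "exact" value lying inside its own censoring
#'   interval. Units are passed through untouched; all downstream results
#'   inherit the units of the input data.
#' @seealso [read_consumption()], [model_spec()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(
#'   hazard = "cd", food = "cereal", value = c(5, NA, NA),
#'   censor = c("exact", "interval", "nd"), lod = 0.5, loq = 1, unit = "mg/kg"
#' ), path)
#' read_occurrence(path)
read_occurrence <- function(path) {
  tbl <- read_table_auto(path)
  need <- c("hazard", "food", "value", "censor", "lod", "loq", "unit")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    stop("occurrence file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- dplyr::mutate(
    tbl,
    hazard = as.character(.data$hazard),
    food = as.character(.data$food),
    value = as.numeric(.data$value),
    censor = tolower(as.character(.data$censor)),
    lod = as.numeric(.data$lod),
    loq = as.numeric(.data$loq),
    unit = as.character(.data$unit)
  )
  validate_occurrence(tbl)
}

#' Validate an occurrence table
#'
#' Checks the row-level invariants of an occurrence table (censoring states,
#' LOD/LOQ ordering, exact values above LOQ, an exact record per pair) and
#' returns the table with `censor` as a factor. Called by [read_occurrence()]
#' and by the synthetic data generator; call it directly on a tibble built in
#' code.
#'
#' @param tbl A data frame with the columns documented in [read_occurrence()].
#' @return The validated tibble.
#' @export
validate_occurrence <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  ok_censor <- tbl$censor %in% c("exact", "interval", "nd")
  if (!all(ok_censor)) {
    stop("unknown censor code(s): ",
         paste(unique(tbl$censor[!ok_censor]), collapse = ", "), call. = FALSE)
  }
  if (any(tbl$lod < 0, na.rm = TRUE)) stop("negative LOD", call. = FALSE)
  if (any(tbl$lod > tbl$loq, na.rm = TRUE)) {
    stop("LOD exceeds LOQ in ", sum(tbl$lod > tbl$loq, na.rm = TRUE),
         " row(s); limits must satisfy LOD <= LOQ", call. = FALSE)
  }
  exact <- tbl$censor == "exact"
  if (any(is.na(tbl$value[exact]))) {
    stop("exact rows must carry a value", call. = FALSE)
  }
  if (any(!is.na(tbl$value[!exact]))) {
    stop("censored rows must have a blank value; censoring is encoded in the ",
         "'censor' column", call. = FALSE)
  }
  bad_exact <- exact & tbl$value <= tbl$loq
  if (any(bad_exact)) {
    stop("row(s) recorded as exact but value lies at or below LOQ: ",
         "an exact measurement must exceed its LOQ (use censor = 'interval' ",
         "or 'nd')", call. = FALSE)
  }
  if (any(tbl$censor == "interval" & tbl$lod >= tbl$loq)) {
    stop("interval-censored rows require LOD < LOQ", call. = FALSE)
  }
  n_exact <- tapply(exact, paste(tbl$hazard, tbl$food, sep = "\r"), sum)
  if (any(n_exact == 0)) {
    stop("no exact values above LOQ for pair(s): ",
         paste(gsub("\r", " / ", names(n_exact)[n_exact == 0]), collapse = "; "),
         ". The concentration distribution is not estimable without at least ",
         "some exact measurements.", call. = FALSE)
  }
  tbl$censor <- factor(tbl$censor, levels = c("exact", "interval", "nd"))
  tbl
}

#' Read a prevalence sample table
#'
#' Reads binomial prevalence samples (number of contaminated units `positive`
#' out of `total` tested) per hazard--food pair. Required when the occurrence
#' model estimates prevalence separately from the concentration distribution.
#'
#' @param path CSV/TSV file with columns `hazard`, `food`, `positive`, `total`.
#' @return A validated tibble.
#' @export
read_prevalence <- function(path) {
  tbl <- read_table_auto(path)
  need <- c("hazard", "food", "positive", "total")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols)) {
    stop("prevalence file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- dplyr::mutate(tbl,
    hazard = as.character(.data$hazard), food = as.character(.data$food),
    positive = as.integer(.data$positive), total = as.integer(.data$total))
  if (any(tbl$positive < 0 | tbl$positive > tbl$total)) {
    stop("prevalence counts must satisfy 0 <= positive <= total", call. = FALSE)
  }
  tbl
}

#' Read consumption diary and body weight tables
#'
#' The diary is wide: one row per respondent-day, a `respondent` column, a
#' `day` column (integer day index, unique within respondent) and one column
#' per food holding the raw consumed amount (0 = not consumed that day).
#' Amounts are read raw -- in the units of the survey, typically grams -- and
#' divided by body weight internally where the model needs per-body-weight
#' quantities, so users never pre-scale their data.
#'
#' @param path_diary CSV/TSV diary file as described.
#' @param path_weights CSV/TSV file with columns `respondent`, `weight`
#'   (body weight in kg, > 0).
#' @return A list with elements `diary` (tibble), `weights` (tibble) and
#'   `foods` (character vector fixing the food ordering used everywhere
#'   downstream).
#' @details Every diary respondent must have a body weight. Respondents with
#'   fewer than two diary days are retained (they still inform amounts and
#'   independent-day frequencies) but are reported in a message since they
#'   carry no day-to-day information. A food with no positive amount anywhere
#'   triggers a warning: its consumption frequency is estimable but its
#'   amount distribution is not.
#' @export
read_consumption <- function(path_diary, path_weights) {
  diary <- read_table_auto(path_diary)
  weights <- read_table_auto(path_weights)
  if (!all(c("respondent", "day") %in% names(diary))) {
    stop("diary needs 'respondent' and 'day' columns", call. = FALSE)
  }
  if (!all(c("respondent", "weight") %in% names(weights))) {
    stop("weights file needs 'respondent' and 'weight' columns", call. = FALSE)
  }
  diary$respondent <- as.character(diary$respondent)
  weights$respondent <- as.character(weights$respondent)
  validate_consumption(diary, weights)
}

#' Validate diary and body-weight tables built in code
#'
#' @param diary,weights Data frames in the layout of [read_consumption()].
#' @return As [read_consumption()].
#' @export
validate_consumption <- function(diary, weights) {
  diary <- tibble::as_tibble(diary)
  weights <- tibble::as_tibble(weights)
  foods <- setdiff(names(diary), c("respondent", "day"))
  if (!length(foods)) stop("diary contains no food columns", call. = FALSE)
  amounts <- as.matrix(diary[foods])
  if (any(is.na(amounts))) stop("diary amounts must not be missing; use 0 for a non-consumption day", call. = FALSE)
  if (any(amounts < 0)) stop("negative consumption amount", call. = FALSE)
  if (anyDuplicated(diary[c("respondent", "day")])) {
    stop("duplicated respondent-day in diary", call. = FALSE)
  }
  missing_w <- setdiff(unique(diary$respondent), weights$respondent)
  if (length(missing_w)) {
    stop("respondent(s) missing a body weight: ",
         paste(utils::head(missing_w, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(weights$weight <= 0 | is.na(weights$weight))) {
    stop("body weights must be positive", call. = FALSE)
  }
  n_days <- table(diary$respondent)
  if (any(n_days < 2L)) {
    message(sum(n_days < 2L), " respondent(s) have a single diary day; they ",
            "inform amounts but carry no day-to-day information")
  }
  n_pos <- colSums(amounts > 0)
  if (any(n_pos == 0L)) {
    warning("food(s) never consumed in the diary: ",
            paste(foods[n_pos == 0L], collapse = ", "),
            " -- frequency is estimable but the amount distribution is not",
            call. = FALSE)
  }
  list(diary = diary, weights = weights, foods = foods)
}

#' Bundle validated exposure-model inputs
#'
#' Convenience constructor collecting the occurrence, prevalence, diary and
#' body-weight tables into one object that [model_spec()] and
#' [sample_posterior()] consume. Any component may be `NULL`; the model built
#' later contains exactly the likelihood components for which data exist.
#'
#' @param occurrence Occurrence tibble ([read_occurrence()]) or `NULL`.
#' @param prevalence Prevalence tibble ([read_prevalence()]) or `NULL`.
#' @param diary,weights Consumption tables ([read_consumption()]) or `NULL`.
#' @return An object of class `bde_data`.
#' @export
bde_data <- function(occurrence = NULL, prevalence = NULL,
                     diary = NULL, weights = NULL) {
  foods <- NULL
  if (!is.null(diary)) {
    cons <- validate_consumption(diary, weights)
    diary <- cons$diary
    weights <- cons$weights
    foods <- cons$foods
  }
  if (!is.null(occurrence)) occurrence <- validate_occurrence(occurrence)
  structure(
    list(occurrence = occurrence, prevalence = prevalence,
         diary = diary, weights = weights, foods = foods),
    class = "bde_data"
  )
}

#' @export
print.bde_data <- function(x, ...) {
  cat("<bde_data>\n")
  if (!is.null(x$occurrence)) {
    cat("  occurrence:", nrow(x$occurrence), "records,",
        length(unique(paste(x$occurrence$hazard, x$occurrence$food))), "hazard-food pair(s)\n")
  }
  if (!is.null(x$prevalence)) cat("  prevalence:", nrow(x$prevalence), "sample(s)\n")
  if (!is.null(x$diary)) {
    cat("  diary:", nrow(x$diary), "respondent-days,",
        length(unique(x$diary$respondent)), "respondents,",
        length(x$foods), "food(s)\n")
  }
  invisible(x)
}

#' Write the input tables of a data bundle to a directory
#'
#' Writes `occurrence.csv`, `prevalence.csv`, `diary.csv`, `weights.csv`
#' (whichever components exist) in the dialect the `read_*` functions accept,
#' so that write-then-read is the identity on valid data.
#'
#' @param data A `bde_data` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bde_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(data$occurrence)) {
    out <- data$occurrence
    out$censor <- as.character(out$censor)
    readr::write_csv(out, file.path(dir, "occurrence.csv"))
  }
  if (!is.null(data$prevalence)) {
    readr::write_csv(data$prevalence, file.path(dir, "prevalence.csv"))
  }
  if (!is.null(data$diary)) {
    readr::write_csv(data$diary, file.path(dir, "diary.csv"))
    readr::write_csv(data$weights, file.path(dir, "weights.csv"))
  }
  invisible(dir)
}

# Delimiter sniffing: CSV unless the header contains a tab.
read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}
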