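#' Canonical nutrient names
#'
#' The nutrients tracked throughout the pipeline, in canonical order. All
#' amounts are expressed per 100 basis units (100 g or 100 mL) in food
#' composition tables: energy in kcal, sodium in mg, everything else in grams.
#'
#' @return Character vector of canonical nutrient names.
#' @export
fop_nutrients <- function() {
  c("energy", "saturated_fat", "trans_fat", "total_fat",
    "total_sugar", "added_sugar", "sodium", "fiber")
}

#' Nutrients reported in intake summaries
#'
#' The subset of nutrients summarized at the population level (daily intake
#' tables and percent-change figures).
#'
#' @return Character vector.
#' @export
fop_intake_nutrients <- function() {
  c("energy", "saturated_fat", "trans_fat", "total_sugar", "sodium", "fiber")
}

#' Default column mapping for food composition CSV files
#'
#' Maps on-disk column names to the canonical internal names. Pass a modified
#' copy to [load_food_db()] when your file uses different headers.
#'
#' @return Named character vector: names are file columns, values canonical.
#' @export
fop_food_db_columns <- function() {
  c(food_id = "food_id", name = "name", category = "category",
    processed = "processed", basis = "basis", serving_size = "serving_size",
    energy_kcal = "energy", satfat_g = "saturated_fat",
    transfat_g = "trans_fat", totalfat_g = "total_fat",
    sugar_total_g = "total_sugar", sugar_added_g = "added_sugar",
    sodium_mg = "sodium", fiber_g = "fiber")
}

valid_basis <- c("per_100_g", "per_100_mL")

#' Validate a food composition table
#'
#' Checks the structural invariants of a food database: unique ids, known
#' basis tokens, non-negative nutrient values, added sugar not exceeding total
#' sugar, saturated + trans fat not exceeding total fat (where total fat is
#' recorded), and a non-empty category for every processed food. Missing
#' nutrient values stay `NA` — they are never coerced to zero; downstream
#' classification treats them conservatively.
#'
#' @param db A data frame with canonical columns (see [fop_food_db_columns()]).
#' @return The validated tibble, invisibly classed as `fop_food_db`.
#' @export
validate_food_db <- function(db) {
  db <- tibble::as_tibble(db)
  required <- c("food_id", "category", "processed", "basis", fop_nutrients())
  missing_cols <- setdiff(required, names(db))
  if (length(missing_cols) > 0) {
    stop("food database is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  db$food_id <- as.character(db$food_id)
  dup <- db$food_id[duplicated(db$food_id)]
  if (length(dup) > 0) {
    stop("duplicate food_id in food database: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_basis <- setdiff(unique(db$basis), valid_basis)
  if (length(bad_basis) > 0) {
    stop("unknown basis token(s): ", paste(bad_basis, collapse = ", "),
         "; expected one of ", paste(valid_basis, collapse = ", "),
         call. = FALSE)
  }
  for (nu in fop_nutrients()) {
    neg <- which(!is.na(db[[nu]]) & db[[nu]] < 0)
    if (length(neg) > 0) {
      stop("negative value for nutrient '", nu, "' at row(s) ",
           paste(neg, collapse = ", "), call. = FALSE)
    }
  }
  bad_sugar <- which(!is.na(db$added_sugar) & !is.na(db$total_sugar) &
                       db$added_sugar > db$total_sugar + 1e-9)
  if (length(bad_sugar) > 0) {
    stop("invariant violated (added_sugar <= total_sugar) at row(s) ",
         paste(bad_sugar, collapse = ", "), call. = FALSE)
  }
  bad_fat <- which(!is.na(db$total_fat) &
                     (ifelse(is.na(db$saturated_fat), 0, db$saturated_fat) +
                        ifelse(is.na(db$trans_fat), 0, db$trans_fat)) >
                     db$total_fat + 1e-9)
  if (length(bad_fat) > 0) {
    stop("invariant violated (saturated_fat + trans_fat <= total_fat) ",
         "at row(s) ", paste(bad_fat, collapse = ", "), call. = FALSE)
  }
  no_cat <- which(db$processed & (is.na(db$category) | db$category == ""))
  if (length(no_cat) > 0) {
    stop("processed foods must have a non-empty category; offending row(s): ",
         paste(no_cat, collapse = ", "), call. = FALSE)
  }
  if (!"serving_size" %in% names(db)) db$serving_size <- NA_real_
  if (!"name" %in% names(db)) db$name <- db$food_id
  class(db) <- unique(c("fop_food_db", class(db)))
  db
}

#' Load a food composition database from delimited text
#'
#' Reads a food composition table (one row per food, nutrient content per
#' 100 g or 100 mL) and validates it. Missing optional nutrients become
#' explicit `NA`, never silent zeros.
#'
#' @param path Path to a delimited text file with a header row.
#' @param col_map Named character vector mapping file columns to canonical
#'   names; defaults to [fop_food_db_columns()].
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A validated `fop_food_db` tibble.
#' @export
load_food_db <- function(path, col_map = fop_food_db_columns(), delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  present <- intersect(names(col_map), names(raw))
  if (length(present) == 0) {
    stop("no recognized columns in ", path, call. = FALSE)
  }
  db <- raw[, present, drop = FALSE]
  names(db) <- unname(col_map[present])
  for (nu in c(fop_nutrients(), "serving_size")) {
    if (!nu %in% names(db)) db[[nu]] <- NA_real_ else db[[nu]] <- as.numeric(db[[nu]])
  }
  db$processed <- as.logical(db$processed)
  validate_food_db(db)
}

#' Load 24-hour recall entries
#'
#' Reads person-food consumption records (`person_id`, `food_id`, `amount` in
#' g or mL on the food's basis) and checks every `food_id` against the food
#' database.
#'
#' @param path Path to a delimited text file with header
#'   `person_id,food_id,amount`.
#' @param food_db A validated `fop_food_db`.
#' @param delim Field delimiter.
#' @return A tibble of recall entries.
#' @export
load_recalls <- function(path, food_db, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  req <- c("person_id", "food_id", "amount")
  if (!all(req %in% names(rec))) {
    stop("recall file must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  rec <- tibble::as_tibble(rec[, req])
  rec$person_id <- as.character(rec$person_id)
  rec$food_id <- as.character(rec$food_id)
  rec$amount <- as.numeric(rec$amount)
  if (nrow(rec) == 0) {
    warning("recall file ", path, " contains no entries", call. = FALSE)
    return(rec)
  }
  validate_recalls(rec, food_db)
}

#' Validate recall entries against a food database
#'
#' @param recalls Tibble with `person_id`, `food_id`, `amount`.
#' @param food_db A validated `fop_food_db`.
#' @return The validated tibble.
#' @export
validate_recalls <- function(recalls, food_db) {
  bad_amt <- which(is.na(recalls$amount) | recalls$amount <= 0)
  if (length(bad_amt) > 0) {
    stop("recall amounts must be positive; offending row(s): ",
         paste(bad_amt, collapse = ", "), call. = FALSE)
  }
  unresolved <- sort(unique(setdiff(recalls$food_id, food_db$food_id)))
  if (length(unresolved) > 0) {
    stop("recall entries reference unknown food_id(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  recalls
}

#' Load the participant table
#'
#' Reads person-level covariates and survey design fields: expansion weight,
#' stratum, PSU, sex, age, BMI, region, locality, socioeconomic level and the
#' pregnancy/lactation flag.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter.
#' @return A tibble of participants.
#' @export
load_participants <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pp <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  req <- c("person_id", "weight", "stratum", "psu", "sex", "age", "bmi",
           "region", "locality", "ses", "pregnant_or_lactating")
  if (!all(req %in% names(pp))) {
    stop("participant file must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  pp <- tibble::as_tibble(pp)
  pp$person_id <- as.character(pp$person_id)
  pp$pregnant_or_lactating <- as.logical(pp$pregnant_or_lactating)
  bad_w <- which(is.na(pp$weight) | pp$weight <= 0)
  if (length(bad_w) > 0) {
    stop("survey weights must be positive; offending row(s): ",
         paste(bad_w, collapse = ", "), call. = FALSE)
  }
  pp
}

#' Write a scenario summary table to delimited text
#'
#' One row per nutrient x scenario (and group level, if present), with
#' weighted median, p25, p75, percent change against the reference scenario,
#' and the contrast p-value. Numbers are written at full double precision so a
#' read-back loses nothing beyond printed precision.
#'
#' @param results Tibble as produced by [summarize_scenarios()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_table <- function(results, path) {
  readr::write_csv(results, path)
  invisible(path)
}

#' Read back a scenario summary table
#'
#' @param path Path written by [write_scenario_table()].
#' @return A tibble.
#' @export
read_scenario_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
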