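#' Aggregate recall entries into per-person daily intake
#'
#' Componentwise sum over a person's recall entries of
#' `amount / 100 * per-100 nutrient value`. Grams and milliliters are treated
#' as interchangeable basis units (density 1). Missing nutrient values in the
#' composition table contribute nothing to the sum (a food with unknown
#' sodium adds 0 mg, not `NA`, so one incomplete food does not void a
#' person's whole day).
#'
#' @param recalls Tibble of recall entries (`person_id`, `food_id`,
#'   `amount`).
#' @param db A validated `fop_food_db`.
#' @param nutrients Nutrients to aggregate; defaults to
#'   [fop_intake_nutrients()].
#' @param persons Optional character vector of person ids to include;
#'   persons without entries get an explicit zero vector. Defaults to the
#'   persons present in `recalls`.
#' @return Tibble: `person_id` plus one column per nutrient (kcal/day for
#'   energy, mg/day for sodium, g/day otherwise).
#' @export
aggregate_intake <- function(recalls, db, nutrients = fop_intake_nutrients(),
                             persons = NULL) {
  stopifnot(inherits(db, "fop_food_db"))
  unresolved <- setdiff(unique(recalls$food_id), db$food_id)
  if (length(unresolved) > 0) {
    stop("recall entries reference unknown food_id(s): ",
         paste(sort(unresolved), collapse = ", "), call. = FALSE)
  }
  comp <- db[, c("food_id", nutrients)]
  joined <- dplyr::left_join(recalls, comp, by = "food_id")
  out <- joined |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(nutrients),
      ~ sum(.data$amount / 100 * dplyr::coalesce(.x, 0))), .groups = "drop")
  if (!is.null(persons)) {
    persons <- as.character(persons)
    missing <- setdiff(persons, out$person_id)
    if (length(missing) > 0) {
      zeros <- tibble::as_tibble(
        c(list(person_id = missing),
          stats::setNames(rep(list(0), length(nutrients)), nutrients)))
      out <- dplyr::bind_rows(out, zeros)
    }
    out <- out[match(persons, out$person_id), , drop = FALSE]
  }
  out
}

#' Apply participant exclusion filters
#'
#' Restricts the analysis sample the way large dietary surveys of adults do:
#' keep persons aged within `age_range`, exclude pregnant or lactating women,
#' exclude aberrant BMI outside `bmi_range`, and exclude implausible energy
#' reporters whose daily energy lies outside the unweighted mean +/-
#' `energy_sd_limit` standard deviations, where the mean and SD are computed
#' once over the pool surviving the earlier filters (the energy rule is not
#' iterated). Persons with missing age or BMI cannot be assessed and are
#' excluded under `missing_data`; they are also left out of the energy
#' mean/SD pool.
#'
#' A person failing several filters is counted once, under the first
#' applicable reason in the fixed order: age, pregnancy/lactation, BMI,
#' energy, missing data.
#'
#' @param participants Participant tibble (see [load_participants()]).
#' @param intakes Per-person intake tibble from [aggregate_intake()]; must
#'   cover every participant.
#' @param age_range Inclusive age bounds in years (default 20-59).
#' @param bmi_range Inclusive BMI bounds in kg/m^2 (default 10-58).
#' @param energy_sd_limit Half-width of the energy band in SDs (default 3).
#' @return List with `retained` (participant tibble), `audit` (list:
#'   `initial_n`, per-reason counts, `final_n`), and `excluded` (tibble:
#'   person_id, reason).
#' @export
apply_exclusions <- function(participants, intakes,
                             age_range = c(20, 59),
                             bmi_range = c(10, 58),
                             energy_sd_limit = 3) {
  pp <- tibble::as_tibble(participants)
  missing_int <- setdiff(pp$person_id, intakes$person_id)
  if (length(missing_int) > 0) {
    stop("no intake vector for participant(s): ",
         paste(utils::head(missing_int, 10), collapse = ", "), call. = FALSE)
  }
  energy <- intakes$energy[match(pp$person_id, intakes$person_id)]

  flag_missing <- is.na(pp$age) | is.na(pp$bmi)
  flag_age <- !is.na(pp$age) & (pp$age < age_range[1] | pp$age > age_range[2])
  flag_preg <- !flag_age & isTRUE_vec(pp$pregnant_or_lactating)
  flag_bmi <- !flag_age & !flag_preg & !is.na(pp$bmi) &
    (pp$bmi < bmi_range[1] | pp$bmi > bmi_range[2])

  pool <- !flag_age & !flag_preg & !flag_bmi & !flag_missing
  mu <- mean(energy[pool])
  sdev <- stats::sd(energy[pool])
  flag_energy <- pool &
    (energy < mu - energy_sd_limit * sdev |
       energy > mu + energy_sd_limit * sdev)

  reason <- rep(NA_character_, nrow(pp))
  reason[flag_missing] <- "missing_data"
  reason[flag_energy] <- "energy_outlier"
  reason[flag_bmi] <- "bmi_aberrant"
  reason[flag_preg] <- "pregnant_or_lactating"
  reason[flag_age] <- "age_out_of_range"

  keep <- is.na(reason)
  audit <- list(
    initial_n = nrow(pp),
    age_out_of_range = sum(reason == "age_out_of_range", na.rm = TRUE),
    pregnant_or_lactating = sum(reason == "pregnant_or_lactating",
                                na.rm = TRUE),
    bmi_aberrant = sum(reason == "bmi_aberrant", na.rm = TRUE),
    energy_outlier = sum(reason == "energy_outlier", na.rm = TRUE),
    missing_data = sum(reason == "missing_data", na.rm = TRUE),
    final_n = sum(keep))
  list(retained = pp[keep, , drop = FALSE],
       audit = audit,
       excluded = tibble::tibble(person_id = pp$person_id[!keep],
                                 reason = reason[!keep]))
}

isTRUE_vec <- function(x) !is.na(x) & x
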