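#' Build the non-compliant to compliant replacement map
#'
#' For every non-compliant processed food, the candidate set is every
#' compliant processed food of the same category. When the set is empty the
#' food is unreplaced (it passes through every scenario unchanged). Otherwise
#' the default candidate rule picks the candidate whose energy density
#' (kcal per 100 basis units) is closest to the original's, ties broken by
#' lexicographic `food_id`, which makes the map fully deterministic and keeps
#' the energy-conservation correction factor as close to 1 as the category
#' allows.
#'
#' The correction factor is `energy_density(original) /
#' energy_density(replacement)`; when either density is zero the ratio is
#' undefined and the factor falls back to 1 with a warning.
#'
#' @param db A validated `fop_food_db`.
#' @param criteria An `fop_criteria` object.
#' @param candidate_rule `"nearest_energy"` (default) or a function
#'   `(original_row, candidates_tibble) -> food_id` for a custom rule.
#' @return An object of class `fop_replacement_map`: a tibble with one row
#'   per non-compliant processed food (`food_id`, `category`,
#'   `replacement_id`, `correction_factor`, `replaced`). The unreplaced ids
#'   are rows with `replaced = FALSE` (also in `attr(, "unreplaced")`).
#' @export
build_replacement_map <- function(db, criteria,
                                  candidate_rule = "nearest_energy") {
  cls <- classify_database(db, criteria)
  foods <- cls$foods
  noncomp <- foods[!foods$complies, , drop = FALSE]
  comp <- foods[foods$complies, , drop = FALSE]
  dens <- stats::setNames(db$energy, db$food_id)

  pick <- function(orig_id, cand_ids) {
    cands <- tibble::tibble(food_id = cand_ids,
                            energy_density = unname(dens[cand_ids]))
    if (is.function(candidate_rule)) {
      orig <- db[db$food_id == orig_id, , drop = FALSE]
      return(as.character(candidate_rule(orig, cands)))
    }
    d <- abs(cands$energy_density - dens[[orig_id]])
    best <- cands$food_id[d == min(d)]
    sort(best)[1]
  }

  n <- nrow(noncomp)
  replacement_id <- rep(NA_character_, n)
  factor <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand_ids <- comp$food_id[comp$category == noncomp$category[i]]
    if (length(cand_ids) == 0) next
    rid <- pick(noncomp$food_id[i], cand_ids)
    replacement_id[i] <- rid
    d_orig <- dens[[noncomp$food_id[i]]]
    d_repl <- dens[[rid]]
    if (is.na(d_orig) || is.na(d_repl) || d_orig <= 0 || d_repl <= 0) {
      warning("zero or missing energy density for pair ",
              noncomp$food_id[i], " -> ", rid,
              "; correction factor set to 1", call. = FALSE)
      factor[i] <- 1
    } else {
      factor[i] <- d_orig / d_repl
    }
  }
  map <- tibble::tibble(food_id = noncomp$food_id,
                        category = noncomp$category,
                        replacement_id = replacement_id,
                        correction_factor = factor,
                        replaced = !is.na(replacement_id))
  attr(map, "unreplaced") <- map$food_id[!map$replaced]
  attr(map, "criteria_name") <- criteria$name
  class(map) <- unique(c("fop_replacement_map", class(map)))
  map
}

#' Apply a replacement scenario to recall data
#'
#' Scenario 1 is the observed diet (identity). Scenario 2 swaps each consumed
#' non-compliant food for its mapped compliant replacement, keeping the
#' consumed amount. Scenario 3 additionally multiplies the amount by the
#' energy-density correction factor so the entry delivers the same energy as
#' the original — except for foods in `exempt_categories` (typically
#' sugar-sweetened beverages, bakery and dairy, where rescaling would imply
#' implausibly large portions), which are replaced but keep the original
#' amount, exactly as in scenario 2. Unreplaced foods pass through unchanged
#' in every scenario.
#'
#' @param recalls Tibble of recall entries.
#' @param db A validated `fop_food_db`.
#' @param map An `fop_replacement_map`.
#' @param scenario 1, 2 or 3.
#' @param exempt_categories Categories exempt from the scenario-3 rescaling.
#' @param restrict_to_categories If non-`NULL`, only entries whose food's
#'   category is in this set are eligible for replacement; all other entries
#'   are returned bit-identical.
#' @return A tibble with the same shape as `recalls`, plus a logical
#'   `replaced_entry` column.
#' @export
apply_scenario <- function(recalls, db, map, scenario,
                           exempt_categories = character(),
                           restrict_to_categories = NULL) {
  stopifnot(scenario %in% c(1, 2, 3))
  unresolved <- setdiff(unique(recalls$food_id), db$food_id)
  if (length(unresolved) > 0) {
    stop("recall entries reference food(s) absent from the database: ",
         paste(sort(unresolved), collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(recalls)
  out$replaced_entry <- FALSE
  if (scenario == 1) return(out)

  idx <- match(out$food_id, map$food_id)
  eligible <- !is.na(idx) & map$replaced[pmax(idx, 1L)]
  if (!is.null(restrict_to_categories)) {
    known <- unique(db$category)
    bad <- setdiff(restrict_to_categories, known)
    if (length(bad) > 0) {
      stop("unknown category label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    food_cat <- db$category[match(out$food_id, db$food_id)]
    eligible <- eligible & food_cat %in% restrict_to_categories
  }
  if (!any(eligible)) return(out)

  mrow <- idx[eligible]
  out$food_id[eligible] <- map$replacement_id[mrow]
  out$replaced_entry[eligible] <- TRUE
  if (scenario == 3) {
    exempt <- map$category[mrow] %in% exempt_categories
    out$amount[eligible][!exempt] <-
      out$amount[eligible][!exempt] * map$correction_factor[mrow][!exempt]
  }
  out
}

#' Replace foods in selected categories only
#'
#' Convenience wrapper around [apply_scenario()] with
#' `restrict_to_categories` set: entries outside the category set are
#' returned unchanged. Restricting to the empty set reproduces scenario 1.
#'
#' @inheritParams apply_scenario
#' @param categories Categories eligible for replacement (subset of the
#'   database's category taxonomy).
#' @return A tibble like [apply_scenario()]'s.
#' @export
run_restricted_replacement <- function(recalls, db, map, categories,
                                       scenario = 2,
                                       exempt_categories = character()) {
  apply_scenario(recalls, db, map, scenario = scenario,
                 exempt_categories = exempt_categories,
                 restrict_to_categories = categories)
}

#' Export a replacement map as CSV
#'
#' @param map An `fop_replacement_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_replacement_map <- function(map, path) {
  readr::write_csv(tibble::as_tibble(map), path)
  invisible(path)
}
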