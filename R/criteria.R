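valid_denominators <- c("per_100_basis", "per_serving", "pct_of_energy",
                        "pct_of_total_fat")

# Atwater-type energy conversion factors used for %-of-energy denominators.
kcal_per_gram <- c(saturated_fat = 9, trans_fat = 9, total_fat = 9,
                   total_sugar = 4, added_sugar = 4)

#' Construct a nutrient-profiling criteria set
#'
#' A criteria set is a named collection of per-category rules: each category
#' is either eligible to carry the front-of-package logo or not, and eligible
#' categories carry nutrient thresholds (cut-offs per 100 g/mL, per serving,
#' or as a percent of energy or of total fat). A food complies when its
#' category is eligible and every threshold passes; comparators are inclusive.
#'
#' @param name Name of the criteria set.
#' @param categories Tibble with columns `category` (unique labels) and
#'   `eligible` (logical; ineligible categories can never carry the logo).
#' @param thresholds Tibble with columns `category`, `nutrient` (one of
#'   [fop_nutrients()]), `cmp` (`"<="` or `">="`), `limit` (non-negative), and
#'   `per` (denominator: `per_100_basis`, `per_serving`, `pct_of_energy`, or
#'   `pct_of_total_fat`).
#' @param allow_ge Nutrients allowed the `">="` comparator; by default only
#'   fiber, the one nutrient for which more is better.
#' @return An object of class `fop_criteria`.
#' @export
criteria_set <- function(name, categories, thresholds, allow_ge = "fiber") {
  categories <- tibble::as_tibble(categories)
  thresholds <- tibble::as_tibble(thresholds)
  stopifnot(all(c("category", "eligible") %in% names(categories)),
            all(c("category", "nutrient", "cmp", "limit", "per") %in%
                  names(thresholds)))
  dup <- categories$category[duplicated(categories$category)]
  if (length(dup) > 0) {
    stop("duplicate category in criteria set: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_nut <- setdiff(unique(thresholds$nutrient), fop_nutrients())
  if (length(bad_nut) > 0) {
    stop("unknown nutrient(s) in thresholds: ",
         paste(bad_nut, collapse = ", "), call. = FALSE)
  }
  bad_per <- setdiff(unique(thresholds$per), valid_denominators)
  if (length(bad_per) > 0) {
    stop("unknown denominator token(s): ", paste(bad_per, collapse = ", "),
         call. = FALSE)
  }
  bad_cmp <- setdiff(unique(thresholds$cmp), c("<=", ">="))
  if (length(bad_cmp) > 0) {
    stop("comparator must be '<=' or '>='; got: ",
         paste(bad_cmp, collapse = ", "), call. = FALSE)
  }
  ge_bad <- thresholds$nutrient[thresholds$cmp == ">=" &
                                  !thresholds$nutrient %in% allow_ge]
  if (length(ge_bad) > 0) {
    stop("'>=' comparator only allowed for: ",
         paste(allow_ge, collapse = ", "), "; got it on: ",
         paste(unique(ge_bad), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(thresholds$limit) | thresholds$limit < 0)) {
    stop("threshold limits must be non-negative", call. = FALSE)
  }
  orphan <- setdiff(unique(thresholds$category), categories$category)
  if (length(orphan) > 0) {
    stop("thresholds reference categories not in the set: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  key <- paste(thresholds$category, thresholds$nutrient, thresholds$per)
  if (anyDuplicated(key)) {
    stop("at most one threshold per (category, nutrient, denominator); ",
         "duplicated: ", paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  structure(list(name = name, categories = categories,
                 thresholds = thresholds),
            class = "fop_criteria")
}

#' @export
print.fop_criteria <- function(x, ...) {
  cat("<fop_criteria> ", x$name, "\n", sep = "")
  cat("  categories: ", nrow(x$categories),
      " (", sum(!x$categories$eligible), " ineligible)\n", sep = "")
  cat("  thresholds: ", nrow(x$thresholds), "\n", sep = "")
  invisible(x)
}

#' Number of categories in a criteria set
#' @param criteria An `fop_criteria` object.
#' @return Integer count.
#' @export
category_count <- function(criteria) {
  stopifnot(inherits(criteria, "fop_criteria"))
  nrow(criteria$categories)
}

#' Load a criteria set from a YAML or JSON configuration file
#'
#' The file has keys `name` and `categories`, each category an object
#' `{category, eligible, thresholds: [{nutrient, cmp, limit, per}]}`.
#' Format is chosen by extension (`.yaml`/`.yml` or `.json`).
#'
#' Two illustrative configurations ship with the package under
#' `system.file("extdata", package = "fopsim")`: a 19-category committee-style
#' set whose sugar limits target added sugar, and a 26-category
#' regulatory-style set whose sugar limits target total sugar and which marks
#' sugar-based categories (soft drinks, jam, jelly, syrup, honey, chocolate
#' products) ineligible for the logo. Their numeric cut-offs are
#' approximations for demonstration, not any authority's published values.
#'
#' @param path Path to the configuration file.
#' @return An `fop_criteria` object.
#' @export
load_criteria <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    stop("unsupported criteria config extension: .", ext, call. = FALSE)
  }
  if (is.null(cfg$name) || is.null(cfg$categories)) {
    stop("criteria config must have keys 'name' and 'categories' (", path,
         ")", call. = FALSE)
  }
  cats <- tibble::tibble(
    category = vapply(cfg$categories, function(x) as.character(x$category),
                      character(1)),
    eligible = vapply(cfg$categories, function(x) {
      if (is.null(x$eligible)) TRUE else isTRUE(x$eligible)
    }, logical(1)))
  thr_list <- lapply(cfg$categories, function(x) {
    if (is.null(x$thresholds) || length(x$thresholds) == 0) return(NULL)
    tibble::tibble(
      category = as.character(x$category),
      nutrient = vapply(x$thresholds, function(t) as.character(t$nutrient),
                        character(1)),
      cmp = vapply(x$thresholds, function(t) as.character(t$cmp),
                   character(1)),
      limit = vapply(x$thresholds, function(t) as.numeric(t$limit),
                     numeric(1)),
      per = vapply(x$thresholds, function(t) as.character(t$per),
                   character(1)))
  })
  thr <- dplyr::bind_rows(thr_list)
  if (nrow(thr) == 0) {
    thr <- tibble::tibble(category = character(), nutrient = character(),
                          cmp = character(), limit = numeric(),
                          per = character())
  }
  tryCatch(
    criteria_set(cfg$name, cats, thr),
    error = function(e) stop("invalid criteria config ", path, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' Evaluate one threshold against one food
#'
#' Computes the observed value on the threshold's denominator and compares it
#' (inclusively) with the limit. Denominators: `per_100_basis` reads the
#' per-100 profile directly; `per_serving` scales by `serving_size / 100`;
#' `pct_of_energy` converts grams to kcal (9 kcal/g for fats, 4 kcal/g for
#' sugars) and expresses them as a percentage of the food's energy;
#' `pct_of_total_fat` expresses the nutrient as a percentage of total fat by
#' weight. A missing nutrient, a `per_serving` rule on a food without a
#' serving size, or a percentage denominator with zero energy/total fat all
#' fail conservatively with a recorded reason.
#'
#' @param food A one-row slice of an `fop_food_db` (or equivalent named list).
#' @param nutrient,cmp,limit,per Threshold fields (see [criteria_set()]).
#' @return List with `observed` (numeric, `NA` when not computable), `passes`
#'   (logical) and `reason` (`NA` or the conservative-failure reason).
#' @export
evaluate_threshold <- function(food, nutrient, cmp, limit, per) {
  fail <- function(reason) list(observed = NA_real_, passes = FALSE,
                                reason = reason)
  value <- food[[nutrient]]
  if (is.null(value) || length(value) == 0 || is.na(value)) {
    return(fail(paste0("missing nutrient '", nutrient, "'")))
  }
  observed <- switch(per,
    per_100_basis = value,
    per_serving = {
      ss <- food[["serving_size"]]
      if (is.null(ss) || length(ss) == 0 || is.na(ss)) {
        return(fail("per_serving rule without serving_size"))
      }
      value * ss / 100
    },
    pct_of_energy = {
      en <- food[["energy"]]
      if (is.null(en) || length(en) == 0 || is.na(en) || en <= 0) {
        return(fail("pct_of_energy rule with missing or zero energy"))
      }
      factor <- kcal_per_gram[[nutrient]]
      if (is.null(factor)) {
        return(fail(paste0("pct_of_energy undefined for '", nutrient, "'")))
      }
      100 * factor * value / en
    },
    pct_of_total_fat = {
      tf <- food[["total_fat"]]
      if (is.null(tf) || length(tf) == 0 || is.na(tf) || tf <= 0) {
        return(fail("pct_of_total_fat rule with missing or zero total fat"))
      }
      100 * value / tf
    },
    stop("unknown denominator: ", per, call. = FALSE))
  passes <- if (cmp == "<=") observed <= limit else observed >= limit
  list(observed = observed, passes = passes, reason = NA_character_)
}

#' Classify one food against a criteria set
#'
#' A food complies when its category is eligible for the logo and every
#' threshold for that category passes. All failures are enumerated, not just
#' the first.
#'
#' @param food A one-row slice of an `fop_food_db`.
#' @param criteria An `fop_criteria` object.
#' @return List with `food_id`, `complies`, `ineligible_category`, and
#'   `failed_thresholds` (tibble: nutrient, per, cmp, observed, limit,
#'   reason).
#' @export
classify_food <- function(food, criteria) {
  stopifnot(inherits(criteria, "fop_criteria"))
  cat_row <- which(criteria$categories$category == food[["category"]])
  if (length(cat_row) == 0) {
    stop("category '", food[["category"]], "' absent from criteria set '",
         criteria$name, "'", call. = FALSE)
  }
  empty_fail <- tibble::tibble(nutrient = character(), per = character(),
                               cmp = character(), observed = numeric(),
                               limit = numeric(), reason = character())
  if (!criteria$categories$eligible[cat_row]) {
    return(list(food_id = food[["food_id"]], complies = FALSE,
                ineligible_category = TRUE, failed_thresholds = empty_fail))
  }
  thr <- criteria$thresholds[criteria$thresholds$category ==
                               food[["category"]], , drop = FALSE]
  fails <- empty_fail
  if (nrow(thr) > 0) {
    for (i in seq_len(nrow(thr))) {
      res <- evaluate_threshold(food, thr$nutrient[i], thr$cmp[i],
                                thr$limit[i], thr$per[i])
      if (!res$passes) {
        fails <- dplyr::bind_rows(fails, tibble::tibble(
          nutrient = thr$nutrient[i], per = thr$per[i], cmp = thr$cmp[i],
          observed = res$observed, limit = thr$limit[i],
          reason = res$reason))
      }
    }
  }
  list(food_id = food[["food_id"]], complies = nrow(fails) == 0,
       ineligible_category = FALSE, failed_thresholds = fails)
}

#' Classify every processed food in a database
#'
#' Applies [classify_food()] to each processed food and summarizes: counts and
#' fractions of compliant, non-compliant, and non-compliant-but-replaceable
#' foods. A non-compliant food is replaceable when at least one compliant
#' processed food shares its category.
#'
#' @param db A validated `fop_food_db`.
#' @param criteria An `fop_criteria` object.
#' @return List with `foods` (tibble: food_id, category, complies,
#'   ineligible_category, n_failed — processed foods only) and `summary`
#'   (one-row tibble: n_processed, n_compliant, n_noncompliant,
#'   n_replaceable, frac_compliant, frac_noncompliant, frac_replaceable;
#'   fractions are `NaN` when there are no processed foods, and
#'   `frac_replaceable` is the replaceable share *of the non-compliant*
#'   foods).
#' @export
classify_database <- function(db, criteria) {
  stopifnot(inherits(db, "fop_food_db"))
  proc <- db[db$processed, , drop = FALSE]
  if (nrow(proc) == 0) {
    foods <- tibble::tibble(food_id = character(), category = character(),
                            complies = logical(),
                            ineligible_category = logical(),
                            n_failed = integer())
  } else {
    rows <- lapply(seq_len(nrow(proc)), function(i) {
      cl <- classify_food(proc[i, ], criteria)
      tibble::tibble(food_id = cl$food_id, category = proc$category[i],
                     complies = cl$complies,
                     ineligible_category = cl$ineligible_category,
                     n_failed = nrow(cl$failed_thresholds))
    })
    foods <- dplyr::bind_rows(rows)
  }
  compliant_cats <- unique(foods$category[foods$complies])
  foods$replaceable <- !foods$complies & foods$category %in% compliant_cats
  n_proc <- nrow(foods)
  n_comp <- sum(foods$complies)
  n_nc <- n_proc - n_comp
  n_repl <- sum(foods$replaceable)
  summary <- tibble::tibble(
    n_processed = n_proc, n_compliant = n_comp, n_noncompliant = n_nc,
    n_replaceable = n_repl,
    frac_compliant = n_comp / n_proc,
    frac_noncompliant = n_nc / n_proc,
    frac_replaceable = n_repl / n_nc)
  list(foods = foods, summary = summary)
}
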