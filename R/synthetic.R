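#' Configuration for the synthetic dietary survey generator
#'
#' Describes a synthetic population and food supply with known ground truth:
#' a food database whose compliance labels are planted exactly, a matching
#' nutrient-profiling criteria set, one 24-hour recall per person with
#' log-normal daily energy, a stratified PSU design with dispersed expansion
#' weights, and planted exclusion cases. Every draw comes from one seeded
#' RNG stream, so a config determines its survey byte-for-byte.
#'
#' Defaults emulate the conditions of a national adult dietary survey: daily
#' energy log-normal with median 1905 kcal (log-SD 0.43, matching a p25-p75
#' of roughly 1380-2480 kcal), one to two recall entries per food category
#' per person-day (15-20 entries in total), a food supply of 12 categories
#' (3 unprocessed staple categories plus 9 processed ones in which 60% of
#' consumption falls on non-compliant foods), 75% of processed categories
#' containing at least one compliant replacement candidate, and compliant
#' foods formulated with less energy (-15%), saturated fat (-40%), trans fat
#' (-35%), sugar (-50%) and sodium (-25%) per kcal but more fiber (+30%)
#' than their non-compliant counterparts.
#'
#' Diet composition is stable across persons: each person consumes every
#' category at the population category share (times log-normal portion
#' noise), and the non-compliant amount fraction within a processed category
#' is fixed at `fraction_noncompliant` rather than drawn per entry. This is
#' what makes the closed-form [expected_change()] a valid target for the
#' median-based pipeline estimate; real surveys add between-person
#' composition heterogeneity that the generator deliberately does not model.
#'
#' @param seed Integer seed; fully determines the generated survey.
#' @param n_participants Number of persons.
#' @param energy_median Median daily energy target, kcal.
#' @param energy_log_sd Log-scale SD of daily energy.
#' @param energy_trunc_z Regular (non-planted) energy targets are drawn from
#'   the log-normal truncated at +/- this many log-SDs, so that the only
#'   persons outside the survey's +/-3 SD energy filter are the planted
#'   outliers.
#' @param amount_log_sd Log-scale SD of relative portion sizes.
#' @param n_categories Total food categories.
#' @param n_unprocessed How many of them are unprocessed staple categories
#'   (never candidates for replacement).
#' @param foods_per_category Foods generated per category.
#' @param fraction_noncompliant Probability that a recall entry in a
#'   processed category falls on a non-compliant food (also sets the
#'   non-compliant share of foods within each processed category).
#' @param fraction_replaceable Fraction of processed categories that contain
#'   at least one compliant food (the rest are unreplaceable).
#' @param reductions Named vector of planted per-kcal reduction fractions of
#'   compliant relative to non-compliant foods; negative values mean the
#'   compliant food has more (used for fiber). `energy` is the reduction in
#'   energy density.
#' @param noise_sd Log-scale SD of within-category nutrient variation
#'   between foods.
#' @param energy_noise_sd Log-scale SD of within-category energy-density
#'   variation; kept tighter than `noise_sd` because energy density varies
#'   far less across brands within a category than individual nutrients do
#'   (it also keeps the nearest-energy-density replacement rule neutral with
#'   respect to the planted per-kcal reductions).
#' @param category_weights Optional non-negative weights (length
#'   `n_categories`) for entry-level category choice; default weights give
#'   sugar-sweetened beverages the largest single share.
#' @param exempt_categories Categories exempt from scenario-3 rescaling;
#'   default: the generated sugar-sweetened-beverage, bakery, and dairy
#'   categories (when present).
#' @param n_strata,psus_per_stratum,weight_log_sd Survey design: strata
#'   count, PSUs per stratum, log-scale SD of expansion weights.
#' @param n_pregnant,n_bmi_aberrant,n_energy_outliers Planted exclusion
#'   cases.
#' @param locality_probs Named probabilities for rural/urban residence.
#' @param locality_processed_multiplier Named multipliers on replaceable
#'   processed-category weights by locality (default no difference); used to
#'   plant subgroup-specific effects.
#' @return A validated list of class `fop_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_participants = 2000,
                             energy_median = 1905,
                             energy_log_sd = 0.43,
                             energy_trunc_z = 1.8,
                             amount_log_sd = 0.3,
                             n_categories = 12,
                             n_unprocessed = 3,
                             foods_per_category = 8,
                             fraction_noncompliant = 0.6,
                             fraction_replaceable = 0.75,
                             reductions = c(energy = 0.15,
                                            saturated_fat = 0.40,
                                            trans_fat = 0.35,
                                            total_sugar = 0.50,
                                            added_sugar = 0.50,
                                            sodium = 0.25,
                                            fiber = -0.30),
                             noise_sd = 0.05,
                             energy_noise_sd = 0.03,
                             category_weights = NULL,
                             exempt_categories = NULL,
                             n_strata = 8,
                             psus_per_stratum = 6,
                             weight_log_sd = 0.5,
                             n_pregnant = 5,
                             n_bmi_aberrant = 2,
                             n_energy_outliers = 3,
                             locality_probs = c(rural = 0.25, urban = 0.75),
                             locality_processed_multiplier =
                               c(rural = 1, urban = 1)) {
  cfg <- as.list(environment())
  validate_generator_config(cfg)
  structure(cfg, class = "fop_generator_config")
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_participants >= 1,
              n_categories >= 2, n_unprocessed >= 0,
              n_unprocessed < n_categories, foods_per_category >= 1,
              energy_median > 0, energy_log_sd > 0, noise_sd > 0,
              energy_noise_sd > 0)
    if (fraction_noncompliant < 0 || fraction_noncompliant > 1) {
      stop("fraction_noncompliant must lie in [0, 1]", call. = FALSE)
    }
    if (fraction_replaceable < 0 || fraction_replaceable > 1) {
      stop("fraction_replaceable must lie in [0, 1]", call. = FALSE)
    }
    if (fraction_replaceable > 0 && foods_per_category < 2) {
      stop("infeasible config: fraction_replaceable > 0 needs at least 2 ",
           "foods per category (one compliant candidate)", call. = FALSE)
    }
    n_plants <- n_pregnant + n_bmi_aberrant + n_energy_outliers
    if (n_plants >= n_participants) {
      stop("infeasible config: planted exclusions (", n_plants,
           ") must be fewer than participants (", n_participants, ")",
           call. = FALSE)
    }
    if (n_energy_outliers > 0.01 * n_participants + 5) {
      stop("infeasible config: too many planted energy outliers would ",
           "inflate the +/-3 SD band past the plants themselves",
           call. = FALSE)
    }
    if (!is.null(category_weights) &&
        length(category_weights) != n_categories) {
      stop("category_weights must have length n_categories", call. = FALSE)
    }
    invisible(NULL)
  })
}

# Category anchor library: plausible energy densities (kcal/100) and per-100
# nutrient anchors, recycled to the configured number of categories.
category_anchor_library <- function() {
  tibble::tribble(
    ~name, ~basis, ~energy, ~saturated_fat, ~trans_fat, ~total_fat,
    ~total_sugar, ~added_sugar, ~sodium, ~fiber,
    "sugar_sweetened_beverages", "per_100_mL", 44, 0, 0, 0, 11, 11, 10, 0,
    "sweet_bakery", "per_100_g", 420, 8, 0.8, 18, 24, 20, 320, 2,
    "dairy_drinks", "per_100_mL", 80, 1.8, 0.08, 3, 10, 6, 50, 0,
    "cereal_bars", "per_100_g", 447, 4, 0.3, 12, 30, 26, 210, 4,
    "salty_snacks", "per_100_g", 520, 6, 0.5, 30, 2, 1, 700, 3,
    "processed_meats", "per_100_g", 280, 9, 0.4, 24, 1.5, 1, 1000, 0,
    "breakfast_cereals", "per_100_g", 380, 2, 0.1, 4, 25, 22, 400, 5,
    "confectionery", "per_100_g", 480, 12, 0.6, 22, 55, 50, 80, 1.5,
    "sauces_dressings", "per_100_g", 160, 2.5, 0.2, 12, 12, 10, 900, 0.8,
    "instant_soups", "per_100_g", 350, 5, 0.6, 14, 6, 4, 1800, 2.5,
    "cheeses", "per_100_g", 330, 15, 0.7, 26, 1.5, 0, 650, 0,
    "cookies", "per_100_g", 460, 10, 1.0, 20, 32, 28, 300, 2.2,
    "flavored_yogurt", "per_100_g", 95, 2.2, 0.1, 3.5, 13, 8, 55, 0.3,
    "canned_goods", "per_100_g", 120, 1, 0.05, 4, 5, 3, 450, 2,
    "ready_meals", "per_100_g", 180, 4, 0.3, 9, 3, 2, 520, 1.8,
    "spreads", "per_100_g", 540, 14, 1.2, 55, 8, 7, 480, 1)
}

unprocessed_anchor_library <- function() {
  tibble::tribble(
    ~name, ~basis, ~energy, ~saturated_fat, ~trans_fat, ~total_fat,
    ~total_sugar, ~added_sugar, ~sodium, ~fiber,
    "fresh_fruit", "per_100_g", 55, 0.1, 0, 0.3, 10, 0, 2, 2.5,
    "vegetables", "per_100_g", 30, 0.1, 0, 0.2, 3, 0, 15, 2.8,
    "plain_staples", "per_100_g", 130, 0.3, 0, 1, 0.5, 0, 5, 2.5,
    "fresh_meat_fish", "per_100_g", 150, 3, 0.1, 8, 0, 0, 70, 0,
    "legumes", "per_100_g", 115, 0.2, 0, 0.8, 1, 0, 10, 6)
}

recycle_anchors <- function(lib, n, suffix_from = 1) {
  reps <- ceiling(n / nrow(lib))
  out <- lib[rep(seq_len(nrow(lib)), reps)[seq_len(n)], , drop = FALSE]
  dup <- duplicated(out$name)
  if (any(dup)) {
    out$name[dup] <- paste0(out$name[dup], "_",
                            cumsum(dup)[dup] + suffix_from)
  }
  out
}

# Internal: per-category plan (anchors, counts, shares, flags).
build_category_plan <- function(cfg) {
  n_proc <- cfg$n_categories - cfg$n_unprocessed
  proc <- recycle_anchors(category_anchor_library(), n_proc)
  proc$processed <- TRUE
  if (cfg$n_unprocessed > 0) {
    unproc <- recycle_anchors(unprocessed_anchor_library(), cfg$n_unprocessed)
    unproc$processed <- FALSE
    plan <- dplyr::bind_rows(proc, unproc)
  } else {
    plan <- proc
  }
  n_unrepl <- round((1 - cfg$fraction_replaceable) * n_proc)
  replaceable <- rep(TRUE, nrow(plan))
  if (n_unrepl > 0) {
    replaceable[seq(n_proc - n_unrepl + 1, n_proc)] <- FALSE
  }
  replaceable[!plan$processed] <- FALSE
  plan$replaceable <- replaceable

  fpc <- cfg$foods_per_category
  plan$n_noncompliant <- ifelse(
    !plan$processed, 0L,
    ifelse(plan$replaceable,
           pmin(pmax(round(cfg$fraction_noncompliant * fpc), 1L), fpc - 1L),
           fpc))
  plan$n_compliant <- ifelse(plan$processed,
                             fpc - plan$n_noncompliant,
                             fpc)
  if (any(plan$processed & plan$replaceable & plan$n_compliant == 0)) {
    stop("infeasible config: a replaceable category has zero compliant ",
         "foods", call. = FALSE)
  }
  if (is.null(cfg$category_weights)) {
    w <- rep(1, nrow(plan))
    w[!plan$processed] <- 1.5
    w[plan$name == "sugar_sweetened_beverages"] <- 2.5
  } else {
    w <- cfg$category_weights
  }
  plan$weight <- w / sum(w)
  plan
}

default_exempt <- function(plan) {
  intersect(c("sugar_sweetened_beverages", "sweet_bakery", "dairy_drinks",
              "flavored_yogurt"), plan$name)
}

# Planted compliant/non-compliant per-100 anchor for nutrient k in a
# category. The compliant reformulation only applies to processed
# categories; unprocessed staples keep their anchors as-is.
planted_anchor <- function(plan_row, nutrient, compliant, reductions) {
  a <- plan_row[[nutrient]]
  if (!compliant || !isTRUE(plan_row$processed)) return(a)
  r <- if (nutrient %in% names(reductions)) reductions[[nutrient]] else 0
  r_e <- reductions[["energy"]]
  if (nutrient == "energy") a * (1 - r_e) else a * (1 - r) * (1 - r_e)
}

# Criteria thresholds generated 3 noise-SDs beyond the compliant anchor, so
# planted-compliant foods pass with near-certainty while planted
# non-compliant foods reliably fail on the strongly reduced nutrients.
build_generated_criteria <- function(plan, cfg) {
  margin <- exp(3 * cfg$noise_sd)
  thr <- list()
  for (i in seq_len(nrow(plan))) {
    if (!plan$processed[i]) next
    for (nu in c("energy", "saturated_fat", "trans_fat", "total_sugar",
                 "added_sugar", "sodium")) {
      r <- if (nu %in% names(cfg$reductions)) cfg$reductions[[nu]] else 0
      if (plan[[nu]][i] <= 0 || r <= 0) next
      lim <- planted_anchor(plan[i, ], nu, TRUE, cfg$reductions) * margin
      thr[[length(thr) + 1]] <- tibble::tibble(
        category = plan$name[i], nutrient = nu, cmp = "<=",
        limit = lim, per = "per_100_basis")
    }
    r_f <- cfg$reductions[["fiber"]]
    if (!is.na(r_f) && r_f < 0 && plan$fiber[i] > 0) {
      lim <- planted_anchor(plan[i, ], "fiber", TRUE, cfg$reductions) / margin
      thr[[length(thr) + 1]] <- tibble::tibble(
        category = plan$name[i], nutrient = "fiber", cmp = ">=",
        limit = lim, per = "per_100_basis")
    }
  }
  criteria_set(
    name = "synthetic",
    categories = tibble::tibble(category = plan$name,
                                eligible = TRUE),
    thresholds = dplyr::bind_rows(thr))
}

# One food's nutrient row from anchors plus log-normal noise, honouring the
# composition invariants (added <= total sugar, sat + trans <= total fat).
draw_food_profile <- function(plan_row, compliant, cfg) {
  sd <- cfg$noise_sd
  val <- function(nu, s = sd) {
    a <- planted_anchor(plan_row, nu, compliant, cfg$reductions)
    if (a <= 0) 0 else a * exp(stats::rnorm(1, 0, s))
  }
  energy <- val("energy", cfg$energy_noise_sd)
  total_sugar <- val("total_sugar")
  added_ratio <- if (plan_row$total_sugar > 0) {
    plan_row$added_sugar / plan_row$total_sugar
  } else 0
  saturated_fat <- val("saturated_fat")
  trans_fat <- val("trans_fat")
  total_fat <- max(val("total_fat"), (saturated_fat + trans_fat) * 1.02)
  list(energy = energy, saturated_fat = saturated_fat,
       trans_fat = trans_fat, total_fat = total_fat,
       total_sugar = total_sugar,
       added_sugar = total_sugar * added_ratio,
       sodium = val("sodium"), fiber = val("fiber"))
}

anchor_profile <- function(plan_row, compliant, cfg) {
  out <- lapply(c("energy", "saturated_fat", "trans_fat", "total_fat",
                  "total_sugar", "added_sugar", "sodium", "fiber"),
                function(nu) planted_anchor(plan_row, nu, compliant,
                                            cfg$reductions))
  names(out) <- c("energy", "saturated_fat", "trans_fat", "total_fat",
                  "total_sugar", "added_sugar", "sodium", "fiber")
  out
}

#' Generate a complete synthetic dietary survey
#'
#' Builds, from one seeded RNG stream: a food database with planted
#' compliance labels (enforced exactly by rejection sampling against the
#' generated criteria set), the matching criteria set, per-person 24-hour
#' recalls whose daily energy hits each person's log-normal target exactly,
#' a participant table with stratified PSU design and planted exclusion
#' cases, and the analytic ground truth ([expected_change()] plus the
#' planted labels).
#'
#' @param config An [generator_config()] object.
#' @return List of class `fop_survey`: `db` (validated `fop_food_db`),
#'   `criteria` (`fop_criteria`), `recalls`, `participants`, `truth` (list:
#'   `expected_change_s3`, `expected_change_s2`, `planted_excluded`,
#'   `food_compliance`, `exempt_categories`), and `config`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "fop_generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  plan <- build_category_plan(config)
  criteria <- build_generated_criteria(plan, config)
  exempt <- if (is.null(config$exempt_categories)) {
    default_exempt(plan)
  } else config$exempt_categories

  # --- foods -----------------------------------------------------------
  foods <- list()
  for (i in seq_len(nrow(plan))) {
    labels <- c(rep(FALSE, plan$n_noncompliant[i]),
                rep(TRUE, plan$n_compliant[i]))
    for (j in seq_along(labels)) {
      compliant <- labels[j]
      fid <- sprintf("F%02d_%02d", i, j)
      prof <- NULL
      for (try in seq_len(200)) {
        cand <- draw_food_profile(plan[i, ], compliant, config)
        row <- c(list(food_id = fid, category = plan$name[i],
                      serving_size = 30), cand)
        if (!plan$processed[i]) { prof <- cand; break }
        cl <- classify_food(row, criteria)
        if (cl$complies == compliant) { prof <- cand; break }
      }
      if (is.null(prof)) prof <- anchor_profile(plan[i, ], compliant, config)
      foods[[length(foods) + 1]] <- tibble::as_tibble(c(
        list(food_id = fid,
             name = paste0(plan$name[i], " item ", j),
             category = plan$name[i],
             processed = plan$processed[i],
             basis = plan$basis[i],
             serving_size = 30,
             planted_compliant = compliant),
        prof))
    }
  }
  db <- dplyr::bind_rows(foods)
  planted <- db[, c("food_id", "category", "planted_compliant")]
  db$planted_compliant <- NULL
  db <- validate_food_db(db)

  # --- participants ----------------------------------------------------
  n <- config$n_participants
  pid <- sprintf("P%05d", seq_len(n))
  stratum <- sample(seq_len(config$n_strata), n, replace = TRUE)
  psu <- paste0(stratum, "-",
                sample(seq_len(config$psus_per_stratum), n, replace = TRUE))
  participants <- tibble::tibble(
    person_id = pid,
    weight = exp(stats::rnorm(n, 0, config$weight_log_sd)),
    stratum = stratum,
    psu = psu,
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.52, 0.48)),
    age = sample(20:59, n, TRUE),
    bmi = pmin(pmax(stats::rnorm(n, 27.5, 4.5), 16.5), 45),
    region = sample(c("north", "center", "south"), n, TRUE,
                    prob = c(0.2, 0.49, 0.31)),
    locality = sample(names(config$locality_probs), n, TRUE,
                      prob = config$locality_probs),
    ses = sample(c("low", "middle", "high"), n, TRUE,
                 prob = c(0.3, 0.3, 0.4)),
    pregnant_or_lactating = FALSE)

  # planted exclusion cases, on distinct persons
  plant_pool <- sample(seq_len(n))
  take <- function(k, eligible = rep(TRUE, n)) {
    picked <- plant_pool[eligible[plant_pool]][seq_len(k)]
    plant_pool <<- setdiff(plant_pool, picked)
    picked
  }
  planted_excluded <- tibble::tibble(person_id = character(),
                                     reason = character())
  if (config$n_pregnant > 0) {
    idx <- take(config$n_pregnant, participants$sex == "female")
    participants$pregnant_or_lactating[idx] <- TRUE
    planted_excluded <- dplyr::bind_rows(planted_excluded, tibble::tibble(
      person_id = pid[idx], reason = "pregnant_or_lactating"))
  }
  if (config$n_bmi_aberrant > 0) {
    idx <- take(config$n_bmi_aberrant)
    participants$bmi[idx] <- rep(c(60.5, 9.0),
                                 length.out = config$n_bmi_aberrant)
    planted_excluded <- dplyr::bind_rows(planted_excluded, tibble::tibble(
      person_id = pid[idx], reason = "bmi_aberrant"))
  }
  energy_boost <- rep(1, n)
  if (config$n_energy_outliers > 0) {
    idx <- take(config$n_energy_outliers)
    energy_boost[idx] <- 6
    planted_excluded <- dplyr::bind_rows(planted_excluded, tibble::tibble(
      person_id = pid[idx], reason = "energy_outlier"))
  }

  # --- recalls ---------------------------------------------------------
  # Truncated log-normal energy targets keep regular persons inside the
  # +/-3 SD screen, so the planted outliers are exactly the removed set;
  # planted outliers sit at a fixed multiple of the median energy.
  z_lim <- config$energy_trunc_z
  u <- stats::runif(n, stats::pnorm(-z_lim), stats::pnorm(z_lim))
  target <- config$energy_median * exp(config$energy_log_sd * stats::qnorm(u))
  target[energy_boost > 1] <- config$energy_median *
    energy_boost[energy_boost > 1]

  # Composition-stable diets: every person consumes every category, at the
  # population category share times log-normal portion noise, with the
  # non-compliant amount fraction fixed at fraction_noncompliant. This keeps
  # the replaced share of each nutrient nearly constant across persons, so
  # the median-based pipeline estimate tracks the mean-based closed form.
  weights_for <- function(loc) {
    mult <- config$locality_processed_multiplier[[loc]]
    w <- plan$weight
    w[plan$replaceable] <- w[plan$replaceable] * mult
    w / sum(w)
  }
  w_by_loc <- lapply(stats::setNames(names(config$locality_probs),
                                     names(config$locality_probs)),
                     weights_for)
  pool_nc <- split(planted$food_id[!planted$planted_compliant],
                   planted$category[!planted$planted_compliant])
  pool_c <- split(planted$food_id[planted$planted_compliant],
                  planted$category[planted$planted_compliant])
  dens <- stats::setNames(db$energy, db$food_id)
  f_nc <- config$fraction_noncompliant

  # per-category sub-entry template: (category index, compliant?, base share)
  tmpl <- list()
  for (i in seq_len(nrow(plan))) {
    cc <- plan$name[i]
    has_c <- !is.null(pool_c[[cc]]) && length(pool_c[[cc]]) > 0
    has_nc <- !is.null(pool_nc[[cc]]) && length(pool_nc[[cc]]) > 0
    if (!plan$processed[i]) {
      tmpl[[length(tmpl) + 1]] <- list(i = i, compliant = TRUE, frac = 1)
    } else {
      f <- if (has_c && has_nc) f_nc else if (has_nc) 1 else 0
      if (f > 0) {
        tmpl[[length(tmpl) + 1]] <- list(i = i, compliant = FALSE, frac = f)
      }
      if (f < 1 && has_c) {
        tmpl[[length(tmpl) + 1]] <- list(i = i, compliant = TRUE,
                                         frac = 1 - f)
      }
    }
  }
  k <- length(tmpl)
  t_cat <- vapply(tmpl, `[[`, integer(1), "i")
  t_cpl <- vapply(tmpl, `[[`, logical(1), "compliant")
  t_frac <- vapply(tmpl, `[[`, numeric(1), "frac")

  person_of <- rep(seq_len(n), each = k)
  slot_of <- rep(seq_len(k), times = n)
  base_share <- vapply(seq_len(n * k), function(j) {
    w <- w_by_loc[[participants$locality[person_of[j]]]]
    w[t_cat[slot_of[j]]] * t_frac[slot_of[j]]
  }, numeric(1))
  food_id <- vapply(seq_len(n * k), function(j) {
    cc <- plan$name[t_cat[slot_of[j]]]
    pool <- if (t_cpl[slot_of[j]]) pool_c[[cc]] else pool_nc[[cc]]
    if (length(pool) == 1) pool else sample(pool, 1)
  }, character(1))
  portion <- base_share * exp(stats::rnorm(n * k, 0, config$amount_log_sd))
  raw_energy <- portion * dens[food_id]
  person_energy <- tapply(raw_energy, person_of, sum)
  scale <- 100 * target[person_of] /
    as.numeric(person_energy[as.character(person_of)])
  recalls <- tibble::tibble(person_id = pid[person_of],
                            food_id = food_id,
                            amount = portion * scale)

  truth <- list(
    expected_change_s3 = expected_change(config, scenario = 3),
    expected_change_s2 = expected_change(config, scenario = 2),
    planted_excluded = planted_excluded,
    food_compliance = planted,
    exempt_categories = exempt)

  structure(list(db = db, criteria = criteria, recalls = recalls,
                 participants = participants, truth = truth,
                 config = config),
            class = "fop_survey")
}

#' Closed-form expected percent change of population intake
#'
#' Analytic expectation of the population mean intake change between
#' scenario 1 and scenario 2 or 3, derived from the generator's planted
#' parameters: category consumption shares, the non-compliant share within
#' each category, and the planted per-kcal reduction fractions. Under
#' scenario 3, replaced entries conserve energy exactly, so a nutrient's
#' replaced portion scales by `1 - r` (its per-kcal reduction); in exempt
#' categories and under scenario 2 the consumed amount is kept, so the
#' portion scales by `(1 - r) * (1 - r_energy)` (the per-100 ratio).
#'
#' Within-category noise is symmetric on the log scale and the generator
#' holds every person's category composition at the population shares, so
#' the survey-weighted median change estimated by the pipeline tracks this
#' mean-based expectation to within Monte-Carlo tolerance.
#'
#' @param config An [generator_config()] object.
#' @param scenario 2 or 3.
#' @param categories Optional restriction: only these categories are
#'   replaced (as in a group-restricted analysis); `NULL` means all.
#' @return Named numeric vector of expected percent changes for
#'   [fop_intake_nutrients()].
#' @export
expected_change <- function(config, scenario = 3, categories = NULL) {
  stopifnot(inherits(config, "fop_generator_config"), scenario %in% c(2, 3))
  plan <- build_category_plan(config)
  exempt <- if (is.null(config$exempt_categories)) {
    default_exempt(plan)
  } else config$exempt_categories
  red <- config$reductions
  r_e <- red[["energy"]]
  nutrients <- fop_intake_nutrients()

  # entry-level category probabilities, mixed over locality
  lambda <- config$locality_probs / sum(config$locality_probs)
  pi_mix <- rep(0, nrow(plan))
  for (loc in names(lambda)) {
    mult <- config$locality_processed_multiplier[[loc]]
    w <- plan$weight
    w[plan$replaceable] <- w[plan$replaceable] * mult
    pi_mix <- pi_mix + lambda[[loc]] * w / sum(w)
  }

  f_entry <- ifelse(!plan$processed, 0,
                    ifelse(plan$replaceable, config$fraction_noncompliant, 1))

  # The nearest-energy-density candidate rule effectively selects the
  # highest-energy compliant food in a category (compliant energy anchors
  # sit well below the originals), so the expected replacement energy
  # density carries the expected maximum of k Gaussian log-noises. The
  # closed form accounts for that selection and for the log-normal
  # ratio-of-independent-noises terms.
  k_cpl <- pmin(pmax(plan$n_compliant, 1), 10)
  m_max <- c(0, 0.5642, 0.8463, 1.0294, 1.1630,
             1.2672, 1.3522, 1.4236, 1.4850, 1.5388)[k_cpl]
  v_max <- c(1, 0.6817, 0.5595, 0.4917, 0.4475,
             0.4159, 0.3919, 0.3729, 0.3574, 0.3443)[k_cpl]
  s2 <- config$noise_sd^2
  a <- config$energy_noise_sd
  sel_dn <- exp(s2 + a^2 * (1 + v_max) / 2 - a * m_max)
  sel_up <- exp(a^2 * (1 + v_max) / 2 + a * m_max)

  out <- stats::setNames(rep(0, length(nutrients)), nutrients)
  for (nu in nutrients) {
    r <- if (nu %in% names(red)) red[[nu]] else 0
    m_nc <- plan[[nu]]
    m_cpl <- if (nu == "energy") m_nc * (1 - r_e) else m_nc * (1 - r) * (1 - r_e)
    m1 <- f_entry * m_nc + (1 - f_entry) * m_cpl
    m1[!plan$processed] <- m_nc[!plan$processed]
    total <- sum(pi_mix * m1)
    if (total <= 0) { out[nu] <- 0; next }
    replaced_nutrient <- pi_mix * f_entry * m_nc * plan$replaceable
    if (!is.null(categories)) {
      replaced_nutrient[!plan$name %in% categories] <- 0
    }
    if (nu == "energy") {
      g2 <- (1 - r_e) * sel_up
      g3 <- rep(1, nrow(plan))
    } else {
      g2 <- (1 - r) * (1 - r_e) * exp(s2)
      g3 <- (1 - r) * sel_dn
    }
    g <- if (scenario == 2) g2 else ifelse(plan$name %in% exempt, g2, g3)
    out[nu] <- 100 * sum(replaced_nutrient * (g - 1)) / total
  }
  out
}
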