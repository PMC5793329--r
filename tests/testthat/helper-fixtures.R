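# Small in-code fixtures shared across the suite.

# A food tibble row with sensible defaults; override any field.
make_food <- function(food_id, category = "snacks", processed = TRUE,
                      basis = "per_100_g", serving_size = 30,
                      energy = 400, saturated_fat = 5, trans_fat = 0.2,
                      total_fat = 15, total_sugar = 20,
                      added_sugar = min(15, total_sugar),
                      sodium = 300, fiber = 2, name = food_id) {
  tibble::tibble(food_id = food_id, name = name, category = category,
                 processed = processed, basis = basis,
                 serving_size = serving_size, energy = energy,
                 saturated_fat = saturated_fat, trans_fat = trans_fat,
                 total_fat = total_fat, total_sugar = total_sugar,
                 added_sugar = added_sugar, sodium = sodium, fiber = fiber)
}

make_db <- function(...) {
  validate_food_db(dplyr::bind_rows(...))
}

# One-category criteria set with simple per-100 limits.
simple_criteria <- function(name = "test",
                            categories = "snacks",
                            eligible = TRUE,
                            sugar_limit = 10, sodium_limit = 400) {
  criteria_set(
    name,
    tibble::tibble(category = categories,
                   eligible = rep_len(eligible, length(categories))),
    dplyr::bind_rows(lapply(categories, function(cc) {
      tibble::tibble(category = cc,
                     nutrient = c("total_sugar", "sodium"),
                     cmp = "<=",
                     limit = c(sugar_limit, sodium_limit),
                     per = "per_100_basis")
    })))
}

# Independent brute-force classifier: re-derives every threshold from raw
# fields with plain loops, no shared code path with the package internals.
brute_force_classify <- function(db, criteria) {
  out <- list()
  for (i in seq_len(nrow(db))) {
    if (!db$processed[i]) next
    row <- db[i, ]
    cat_i <- match(row$category, criteria$categories$category)
    if (!criteria$categories$eligible[cat_i]) {
      out[[length(out) + 1]] <- data.frame(food_id = row$food_id,
                                           complies = FALSE)
      next
    }
    thr <- criteria$thresholds[criteria$thresholds$category == row$category, ]
    ok <- TRUE
    if (nrow(thr) > 0) for (j in seq_len(nrow(thr))) {
      v <- row[[thr$nutrient[j]]]
      obs <- NA_real_
      if (!is.na(v)) {
        if (thr$per[j] == "per_100_basis") obs <- v
        if (thr$per[j] == "per_serving" && !is.na(row$serving_size)) {
          obs <- v * row$serving_size / 100
        }
        if (thr$per[j] == "pct_of_energy" && !is.na(row$energy) &&
            row$energy > 0) {
          kc <- if (thr$nutrient[j] %in%
                      c("saturated_fat", "trans_fat", "total_fat")) 9 else 4
          obs <- 100 * kc * v / row$energy
        }
        if (thr$per[j] == "pct_of_total_fat" && !is.na(row$total_fat) &&
            row$total_fat > 0) {
          obs <- 100 * v / row$total_fat
        }
      }
      pass <- !is.na(obs) &&
        ((thr$cmp[j] == "<=" && obs <= thr$limit[j]) ||
           (thr$cmp[j] == ">=" && obs >= thr$limit[j]))
      if (!pass) ok <- FALSE
    }
    out[[length(out) + 1]] <- data.frame(food_id = row$food_id,
                                         complies = ok)
  }
  do.call(rbind, out)
}

# Independent brute-force weighted quantile: linear scan of the normalized
# cumulative weights of the sorted sample.
brute_force_wq <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cum <- cumsum(w) / sum(w)
  res <- numeric(length(p))
  for (j in seq_along(p)) {
    i <- 1
    while (cum[i] < p[j] - 1e-12) i <- i + 1
    if (i < length(x) && abs(cum[i] - p[j]) <= 1e-12) {
      res[j] <- (x[i] + x[i + 1]) / 2
    } else {
      res[j] <- x[i]
    }
  }
  res
}

# Random small food database for oracle-equivalence fuzzing.
random_db <- function(n_foods, n_categories = 3) {
  cats <- paste0("cat", seq_len(n_categories))
  rows <- lapply(seq_len(n_foods), function(i) {
    tf <- runif(1, 5, 40)
    sf <- runif(1, 0, tf * 0.8)
    trf <- runif(1, 0, tf - sf)
    ts <- runif(1, 0, 60)
    make_food(sprintf("R%03d", i),
              category = sample(cats, 1),
              processed = runif(1) < 0.8,
              serving_size = if (runif(1) < 0.2) NA_real_ else
                runif(1, 15, 60),
              energy = runif(1, 0, 600),
              saturated_fat = sf, trans_fat = trf, total_fat = tf,
              total_sugar = ts, added_sugar = runif(1, 0, ts),
              sodium = runif(1, 0, 1500), fiber = runif(1, 0, 8))
  })
  make_db(dplyr::bind_rows(rows))
}

random_criteria <- function(n_categories = 3) {
  cats <- paste0("cat", seq_len(n_categories))
  thr <- dplyr::bind_rows(lapply(cats, function(cc) {
    pick <- sample(c("per_100_basis", "per_serving", "pct_of_energy",
                     "pct_of_total_fat"), 2)
    nut <- vapply(pick, function(pp) {
      if (pp == "pct_of_energy") {
        sample(c("saturated_fat", "total_sugar", "added_sugar"), 1)
      } else if (pp == "pct_of_total_fat") {
        sample(c("saturated_fat", "trans_fat"), 1)
      } else {
        sample(c("energy", "saturated_fat", "total_sugar", "sodium"), 1)
      }
    }, character(1))
    tibble::tibble(category = cc, nutrient = unname(nut), cmp = "<=",
                   limit = runif(2, 1, 50), per = pick)
  }))
  thr <- thr[!duplicated(thr[, c("category", "nutrient", "per")]), ]
  criteria_set("fuzz",
               tibble::tibble(category = cats,
                              eligible = runif(n_categories) < 0.8),
               thr)
}

# Minimal participant table wrapper.
make_participants <- function(n, weight = 1, stratum = 1,
                              psu = seq_len(n), age = 35, bmi = 25,
                              sex = "female", pregnant = FALSE,
                              locality = "urban") {
  tibble::tibble(person_id = sprintf("p%03d", seq_len(n)),
                 weight = rep_len(weight, n),
                 stratum = rep_len(stratum, n),
                 psu = rep_len(psu, n),
                 sex = rep_len(sex, n), age = rep_len(age, n),
                 bmi = rep_len(bmi, n),
                 region = "center", locality = rep_len(locality, n),
                 ses = "middle",
                 pregnant_or_lactating = rep_len(pregnant, n))
}
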