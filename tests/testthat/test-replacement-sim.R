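# A category with one compliant low-sugar option and planted violators.
replacement_fixture <- function() {
  make_db(
    make_food("bar_nc", category = "bars", energy = 446.86,
              total_sugar = 40, added_sugar = 30),
    make_food("bar_ok", category = "bars", energy = 290.5,
              total_sugar = 5, added_sugar = 2),
    make_food("lonely_nc", category = "lonely", energy = 500,
              total_sugar = 50, added_sugar = 40),
    make_food("soda_nc", category = "ssb", basis = "per_100_mL",
              energy = 44, total_sugar = 11, added_sugar = 11,
              saturated_fat = 0, trans_fat = 0, total_fat = 0, fiber = 0,
              sodium = 10),
    make_food("water_ok", category = "ssb", basis = "per_100_mL",
              energy = 2, total_sugar = 0.4, added_sugar = 0,
              saturated_fat = 0, trans_fat = 0, total_fat = 0, fiber = 0,
              sodium = 5))
}

fixture_criteria <- function() {
  simple_criteria(categories = c("bars", "lonely", "ssb"),
                  sugar_limit = 8, sodium_limit = 2000)
}

test_that("replacement map picks nearest energy density and flags the rest", {
  db <- replacement_fixture()
  crit <- fixture_criteria()
  map <- build_replacement_map(db, crit)
  expect_setequal(map$food_id, c("bar_nc", "lonely_nc", "soda_nc"))
  expect_equal(map$replacement_id[map$food_id == "bar_nc"], "bar_ok")
  expect_equal(attr(map, "unreplaced"), "lonely_nc")
  expect_false(map$replaced[map$food_id == "lonely_nc"])
  # worked example: 446.86 / 290.5 = 1.54 to two decimals
  expect_equal(round(map$correction_factor[map$food_id == "bar_nc"], 2),
               1.54)
})

test_that("nearest-density choice matches brute force, ties lexicographic", {
  db <- make_db(
    make_food("orig", category = "c", energy = 446.86, total_sugar = 40),
    make_food("c290", category = "c", energy = 290, total_sugar = 5),
    make_food("c300", category = "c", energy = 300, total_sugar = 5),
    make_food("c460", category = "c", energy = 460, total_sugar = 5))
  crit <- simple_criteria(categories = "c", sugar_limit = 8)
  map <- build_replacement_map(db, crit)
  # brute force: |290-446.86|=156.86, |300-446.86|=146.86, |460-446.86|=13.14
  expect_equal(map$replacement_id[map$food_id == "orig"], "c460")

  tied <- make_db(
    make_food("orig", category = "c", energy = 400, total_sugar = 40),
    make_food("a_cand", category = "c", energy = 390, total_sugar = 5),
    make_food("b_cand", category = "c", energy = 410, total_sugar = 5))
  map2 <- build_replacement_map(tied, crit)
  expect_equal(map2$replacement_id[map2$food_id == "orig"], "a_cand")
})

test_that("scenario semantics: identity, swap, and energy-conserving swap", {
  db <- replacement_fixture()
  crit <- fixture_criteria()
  map <- build_replacement_map(db, crit)
  rec <- tibble::tibble(person_id = c("p1", "p1", "p2"),
                        food_id = c("bar_nc", "lonely_nc", "soda_nc"),
                        amount = c(100, 80, 600))

  s1 <- apply_scenario(rec, db, map, 1)
  expect_equal(s1[names(rec)], rec)

  s2 <- apply_scenario(rec, db, map, 2)
  expect_equal(s2$food_id, c("bar_ok", "lonely_nc", "water_ok"))
  expect_equal(s2$amount, rec$amount)

  s3 <- apply_scenario(rec, db, map, 3)
  # 100 g at 446.86 kcal -> 446.86/290.5 = 1.538 -> ~154 g of replacement
  expect_equal(round(s3$amount[1]), 154)
  e_orig <- 100 / 100 * 446.86
  e_new <- s3$amount[1] / 100 * 290.5
  expect_lt(abs(e_new - e_orig) / e_orig, 1e-9)
  # unreplaced passes through
  expect_equal(s3$food_id[2], "lonely_nc")
  expect_equal(s3$amount[2], 80)
})

test_that("identical energy density gives factor 1 and unchanged amount", {
  db <- make_db(
    make_food("nc", category = "c", energy = 300, total_sugar = 40),
    make_food("ok", category = "c", energy = 300, total_sugar = 5))
  map <- build_replacement_map(db, simple_criteria(categories = "c",
                                                   sugar_limit = 8))
  expect_equal(map$correction_factor[map$food_id == "nc"], 1)
  rec <- tibble::tibble(person_id = "p1", food_id = "nc", amount = 120)
  expect_equal(apply_scenario(rec, db, map, 3)$amount, 120)
})

test_that("exempt categories are replaced but never rescaled", {
  db <- replacement_fixture()
  map <- build_replacement_map(db, fixture_criteria())
  rec <- tibble::tibble(person_id = "p1", food_id = "soda_nc", amount = 600)
  s2 <- apply_scenario(rec, db, map, 2)
  s3 <- apply_scenario(rec, db, map, 3, exempt_categories = "ssb")
  expect_equal(s3$food_id, s2$food_id)
  expect_equal(s3$amount, s2$amount)
  # without the exemption the rescale would be enormous (44/2 = 22x)
  s3_free <- apply_scenario(rec, db, map, 3)
  expect_equal(s3_free$amount, 600 * 22)
})

test_that("zero-energy replacement falls back to factor 1 with a warning", {
  db <- make_db(
    make_food("nc", category = "c", energy = 300, total_sugar = 40),
    make_food("zero", category = "c", energy = 0, total_sugar = 0,
              added_sugar = 0))
  expect_warning(map <- build_replacement_map(
    db, simple_criteria(categories = "c", sugar_limit = 8)),
    "correction factor set to 1")
  expect_equal(map$correction_factor[map$food_id == "nc"], 1)
})

test_that("restricted replacement touches only the named categories", {
  db <- replacement_fixture()
  crit <- fixture_criteria()
  map <- build_replacement_map(db, crit)
  rec <- tibble::tibble(person_id = c("p1", "p1"),
                        food_id = c("bar_nc", "soda_nc"),
                        amount = c(100, 600))
  only_ssb <- run_restricted_replacement(rec, db, map, "ssb")
  expect_equal(only_ssb$food_id, c("bar_nc", "water_ok"))
  expect_equal(only_ssb$amount, rec$amount)

  none <- run_restricted_replacement(rec, db, map, character(0))
  expect_equal(none[names(rec)], rec)

  # restriction vacuous when it covers every non-compliant food consumed
  ssb_only_diet <- rec[2, ]
  full <- apply_scenario(ssb_only_diet, db, map, 2)
  restricted <- run_restricted_replacement(ssb_only_diet, db, map, "ssb")
  expect_equal(restricted, full)

  expect_error(run_restricted_replacement(rec, db, map, "no_such_cat"),
               "unknown category")
})

test_that("modified entries nest: restricted within unrestricted, s1 empty", {
  set.seed(31)
  sv <- generate_survey(generator_config(seed = 31, n_participants = 40))
  map <- build_replacement_map(sv$db, sv$criteria)
  cats <- unique(sv$db$category)
  sub <- sample(cats, 3)
  full <- apply_scenario(sv$recalls, sv$db, map, 2)
  restr <- apply_scenario(sv$recalls, sv$db, map, 2,
                          restrict_to_categories = sub)
  expect_true(all(which(restr$replaced_entry) %in%
                    which(full$replaced_entry)))
  s1 <- apply_scenario(sv$recalls, sv$db, map, 1)
  expect_false(any(s1$replaced_entry))
  # determinism: identical inputs, identical outputs
  expect_identical(full, apply_scenario(sv$recalls, sv$db, map, 2))
})

test_that("every introduced food re-classifies as compliant", {
  sv <- generate_survey(generator_config(seed = 5, n_participants = 60))
  map <- build_replacement_map(sv$db, sv$criteria)
  s2 <- apply_scenario(sv$recalls, sv$db, map, 2)
  introduced <- unique(s2$food_id[s2$replaced_entry])
  expect_gt(length(introduced), 0)
  for (fid in introduced) {
    cl <- classify_food(sv$db[sv$db$food_id == fid, ], sv$criteria)
    expect_true(cl$complies)
  }
})
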