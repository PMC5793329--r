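test_that("weighted quantile handles the canonical cases", {
  expect_equal(weighted_quantile(c(1, 2, 3), p = 0.5), 2)
  # dominant weight absorbs the median
  expect_equal(weighted_quantile(c(1, 100), c(99, 1), 0.5), 1)
  # exact cumulative hit averages the adjacent order statistics
  expect_equal(weighted_quantile(c(1, 2, 3, 4), p = 0.5), 2.5)
  expect_error(weighted_quantile(numeric(0), p = 0.5), "empty")
  expect_error(weighted_quantile(1:3, c(1, -1, 1), 0.5), "positive")
  expect_error(weighted_quantile(1:3, p = 1), "in \\(0, 1\\)")
})

test_that("weighted quantile matches brute-force cumulative-weight scan", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(3:25, 1)
    x <- rnorm(n) * 10
    w <- rexp(n) + 0.05
    p <- c(0.25, 0.5, 0.75)
    expect_equal(weighted_quantile(x, w, p), brute_force_wq(x, w, p))
  }
})

test_that("equal weights reproduce the standard type-2 sample quantile", {
  set.seed(12)
  for (rep in 1:10) {
    x <- rnorm(sample(4:40, 1))
    for (p in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
      expect_equal(weighted_quantile(x, p = p),
                   unname(quantile(x, p, type = 2)))
    }
  }
})

test_that("quantiles are monotone in p and scale-equivariant", {
  set.seed(13)
  x <- rlnorm(40); w <- rexp(40) + 0.1
  q <- weighted_quantile(x, w, c(0.25, 0.5, 0.75))
  expect_true(q[1] <= q[2] && q[2] <= q[3])
  expect_equal(weighted_quantile(3.7 * x, w, c(0.25, 0.5, 0.75)), 3.7 * q)
})

test_that("percent change reproduces published-style figures from medians", {
  # medians 1905 -> 1802 print as a 5.4% reduction
  expect_equal(round(percent_change(1905, 1802), 1), -5.4)
  # trans fat 0.25 -> 0.2 prints as -20%
  expect_equal(round(percent_change(0.25, 0.2), 1), -20)
  expect_equal(percent_change(123.4, 123.4), 0)
  expect_warning(out <- percent_change(0, 5), "undefined")
  expect_true(is.na(out))
  # invariant to common rescaling
  expect_equal(percent_change(22, 18), percent_change(2200, 1800))
})

test_that("null contrast gives near-zero coefficient and p near 1", {
  set.seed(21)
  n <- 60
  pp <- make_participants(n, weight = rexp(n) + 0.2,
                          stratum = rep(1:3, each = 20),
                          psu = rep(1:12, each = 5))
  intake <- tibble::tibble(person_id = pp$person_id,
                           total_sugar = rlnorm(n, 4, 0.4))
  res <- compare_scenarios(intake, intake, pp)
  expect_equal(res$estimate, 0, tolerance = 1e-12)
  expect_gt(res$p_value, 0.99)
})

test_that("a planted multiplicative effect is recovered on the log scale", {
  set.seed(22)
  n <- 500
  pp <- make_participants(n, weight = rexp(n) + 0.2,
                          stratum = rep(1:5, each = 100),
                          psu = rep(1:50, each = 10))
  ref <- tibble::tibble(person_id = pp$person_id,
                        total_sugar = rlnorm(n, 4.4, 0.5))
  alt <- ref
  alt$total_sugar <- ref$total_sugar * 0.6
  res <- compare_scenarios(ref, alt, pp)
  # the zero-protection offset slightly compresses the log scale, so the
  # coefficient sits near, not exactly at, log(0.6)
  expect_equal(res$estimate, log(0.6), tolerance = 0.1)
  expect_lt(res$p_value, 0.05)
})

test_that("cluster-robust p agrees with an independent matrix computation", {
  set.seed(23)
  n <- 20
  pp <- make_participants(n, weight = rexp(n) + 0.5,
                          stratum = 1, psu = rep(1:5, each = 4))
  ref <- tibble::tibble(person_id = pp$person_id,
                        energy = rlnorm(n, 7.5, 0.3))
  alt <- ref
  alt$energy <- ref$energy * exp(rnorm(n, -0.1, 0.05))
  res <- compare_scenarios(ref, alt, pp)

  # independent: textbook weighted OLS + CR0 sandwich, hand-built matrices
  delta <- min(c(ref$energy, alt$energy)[c(ref$energy, alt$energy) > 0]) / 2
  y <- log(c(ref$energy, alt$energy) + delta)
  X <- cbind(1, rep(c(0, 1), each = n))
  w <- rep(pp$weight, 2)
  cl <- rep(pp$psu, 2)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  resid <- as.numeric(y - X %*% beta)
  meat <- matrix(0, 2, 2)
  for (g in unique(cl)) {
    idx <- cl == g
    sg <- t(X[idx, , drop = FALSE]) %*% (w[idx] * resid[idx])
    meat <- meat + sg %*% t(sg)
  }
  G <- length(unique(cl)); N <- length(y)
  adj <- G / (G - 1) * (N - 1) / (N - 2)   # CR1 small-sample factor
  V <- solve(XtWX) %*% (adj * meat) %*% solve(XtWX)
  tstat <- beta[2] / sqrt(V[2, 2])
  p_ind <- 2 * pt(-abs(tstat), df = G - 1)

  expect_equal(res$estimate, beta[2], tolerance = 1e-8)
  expect_equal(res$p_value, p_ind, tolerance = 1e-6)
})

test_that("an all-zero nutrient yields NA with a warning", {
  pp <- make_participants(10)
  ref <- tibble::tibble(person_id = pp$person_id, trans_fat = rep(0, 10))
  alt <- ref
  expect_warning(res <- compare_scenarios(ref, alt, pp), "all-zero")
  expect_true(is.na(res$p_value))
})

test_that("scenario summaries respect ordering and reference invariants", {
  set.seed(25)
  sv <- generate_survey(generator_config(seed = 25, n_participants = 80))
  map <- build_replacement_map(sv$db, sv$criteria)
  i1 <- aggregate_intake(sv$recalls, sv$db,
                         persons = sv$participants$person_id)
  r2 <- apply_scenario(sv$recalls, sv$db, map, 2)
  i2 <- aggregate_intake(r2, sv$db, persons = sv$participants$person_id)
  s <- summarize_scenarios(list(scenario1 = i1, scenario2 = i2),
                           sv$participants)
  expect_true(all(s$p25 <= s$median & s$median <= s$p75))
  ref_rows <- s[s$scenario == "scenario1", ]
  expect_true(all(ref_rows$pct_change == 0))
  expect_true(all(is.na(ref_rows$p_value)))
})

test_that("group summaries depend only on each group's members", {
  set.seed(26)
  n <- 40
  pp <- make_participants(n, weight = rexp(n) + 0.2)
  pp$locality <- rep(c("rural", "urban"), each = n / 2)
  intake <- tibble::tibble(person_id = pp$person_id,
                           energy = rlnorm(n, 7.5, 0.4))
  g <- summarize_by_group(intake, pp, "locality")
  # permute the OTHER group's values: rural summary unchanged
  intake2 <- intake
  urb <- pp$person_id[pp$locality == "urban"]
  intake2$energy[match(urb, intake2$person_id)] <-
    sample(intake2$energy[match(urb, intake2$person_id)])
  g2 <- summarize_by_group(intake2, pp, "locality")
  expect_equal(g[g$level == "rural", ], g2[g2$level == "rural", ])
  expect_equal(summarize_by_group(intake, pp, "none")$level, "national")
})

test_that("an effect planted only in urban areas shows up only there", {
  cfg <- generator_config(seed = 33, n_participants = 600,
                          locality_processed_multiplier =
                            c(rural = 0.15, urban = 1))
  sv <- generate_survey(cfg)
  map <- build_replacement_map(sv$db, sv$criteria)
  i1 <- aggregate_intake(sv$recalls, sv$db,
                         persons = sv$participants$person_id)
  r3 <- apply_scenario(sv$recalls, sv$db, map, 3,
                       exempt_categories = sv$truth$exempt_categories)
  i3 <- aggregate_intake(r3, sv$db, persons = sv$participants$person_id)
  s <- summarize_scenarios(list(scenario1 = i1, scenario3 = i3),
                           sv$participants, by = "locality")
  sugar <- s[s$scenario == "scenario3" & s$nutrient == "total_sugar", ]
  expect_lt(sugar$pct_change[sugar$level == "urban"],
            sugar$pct_change[sugar$level == "rural"])
})

test_that("null rejection rate is near nominal over many small surveys", {
  set.seed(77)
  n <- 120
  reps <- 400
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    pp <- make_participants(n, weight = rexp(n) + 0.2,
                            stratum = rep(1:4, each = 30),
                            psu = rep(1:24, each = 5))
    base <- rlnorm(n, 5, 0.4)
    ref <- tibble::tibble(person_id = pp$person_id,
                          energy = base * exp(rnorm(n, 0, 0.15)))
    alt <- tibble::tibble(person_id = pp$person_id,
                          energy = base * exp(rnorm(n, 0, 0.15)))
    rej[r] <- compare_scenarios(ref, alt, pp)$p_value < 0.05
  }
  rate <- mean(rej)
  # binomial 99.9% band around 0.05 at 400 reps
  expect_gt(rate, 0.05 - 3.29 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rate, 0.05 + 3.29 * sqrt(0.05 * 0.95 / reps))
})
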