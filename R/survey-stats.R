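#' Survey-weighted quantile
#'
#' Left-continuous cumulative-weight definition: sort the values, accumulate
#' normalized weights, and return the smallest value whose cumulative weight
#' reaches `p`. When the cumulative weight hits `p` exactly at an order
#' statistic (so the inverse CDF is flat there), the midpoint of that value
#' and the next is returned. With equal weights this reproduces R's
#' `quantile(type = 2)` for every `p`; a point carrying dominant weight
#' absorbs the quantile, as it should for expansion-weighted survey data.
#'
#' @param x Numeric values (finite).
#' @param w Positive weights, recycled if scalar.
#' @param p Probabilities in (0, 1); vectorized.
#' @return Numeric vector, one quantile per element of `p`.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), p) {
  if (length(w) == 1) w <- rep(w, length(x))
  if (length(x) == 0) stop("empty input to weighted_quantile", call. = FALSE)
  if (length(w) != length(x)) stop("length(w) != length(x)", call. = FALSE)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  if (any(!is.finite(w) | w <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  n <- length(x)
  vapply(p, function(pp) {
    i <- which(cw >= pp - 1e-12)[1]
    if (i < n && abs(cw[i] - pp) <= 1e-12) (x[i] + x[i + 1]) / 2 else x[i]
  }, numeric(1))
}

#' Percent change between two summary values
#'
#' `100 * (after - before) / before`. Undefined when `before` is zero; such
#' elements are reported as `NA` with a warning.
#'
#' @param before,after Numeric vectors (recycled).
#' @return Numeric vector of percent changes.
#' @export
percent_change <- function(before, after) {
  out <- 100 * (after - before) / before
  zero <- !is.na(before) & before == 0
  if (any(zero)) {
    warning("percent change undefined for zero baseline; reported as NA",
            call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Offset for log-transforming intake with zeros
#'
#' Half the smallest positive observed value, the conventional small offset
#' for log-transforming skewed intake data that contains exact zeros (e.g.
#' trans fat on days without processed fat sources).
#'
#' @param x Numeric values (both scenarios pooled).
#' @return A single non-negative number (0 when no positive value exists).
#' @export
log_offset <- function(x) {
  pos <- x[!is.na(x) & x > 0]
  if (length(pos) == 0) return(0)
  min(pos) / 2
}

#' Contrast two scenarios by weighted log-linear regression
#'
#' For each nutrient, stacks the reference and alternative person-level
#' intakes, fits a weighted linear model of `log(intake + offset)` on a
#' scenario indicator (survey expansion weights as regression weights), and
#' estimates the indicator's variance with a cluster-robust sandwich at the
#' PSU-within-stratum level. Because each person appears in both scenarios
#' and persons nest in PSUs, the clustering also absorbs the within-person
#' pairing. The p-value is two-sided on a t reference with
#' (number of clusters - 1) degrees of freedom.
#'
#' @param intakes_ref,intakes_alt Intake tibbles from [aggregate_intake()]
#'   covering the same persons.
#' @param design Tibble with `person_id`, `weight`, `stratum`, `psu`.
#' @param nutrients Nutrients to contrast; defaults to the shared intake
#'   columns.
#' @return Tibble: nutrient, estimate (indicator coefficient on the log
#'   scale), se, p_value, offset. A nutrient with all-zero intake in either
#'   scenario gets `NA` with a warning.
#' @export
compare_scenarios <- function(intakes_ref, intakes_alt, design,
                              nutrients = NULL) {
  if (is.null(nutrients)) {
    nutrients <- setdiff(intersect(names(intakes_ref), names(intakes_alt)),
                         "person_id")
  }
  if (!setequal(intakes_ref$person_id, intakes_alt$person_id)) {
    stop("the two intake collections must cover the same persons",
         call. = FALSE)
  }
  missing_design <- setdiff(intakes_ref$person_id, design$person_id)
  if (length(missing_design) > 0) {
    stop("design does not cover person(s): ",
         paste(utils::head(missing_design, 10), collapse = ", "),
         call. = FALSE)
  }
  ids <- intakes_ref$person_id
  alt <- intakes_alt[match(ids, intakes_alt$person_id), , drop = FALSE]
  drow <- design[match(ids, design$person_id), , drop = FALSE]
  cluster <- interaction(drow$stratum, drow$psu, drop = TRUE)
  res <- lapply(nutrients, function(nu) {
    x_ref <- intakes_ref[[nu]]
    x_alt <- alt[[nu]]
    if (all(x_ref == 0) || all(x_alt == 0)) {
      warning("nutrient '", nu, "' is all-zero in one scenario; ",
              "contrast reported as NA", call. = FALSE)
      return(tibble::tibble(nutrient = nu, estimate = NA_real_,
                            se = NA_real_, p_value = NA_real_,
                            offset = NA_real_))
    }
    delta <- log_offset(c(x_ref, x_alt))
    if (isTRUE(all.equal(x_ref, x_alt, tolerance = 1e-12))) {
      # the contrast of identical intakes is exactly null; the sandwich
      # t-ratio would be 0/0 numerical noise
      return(tibble::tibble(nutrient = nu, estimate = 0, se = 0,
                            p_value = 1, offset = delta))
    }
    dat <- data.frame(
      y = log(c(x_ref, x_alt) + delta),
      scen = rep(c(0, 1), each = length(ids)),
      w = rep(drow$weight, 2),
      cl = rep(cluster, 2))
    fit <- stats::lm(y ~ scen, data = dat, weights = w)
    vc <- sandwich::vcovCL(fit, cluster = dat$cl)
    ct <- lmtest::coeftest(fit, vcov. = vc, df = nlevels(cluster) - 1)
    tibble::tibble(nutrient = nu, estimate = unname(ct["scen", "Estimate"]),
                   se = unname(ct["scen", "Std. Error"]),
                   p_value = unname(ct["scen", "Pr(>|t|)"]),
                   offset = delta)
  })
  dplyr::bind_rows(res)
}

#' Weighted median and interquartile range per nutrient
#'
#' @param intakes Intake tibble from [aggregate_intake()].
#' @param design Tibble with `person_id` and `weight` (extra columns
#'   ignored).
#' @param nutrients Nutrients to summarize.
#' @return Tibble: nutrient, median, p25, p75 (survey-weighted).
#' @export
intake_quantiles <- function(intakes, design,
                             nutrients = setdiff(names(intakes),
                                                 "person_id")) {
  w <- design$weight[match(intakes$person_id, design$person_id)]
  if (anyNA(w)) stop("design does not cover all persons", call. = FALSE)
  rows <- lapply(nutrients, function(nu) {
    q <- weighted_quantile(intakes[[nu]], w, p = c(0.25, 0.5, 0.75))
    tibble::tibble(nutrient = nu, median = q[2], p25 = q[1], p75 = q[3])
  })
  dplyr::bind_rows(rows)
}

#' Summarize intake scenarios with weighted medians and contrasts
#'
#' Produces the standard scenario-comparison table: per scenario and nutrient
#' the survey-weighted median and p25-p75, the percent change of the median
#' against the reference scenario (computed at full precision, before any
#' rounding), and the cluster-robust contrast p-value from
#' [compare_scenarios()]. With `by`, every statistic is computed within each
#' level of a participant grouping variable using only that level's members;
#' empty levels are omitted with a warning.
#'
#' @param scenarios Named list of intake tibbles (e.g.
#'   `list(scenario1 = ..., scenario2 = ..., scenario3 = ...)`), all covering
#'   the same persons.
#' @param design Participant tibble with `person_id`, `weight`, `stratum`,
#'   `psu` and any grouping variables.
#' @param reference Name of the reference scenario (default: the first).
#' @param nutrients Nutrients to summarize.
#' @param by Optional grouping variable name present in `design` (`sex`,
#'   `region`, `locality`, `ses`, an age-band or BMI-class column, ...), or
#'   `NULL` for one national summary.
#' @return Tibble: group, level, scenario, nutrient, median, p25, p75,
#'   pct_change, p_value. For the reference scenario `pct_change` is 0 and
#'   `p_value` is `NA`.
#' @export
summarize_scenarios <- function(scenarios, design,
                                reference = names(scenarios)[1],
                                nutrients = NULL, by = NULL) {
  stopifnot(is.list(scenarios), length(scenarios) >= 1,
            !is.null(names(scenarios)), reference %in% names(scenarios))
  if (is.null(nutrients)) {
    nutrients <- setdiff(names(scenarios[[1]]), "person_id")
  }
  if (is.null(by)) {
    levels_tbl <- tibble::tibble(level = "national")
    member_ids <- list(national = design$person_id)
  } else {
    if (!by %in% names(design)) {
      stop("grouping variable '", by, "' not found in design", call. = FALSE)
    }
    lv <- sort(unique(as.character(design[[by]])))
    member_ids <- lapply(lv, function(l) {
      design$person_id[as.character(design[[by]]) == l]
    })
    names(member_ids) <- lv
    empty <- lv[vapply(member_ids, length, integer(1)) == 0]
    if (length(empty) > 0) {
      warning("empty group level(s) omitted: ",
              paste(empty, collapse = ", "), call. = FALSE)
      member_ids <- member_ids[setdiff(lv, empty)]
    }
    levels_tbl <- tibble::tibble(level = names(member_ids))
  }
  out <- list()
  for (lev in levels_tbl$level) {
    ids <- member_ids[[lev]]
    dsub <- design[design$person_id %in% ids, , drop = FALSE]
    ref_int <- scenarios[[reference]]
    ref_sub <- ref_int[ref_int$person_id %in% ids, , drop = FALSE]
    ref_q <- intake_quantiles(ref_sub, dsub, nutrients)
    for (scn in names(scenarios)) {
      sint <- scenarios[[scn]]
      ssub <- sint[sint$person_id %in% ids, , drop = FALSE]
      q <- intake_quantiles(ssub, dsub, nutrients)
      if (scn == reference) {
        pc <- rep(0, nrow(q))
        pv <- rep(NA_real_, nrow(q))
      } else {
        pc <- percent_change(ref_q$median, q$median)
        contrast <- compare_scenarios(ref_sub, ssub, dsub, nutrients)
        pv <- contrast$p_value[match(q$nutrient, contrast$nutrient)]
      }
      out[[length(out) + 1]] <- tibble::tibble(
        group = if (is.null(by)) "none" else by,
        level = lev, scenario = scn, nutrient = q$nutrient,
        median = q$median, p25 = q$p25, p75 = q$p75,
        pct_change = pc, p_value = pv)
    }
  }
  dplyr::bind_rows(out)
}

#' Weighted medians and IQRs by participant group
#'
#' Group-level descriptive summary of a single intake table: within each
#' level of `grouping`, the weighted median and p25-p75 per nutrient.
#'
#' @param intakes Intake tibble.
#' @param design Participant tibble including the grouping variable.
#' @param grouping Grouping variable name, or `"none"` for a single national
#'   row set.
#' @param nutrients Nutrients to summarize.
#' @return Tibble: group, level, nutrient, median, p25, p75.
#' @export
summarize_by_group <- function(intakes, design, grouping = "none",
                               nutrients = setdiff(names(intakes),
                                                   "person_id")) {
  by <- if (identical(grouping, "none")) NULL else grouping
  res <- summarize_scenarios(list(intake = intakes), design,
                             reference = "intake", nutrients = nutrients,
                             by = by)
  res[, c("group", "level", "nutrient", "median", "p25", "p75")]
}
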