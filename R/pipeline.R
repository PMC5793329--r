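#' Run the full food-replacement pipeline
#'
#' Ties the stages together the way the analysis is meant to be run: load (or
#' accept in-memory) food composition, recall, and participant tables; apply
#' the participant exclusion filters; classify the food database under each
#' criteria set; build the replacement map; simulate scenarios 1-3; and
#' summarize survey-weighted medians, percent changes, and contrasts. All
#' outputs are written to `out_dir`:
#'
#' * `exclusion_audit.json` — per-reason exclusion counts,
#' * `classification_<criteria>.csv` and `replacement_map_<criteria>.csv`,
#' * `intake_summary_<criteria>.csv` — the scenario x nutrient median
#'   (p25-p75) table,
#' * `percent_change_<criteria>.csv` and `percent_change_<criteria>.png` —
#'   scenario-3 percent change per nutrient with significance flag,
#' * `criteria_comparison.csv` when two or more criteria sets are given,
#' * `run.log` — stage-by-stage record counts and warnings.
#'
#' A consistency check re-derives every percent change in the figure file
#' from the medians table and stops if they disagree.
#'
#' @param config List with elements: `food_db`, `recalls`, `participants`
#'   (each a path or an already-loaded tibble), `criteria` (named list of
#'   paths or `fop_criteria` objects), `out_dir`, and optionally
#'   `exempt_categories` (default none), `restrict_to_categories`,
#'   `grouping` (participant column for an additional grouped summary),
#'   and `exclusions = FALSE` to skip the participant filters.
#' @return Invisibly, a list with per-criteria results (`classification`,
#'   `map`, `scenarios` intake tibbles, `summary` tibble), the exclusion
#'   `audit`, and the `comparison` tibble (or `NULL`).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir),
            !is.null(config$criteria), length(config$criteria) >= 1,
            !is.null(names(config$criteria)))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
  }

  db <- if (is.character(config$food_db)) {
    load_food_db(config$food_db)
  } else validate_food_db(config$food_db)
  logf("food_db: ", nrow(db), " foods (", sum(db$processed), " processed)")

  participants <- if (is.character(config$participants)) {
    load_participants(config$participants)
  } else tibble::as_tibble(config$participants)
  recalls <- if (is.character(config$recalls)) {
    load_recalls(config$recalls, db)
  } else validate_recalls(tibble::as_tibble(config$recalls), db)
  logf("recalls: ", nrow(recalls), " entries, ",
       length(unique(recalls$person_id)), " persons; participants: ",
       nrow(participants))

  intake1 <- aggregate_intake(recalls, db, persons = participants$person_id)
  if (isFALSE(config$exclusions)) {
    retained <- participants
    audit <- list(initial_n = nrow(participants), final_n = nrow(participants))
  } else {
    excl <- apply_exclusions(participants, intake1)
    retained <- excl$retained
    audit <- excl$audit
  }
  jsonlite::write_json(audit, file.path(config$out_dir,
                                        "exclusion_audit.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("exclusions: ", audit$initial_n, " -> ", audit$final_n)
  recalls <- recalls[recalls$person_id %in% retained$person_id, ,
                     drop = FALSE]

  exempt <- if (is.null(config$exempt_categories)) {
    character()
  } else config$exempt_categories
  restrict <- config$restrict_to_categories

  results <- list()
  for (crit_name in names(config$criteria)) {
    cr <- config$criteria[[crit_name]]
    criteria <- if (is.character(cr)) load_criteria(cr) else cr
    stopifnot(inherits(criteria, "fop_criteria"))
    cls <- classify_database(db, criteria)
    readr::write_csv(cls$foods, file.path(
      config$out_dir, paste0("classification_", crit_name, ".csv")))
    logf("criteria ", crit_name, ": ", cls$summary$n_noncompliant, "/",
         cls$summary$n_processed, " processed foods non-compliant, ",
         cls$summary$n_replaceable, " replaceable")
    map <- build_replacement_map(db, criteria)
    write_replacement_map(map, file.path(
      config$out_dir, paste0("replacement_map_", crit_name, ".csv")))

    scen <- list()
    for (s in 1:3) {
      rec_s <- apply_scenario(recalls, db, map, scenario = s,
                              exempt_categories = exempt,
                              restrict_to_categories = restrict)
      scen[[paste0("scenario", s)]] <- aggregate_intake(
        rec_s, db, persons = retained$person_id)
    }
    summary_tbl <- summarize_scenarios(scen, retained,
                                       reference = "scenario1")
    if (!is.null(config$grouping)) {
      grouped <- summarize_scenarios(scen, retained,
                                     reference = "scenario1",
                                     by = config$grouping)
      summary_tbl <- dplyr::bind_rows(summary_tbl, grouped)
    }
    write_scenario_table(summary_tbl, file.path(
      config$out_dir, paste0("intake_summary_", crit_name, ".csv")))

    pc <- summary_tbl[summary_tbl$scenario == "scenario3" &
                        summary_tbl$level == "national", ,
                      drop = FALSE]
    pc_tbl <- tibble::tibble(nutrient = pc$nutrient,
                             pct_change = pc$pct_change,
                             significant = !is.na(pc$p_value) &
                               pc$p_value < 0.05)
    readr::write_csv(pc_tbl, file.path(
      config$out_dir, paste0("percent_change_", crit_name, ".csv")))
    check_percent_change_consistency(summary_tbl, pc_tbl)
    plot_percent_change(pc_tbl, file.path(
      config$out_dir, paste0("percent_change_", crit_name, ".png")),
      title = paste0("Scenario 3 vs observed intake (", crit_name, ")"))
    results[[crit_name]] <- list(criteria = criteria, classification = cls,
                                 map = map, scenarios = scen,
                                 summary = summary_tbl)
  }

  comparison <- NULL
  if (length(results) >= 2) {
    nm <- names(results)
    comparison <- compare_criteria(
      results[[nm[1]]]$scenarios$scenario3,
      results[[nm[2]]]$scenarios$scenario3,
      retained, labels = nm[1:2])
    readr::write_csv(comparison,
                     file.path(config$out_dir, "criteria_comparison.csv"))
    logf("criteria comparison written: ", nm[1], " vs ", nm[2])
  }
  logf("done")
  invisible(list(results = results, audit = audit, retained = retained,
                 comparison = comparison))
}

# Every percent change in the figure file must be recomputable from the
# medians table at full precision.
check_percent_change_consistency <- function(summary_tbl, pc_tbl,
                                             tol = 1e-8) {
  nat <- summary_tbl[summary_tbl$level == "national", , drop = FALSE]
  ref <- nat[nat$scenario == "scenario1", , drop = FALSE]
  s3 <- nat[nat$scenario == "scenario3", , drop = FALSE]
  for (i in seq_len(nrow(pc_tbl))) {
    nu <- pc_tbl$nutrient[i]
    before <- ref$median[ref$nutrient == nu]
    after <- s3$median[s3$nutrient == nu]
    expected <- 100 * (after - before) / before
    if (!isTRUE(all.equal(expected, pc_tbl$pct_change[i],
                          tolerance = tol))) {
      stop("internal consistency check failed: percent change for '", nu,
           "' does not reproduce from the medians table", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Bar chart of scenario percent changes
#'
#' @param pc_tbl Tibble with `nutrient`, `pct_change`, `significant`.
#' @param path Output PNG path (written with `ggplot2::ggsave`).
#' @param title Plot title.
#' @return The ggplot object, invisibly.
#' @export
plot_percent_change <- function(pc_tbl, path = NULL,
                                title = "Percent change in median intake") {
  p <- ggplot2::ggplot(pc_tbl, ggplot2::aes(
    x = stats::reorder(.data$nutrient, .data$pct_change),
    y = .data$pct_change, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2b2b2"),
                               name = "p < 0.05") +
    ggplot2::labs(x = NULL, y = "% change of weighted median",
                  title = title) +
    ggplot2::theme_minimal(base_size = 11)
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 3.5, dpi = 150)
  }
  invisible(p)
}

#' Contrast scenario-3 intake between two criteria sets
#'
#' Per-nutrient difference between the scenario-3 diets simulated under two
#' criteria sets on the same retained persons: percent difference of the
#' survey-weighted medians (B relative to A) and the cluster-robust p-value
#' from the same weighted log-linear contrast machinery used between
#' scenarios.
#'
#' @param intakes_a,intakes_b Scenario-3 intake tibbles under criteria A
#'   and B, covering identical persons.
#' @param design Participant tibble (`person_id`, `weight`, `stratum`,
#'   `psu`).
#' @param labels Length-2 character vector naming the two criteria sets.
#' @return Tibble: nutrient, median_a, median_b, pct_difference (B vs A),
#'   p_value.
#' @export
compare_criteria <- function(intakes_a, intakes_b, design,
                             labels = c("A", "B")) {
  if (!setequal(intakes_a$person_id, intakes_b$person_id)) {
    stop("criteria comparison requires identical person sets", call. = FALSE)
  }
  nutrients <- setdiff(intersect(names(intakes_a), names(intakes_b)),
                       "person_id")
  qa <- intake_quantiles(intakes_a, design, nutrients)
  qb <- intake_quantiles(intakes_b, design, nutrients)
  contrast <- compare_scenarios(intakes_a, intakes_b, design, nutrients)
  tibble::tibble(
    nutrient = nutrients,
    criteria_a = labels[1], criteria_b = labels[2],
    median_a = qa$median[match(nutrients, qa$nutrient)],
    median_b = qb$median[match(nutrients, qb$nutrient)],
    pct_difference = percent_change(
      qa$median[match(nutrients, qa$nutrient)],
      qb$median[match(nutrients, qb$nutrient)]),
    p_value = contrast$p_value[match(nutrients, contrast$nutrient)])
}

#' Write a ready-to-run synthetic fixture directory
#'
#' Emits the CSV/YAML files the pipeline reads (food database, recalls,
#' participants, criteria config) from a generated survey, so the
#' file-based entry points can be exercised end to end.
#'
#' @param survey An `fop_survey` from [generate_survey()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey_fixture <- function(survey, dir) {
  stopifnot(inherits(survey, "fop_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inv <- fop_food_db_columns()
  db_out <- tibble::as_tibble(survey$db)
  names(db_out) <- names(inv)[match(names(db_out), unname(inv))]
  readr::write_csv(db_out, file.path(dir, "food_db.csv"))
  readr::write_csv(survey$recalls, file.path(dir, "recalls.csv"))
  readr::write_csv(survey$participants, file.path(dir, "participants.csv"))
  cr <- survey$criteria
  cfg <- list(name = cr$name, categories = lapply(
    seq_len(nrow(cr$categories)), function(i) {
      cat_name <- cr$categories$category[i]
      thr <- cr$thresholds[cr$thresholds$category == cat_name, ,
                           drop = FALSE]
      list(category = cat_name, eligible = cr$categories$eligible[i],
           thresholds = lapply(seq_len(nrow(thr)), function(j) {
             list(nutrient = thr$nutrient[j], cmp = thr$cmp[j],
                  limit = thr$limit[j], per = thr$per[j])
           }))
    }))
  yaml::write_yaml(cfg, file.path(dir, "criteria.yaml"))
  invisible(dir)
}
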