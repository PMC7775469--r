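#' Named exclusion cascade
#'
#' Applies the analysis' user filters in a fixed, logged order:
#' `drop_single_recording` removes users with only one EMA recording,
#' `drop_right_censored` removes users whose first entry lies within one
#' horizon of the export end, `drop_missing_age` removes users with a missing
#' age or age at onset. Each step's before/after user counts are returned so
#' downstream tables can cite the cascade.
#'
#' @param cohort An [ema_cohort()].
#' @param horizon A [horizon_config()].
#' @param drop_single_recording,drop_right_censored,drop_missing_age Logical
#'   switches for the individual filters.
#' @return A list with the filtered `cohort` and a `log` tibble
#'   (`step`, `n_before`, `n_after`, `n_dropped`).
#' @export
apply_exclusions <- function(cohort, horizon = horizon_config(),
                             drop_single_recording = FALSE,
                             drop_right_censored = FALSE,
                             drop_missing_age = FALSE) {
  stopifnot(inherits(cohort, "ema_cohort"))
  horizon <- as_horizon(horizon)
  log <- list()
  keep_users <- function(cohort, users, step) {
    n_before <- length(unique(cohort$recordings$user_id))
    rec <- cohort$recordings |> filter(.data$user_id %in% users)
    reg <- cohort$registrations |> filter(.data$user_id %in% users)
    out <- ema_cohort(rec, reg, cohort$export_end)
    log[[length(log) + 1L]] <<- tibble(
      step = step, n_before = n_before,
      n_after = length(unique(out$recordings$user_id))
    )
    out
  }
  if (drop_single_recording) {
    counts <- count(cohort$recordings, .data$user_id)
    cohort <- keep_users(cohort, counts$user_id[counts$n > 1],
                         "drop_single_recording")
  }
  if (drop_right_censored) {
    censored <- validate_cohort(cohort, horizon)$right_censored
    users <- setdiff(unique(cohort$recordings$user_id), censored)
    cohort <- keep_users(cohort, users, "drop_right_censored")
  }
  if (drop_missing_age) {
    reg <- cohort$registrations
    ok <- reg$user_id[!is.na(reg$ageAtRegistration) & !is.na(reg$ageAtOnset)]
    cohort <- keep_users(cohort, intersect(unique(cohort$recordings$user_id),
                                           ok), "drop_missing_age")
  }
  log <- if (length(log) > 0) bind_rows(log) else {
    tibble(step = character(), n_before = integer(), n_after = integer())
  }
  log$n_dropped <- log$n_before - log$n_after
  list(cohort = cohort, log = log)
}

#' Adherence report: profiles, histograms, stratum summary
#'
#' Runs the duration/continuity analysis end to end and writes
#' `profiles.csv`, `duration_histogram.csv`, `duration_histogram_cumulative.csv`
#' and `strata_summary.csv` into `out_dir`. Deterministic: rerunning on the
#' same cohort reproduces identical files.
#'
#' @param cohort An [ema_cohort()] with at least one recording.
#' @param horizon A [horizon_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with `profiles`, `histogram`,
#'   `histogram_cumulative`, `strata_summary`.
#' @export
run_adherence <- function(cohort, horizon = horizon_config(),
                          out_dir = NULL) {
  stopifnot(inherits(cohort, "ema_cohort"))
  horizon <- as_horizon(horizon)
  if (nrow(cohort$recordings) == 0) abort("cohort has no recordings")
  profiles <- adherence_profiles(cohort$recordings, horizon)
  daily <- daily_series(cohort$recordings, horizon)
  strata <- build_strata(daily, horizon)
  out <- list(
    profiles = profiles,
    histogram = duration_histogram(profiles, FALSE, horizon),
    histogram_cumulative = duration_histogram(profiles, TRUE, horizon),
    strata_summary = strata_summary(strata, horizon)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out$profiles, file.path(out_dir, "profiles.csv"))
    readr::write_csv(out$histogram, file.path(out_dir, "duration_histogram.csv"))
    readr::write_csv(out$histogram_cumulative,
                     file.path(out_dir, "duration_histogram_cumulative.csv"))
    readr::write_csv(out$strata_summary,
                     file.path(out_dir, "strata_summary.csv"))
  }
  invisible(out)
}

#' Return-after-break classification report
#'
#' Applies the single-recording exclusion, builds the per-item strata, runs
#' the evaluation grid and writes `grid_long.csv`, the algorithm-by-stratum
#' `grid_table.csv` and a `skips.json` log of skipped combinations.
#'
#' @param cohort An [ema_cohort()].
#' @param horizon A [horizon_config()].
#' @param algorithms Algorithm list for [run_grid()].
#' @param split A [split_config()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @return Invisibly, the `ema_grid`.
#' @export
run_classify <- function(cohort, horizon = horizon_config(),
                         algorithms = default_algorithms(),
                         split = split_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "ema_cohort"))
  horizon <- as_horizon(horizon)
  excl <- apply_exclusions(cohort, horizon, drop_single_recording = TRUE)
  daily <- daily_series(excl$cohort$recordings, horizon)
  strata <- build_strata(daily, horizon)
  grid <- run_grid(strata, algorithms, split, horizon)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(as_tibble(grid), file.path(out_dir, "grid_long.csv"))
    readr::write_csv(grid_table(grid), file.path(out_dir, "grid_table.csv"))
    skips <- grid |>
      as_tibble() |>
      filter(!is.na(.data$skip_reason)) |>
      select("algorithm", "item", "k", "skip_reason")
    jsonlite::write_json(skips, file.path(out_dir, "skips.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(grid)
}

#' Registration-rule mining report
#'
#' Two mining runs over the complete-case registration features: one on the
#' MiniTF items alone, one on the TSCHQ subset joined with the horizon-free
#' `NumDays` column. Users excluded by the right-censoring and missing-age
#' filters are removed first. Writes `rules_minitf.csv` and
#' `rules_tschq_numdays.csv`.
#'
#' @param cohort An [ema_cohort()].
#' @param horizon A [horizon_config()].
#' @param config A [mining_config()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @return Invisibly, a list with `minitf` and `tschq_numdays` rule tibbles
#'   and the exclusion `log`.
#' @export
run_rules <- function(cohort, horizon = horizon_config(),
                      config = mining_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "ema_cohort"))
  horizon <- as_horizon(horizon)
  excl <- apply_exclusions(cohort, horizon, drop_right_censored = TRUE)
  profiles <- adherence_profiles(excl$cohort$recordings, horizon)
  labels_tbl <- profiles |> select("user_id", "return")

  reg <- excl$cohort$registrations |>
    filter(.data$user_id %in% labels_tbl$user_id)

  mine <- function(feats) {
    joined <- inner_join(feats, labels_tbl, by = "user_id")
    hotspot_induce(
      joined |> select(-"return"), joined$return, config
    )
  }
  minitf_rules <- mine(registration_features(reg, "minitf"))
  excl_age <- apply_exclusions(excl$cohort, horizon, drop_missing_age = TRUE)
  reg_age <- excl_age$cohort$registrations |>
    filter(.data$user_id %in% labels_tbl$user_id)
  tschq_rules <- mine(registration_features(
    reg_age, "tschq",
    numdays = numdays_features(profiles)
  ))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(render_rules(minitf_rules),
                     file.path(out_dir, "rules_minitf.csv"))
    readr::write_csv(render_rules(tschq_rules),
                     file.path(out_dir, "rules_tschq_numdays.csv"))
  }
  invisible(list(
    minitf = minitf_rules, tschq_numdays = tschq_rules,
    log = bind_rows(excl$log, excl_age$log)
  ))
}
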