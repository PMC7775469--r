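#' Read configuration for long-format EMA tables
#'
#' Describes how the columns of a CSV export map onto the canonical recording
#' table. Values of the dichotomous item `q1` may arrive as labels (e.g. `Y`
#' and `N`) and are translated through `q1_map`; the VAS items `q2`--`q7` are
#' rescaled from `vas_scale` to `[0, 1]` at read time, so platform-specific
#' slider ranges (0--100 sliders, mis-scaled clients) can be normalised on
#' input.
#'
#' @param user_id,timestamp Column names holding the user identifier and the
#'   ISO-8601 timestamp.
#' @param items Named character vector mapping canonical item names
#'   (`q1`..`q7`) to column names in the file. Items absent from the file may
#'   be dropped from this map.
#' @param q1_map Optional named vector translating raw `q1` cell values to
#'   0/1, e.g. `c(Y = 1, N = 0)`. `NULL` means the column is already numeric.
#' @param vas_scale Length-2 numeric `c(min, max)` of the raw VAS values;
#'   default `c(0, 1)` (already normalised).
#' @return A list of class `ema_read_config`.
#' @examples
#' ema_read_config(q1_map = c(Y = 1, N = 0), vas_scale = c(0, 100))
#' @export
ema_read_config <- function(user_id = "user_id",
                            timestamp = "timestamp",
                            items = setNames(ema_items(), ema_items()),
                            q1_map = NULL,
                            vas_scale = c(0, 1)) {
  if (is.null(names(items)) || !all(names(items) %in% ema_items())) {
    abort("`items` must be a named vector with names among q1..q7")
  }
  if (length(vas_scale) != 2 || vas_scale[2] <= vas_scale[1]) {
    abort("`vas_scale` must be c(min, max) with max > min")
  }
  structure(
    list(
      user_id = user_id, timestamp = timestamp, items = items,
      q1_map = q1_map, vas_scale = as.numeric(vas_scale)
    ),
    class = "ema_read_config"
  )
}

#' Load a read configuration from a YAML file
#'
#' Accepts the keys `user_id`, `timestamp`, `items` (map canonical -> column),
#' `q1_map` (map label -> 0/1) and `vas_scale` (`[min, max]`); missing keys
#' fall back to the [ema_read_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return An `ema_read_config` object.
#' @export
read_ema_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- ema_read_config()
  items <- if (!is.null(y$items)) unlist(y$items) else defaults$items
  q1_map <- if (!is.null(y$q1_map)) unlist(y$q1_map) else NULL
  ema_read_config(
    user_id = y$user_id %||% defaults$user_id,
    timestamp = y$timestamp %||% defaults$timestamp,
    items = items,
    q1_map = q1_map,
    vas_scale = y$vas_scale %||% defaults$vas_scale
  )
}

parse_iso_timestamp <- function(x) {
  fmts <- c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"
  )
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in fmts) {
    idx <- which(is.na(out) & !is.na(x) & nzchar(x))
    if (length(idx) == 0) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  out
}

row_error <- function(rows, what) {
  # rows are 1-based data rows; +1 accounts for the header line
  abort(sprintf(
    "%s at line%s %s", what, if (length(rows) > 1) "s" else "",
    paste(rows + 1L, collapse = ", ")
  ))
}

#' Read a long-format EMA table
#'
#' Reads a CSV with one prompt response per row (columns: user id, ISO-8601
#' timestamp, one column per EMA item) into the canonical recording tibble.
#' Rows in which every item cell is empty are not EMA entries and are dropped;
#' the dropped count is reported via a message and stored in the `n_dropped`
#' attribute. Values are validated against the item ranges (`q1` in `{0, 1}`,
#' `q2`..`q7` in `[0, 1]` after rescaling); violations abort with the
#' offending line numbers.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param config An [ema_read_config()] (or path handled by
#'   [read_ema_config()] upstream).
#' @return A tibble with columns `user_id` (character), `timestamp` (POSIXct,
#'   UTC) and `q1`..`q7` (double, `NA` where unanswered), sorted stably by
#'   `(user_id, timestamp)`.
#' @examples
#' path <- system.file("extdata", "ema_demo.csv", package = "emadhere")
#' cfg <- read_ema_config(
#'   system.file("extdata", "ema_config_demo.yaml", package = "emadhere")
#' )
#' read_ema_table(path, cfg)
#' @export
read_ema_table <- function(path, config = ema_read_config()) {
  stopifnot(inherits(config, "ema_read_config"))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (col in c(config$user_id, config$timestamp)) {
    if (!col %in% names(raw)) {
      abort(sprintf("mandatory column '%s' is missing from %s", col, path))
    }
  }
  present <- config$items[config$items %in% names(raw)]
  missing_items <- setdiff(config$items, names(raw))
  if (length(present) == 0) {
    abort(sprintf(
      "no EMA item column found; expected any of: %s",
      paste(config$items, collapse = ", ")
    ))
  }
  if (length(missing_items) > 0) {
    inform(sprintf(
      "item column%s absent from file: %s",
      if (length(missing_items) > 1) "s" else "",
      paste(missing_items, collapse = ", ")
    ))
  }

  n <- nrow(raw)
  out <- tibble(
    user_id = as.character(raw[[config$user_id]]),
    timestamp = parse_iso_timestamp(raw[[config$timestamp]])
  )
  bad_ts <- which(is.na(out$timestamp))
  if (length(bad_ts) > 0) row_error(bad_ts, "unparseable timestamp")

  for (item in ema_items()) out[[item]] <- rep(NA_real_, n)
  for (item in names(present)) {
    cells <- raw[[present[[item]]]]
    empty <- is.na(cells) | !nzchar(trimws(cells))
    vals <- rep(NA_real_, n)
    if (item == "q1" && !is.null(config$q1_map)) {
      mapped <- unname(config$q1_map[trimws(cells[!empty])])
      bad <- which(!empty)[is.na(mapped)]
      if (length(bad) > 0) row_error(bad, "q1 value outside its declared encoding")
      vals[!empty] <- as.numeric(mapped)
    } else {
      num <- suppressWarnings(as.numeric(cells[!empty]))
      bad <- which(!empty)[is.na(num)]
      if (length(bad) > 0) row_error(bad, sprintf("non-numeric %s value", item))
      if (item != "q1") {
        num <- (num - config$vas_scale[1]) /
          (config$vas_scale[2] - config$vas_scale[1])
      }
      vals[!empty] <- num
    }
    rng <- if (item == "q1") c(0, 1) else c(0, 1)
    bad <- which(!empty)[vals[!empty] < rng[1] | vals[!empty] > rng[2] |
      (item == "q1" & !vals[!empty] %in% c(0, 1))]
    if (length(bad) > 0) row_error(bad, sprintf("%s value out of range", item))
    out[[item]] <- vals
  }

  has_answer <- rowSums(!is.na(as.matrix(out[ema_items()]))) > 0
  n_dropped <- sum(!has_answer)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d row(s) with no item answered", n_dropped))
  }
  out <- out[has_answer, , drop = FALSE]
  out <- arrange(out, .data$user_id, .data$timestamp)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a recording tibble back to CSV
#'
#' Inverse of [read_ema_table()] under the default configuration; timestamps
#' are written as ISO-8601 (`%Y-%m-%dT%H:%M:%S`, UTC) so a write/read
#' round-trip reproduces the recordings exactly.
#'
#' @param recordings Recording tibble as returned by [read_ema_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ema_table <- function(recordings, path) {
  out <- recordings
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

minitf_items <- function() paste0("tf", 1:12)

tschq_fields <- function() {
  c(
    "sex", "ageAtRegistration", "ageAtOnset", "onsetrelation",
    "familyHistory", "variability"
  )
}

#' Read the registration (questionnaire) table
#'
#' One row per user with the 12 MiniTF items (coded `2` = True, `1` =
#' Partially True, `0` = False), the MiniTF total score (0--24), and the TSCHQ
#' subset (sex, ages, onset relation, family history, variability; categorical
#' codes are kept opaque). Empty cells become `NA`, never an imputed value.
#' When all 12 MiniTF items are present the score is recomputed as their sum;
#' a provided score that disagrees triggers a warning naming the user and the
#' recomputed value is kept. When any item is missing the score is marked
#' missing, because it cannot be cross-checked.
#'
#' @param path CSV path with a `user_id` column plus any of `tf1`..`tf12`,
#'   `minitf_score`, and the TSCHQ columns.
#' @return A tibble keyed by `user_id`.
#' @export
read_registration_table <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"user_id" %in% names(raw)) abort("mandatory column 'user_id' is missing")
  ids <- as.character(raw$user_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate user_id in registration table: %s",
                  paste(dup, collapse = ", ")))
  }

  num_col <- function(name) {
    if (!name %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    cells <- raw[[name]]
    empty <- is.na(cells) | !nzchar(trimws(cells))
    vals <- rep(NA_real_, nrow(raw))
    num <- suppressWarnings(as.numeric(cells[!empty]))
    bad <- which(!empty)[is.na(num)]
    if (length(bad) > 0) row_error(bad, sprintf("non-numeric %s value", name))
    vals[!empty] <- num
    vals
  }

  out <- tibble(user_id = ids)
  for (tf in minitf_items()) {
    v <- num_col(tf)
    bad <- which(!is.na(v) & !v %in% c(0, 1, 2))
    if (length(bad) > 0) row_error(bad, sprintf("%s code outside {0,1,2}", tf))
    out[[tf]] <- as.integer(v)
  }
  provided_score <- num_col("minitf_score")
  items <- as.matrix(out[minitf_items()])
  complete <- rowSums(is.na(items)) == 0
  recomputed <- ifelse(complete, rowSums(items), NA_real_)
  mismatch <- which(complete & !is.na(provided_score) &
                      provided_score != recomputed)
  if (length(mismatch) > 0) {
    warn(sprintf(
      "minitf_score disagrees with the item sum for user(s) %s; using the item sum",
      paste(ids[mismatch], collapse = ", ")
    ))
  }
  out$minitf_score <- as.integer(recomputed)

  for (f in tschq_fields()) out[[f]] <- num_col(f)
  bad_age <- which(!is.na(out$ageAtRegistration) & out$ageAtRegistration < 0 |
                     !is.na(out$ageAtOnset) & out$ageAtOnset < 0)
  if (length(bad_age) > 0) row_error(bad_age, "negative age")
  bad_order <- which(!is.na(out$ageAtOnset) & !is.na(out$ageAtRegistration) &
                       out$ageAtOnset > out$ageAtRegistration)
  if (length(bad_order) > 0) {
    row_error(bad_order, "ageAtOnset exceeds ageAtRegistration")
  }
  for (f in c("sex", "onsetrelation", "familyHistory", "variability")) {
    out[[f]] <- as.integer(out[[f]])
  }
  out
}

#' @rdname read_registration_table
#' @param registrations Registration tibble.
#' @export
write_registration_table <- function(registrations, path) {
  readr::write_csv(registrations, path, na = "")
  invisible(path)
}

#' Bundle recordings and registrations into a cohort
#'
#' A cohort couples the EMA recording table with the per-user registration
#' table and the right-censoring boundary of the export. Recordings are
#' re-sorted stably by `(user_id, timestamp)`. Recordings whose user lacks a
#' registration row are tolerated with a warning (use [validate_cohort()] to
#' list them).
#'
#' @param recordings Recording tibble ([read_ema_table()]).
#' @param registrations Registration tibble ([read_registration_table()]).
#' @param export_end Date marking the end of the export window; defaults to
#'   the last recording date. Must not precede it.
#' @return An object of class `ema_cohort` with elements `recordings`,
#'   `registrations`, `export_end`.
#' @export
ema_cohort <- function(recordings, registrations, export_end = NULL) {
  recordings <- arrange(as_tibble(recordings), .data$user_id, .data$timestamp)
  registrations <- as_tibble(registrations)
  last_day <- if (nrow(recordings) > 0) {
    max(as.Date(recordings$timestamp, tz = "UTC"))
  } else {
    NULL
  }
  if (is.null(export_end)) {
    if (is.null(last_day)) abort("an empty cohort needs an explicit export_end")
    export_end <- last_day
  }
  export_end <- as.Date(export_end)
  if (!is.null(last_day) && export_end < last_day) {
    abort("export_end precedes the last recording date")
  }
  orphans <- setdiff(unique(recordings$user_id), registrations$user_id)
  if (length(orphans) > 0) {
    warn(sprintf("%d user(s) have recordings but no registration row",
                 length(orphans)))
  }
  structure(
    list(
      recordings = recordings, registrations = registrations,
      export_end = export_end
    ),
    class = "ema_cohort"
  )
}

#' @export
print.ema_cohort <- function(x, ...) {
  cat(sprintf(
    "<ema_cohort> %d recordings, %d recorded user(s), %d registered user(s), export ends %s\n",
    nrow(x$recordings), length(unique(x$recordings$user_id)),
    nrow(x$registrations), format(x$export_end)
  ))
  invisible(x)
}

#' Validate a cohort
#'
#' Report-only checks mirroring the exclusion bookkeeping of the analysis:
#' registered users without any recording, orphan recordings (no registration
#' row), and right-censored users whose first recording falls so close to the
#' export end that fewer than `N` days are observable.
#'
#' @param cohort An [ema_cohort()].
#' @param horizon A [horizon_config()].
#' @return A list of class `cohort_validation` with character vectors
#'   `users_without_recordings`, `orphan_recordings`, `right_censored`, and a
#'   logical `clean`.
#' @export
validate_cohort <- function(cohort, horizon = horizon_config()) {
  stopifnot(inherits(cohort, "ema_cohort"))
  horizon <- as_horizon(horizon)
  rec_users <- unique(cohort$recordings$user_id)
  reg_users <- cohort$registrations$user_id
  firsts <- cohort$recordings |>
    mutate(day = as.Date(.data$timestamp, tz = "UTC")) |>
    summarise(first_day = min(.data$day), .by = "user_id")
  observable <- as.integer(cohort$export_end - firsts$first_day) + 1L
  out <- list(
    users_without_recordings = setdiff(reg_users, rec_users),
    orphan_recordings = setdiff(rec_users, reg_users),
    right_censored = firsts$user_id[observable < horizon$n]
  )
  out$clean <- all(lengths(out[1:3]) == 0)
  structure(out, class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("<cohort_validation>\n")
  cat(sprintf("  users without recordings: %d\n",
              length(x$users_without_recordings)))
  cat(sprintf("  orphan recordings (unregistered users): %d\n",
              length(x$orphan_recordings)))
  cat(sprintf("  right-censored users: %d\n", length(x$right_censored)))
  if (x$clean) cat("  cohort is clean\n")
  invisible(x)
}
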