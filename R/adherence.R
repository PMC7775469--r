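#' Collapse recordings into per-day, per-item series
#'
#' A user has an EMA entry on a day only if at least one item of at least one
#' prompt was answered. Within a day, the answers to one item are collapsed to
#' their arithmetic mean (the dichotomous `q1` is averaged on its 0/1 coding).
#' Days are indexed by interaction, not by calendar: `t = 1` is the user's
#' first entry day, and consecutive `t` need not be adjacent dates. Entries
#' after the user's `N`-th distinct interaction day (counted jointly over all
#' items) are ignored; the per-item index `t` then counts that item's own
#' active days among the retained ones.
#'
#' @param recordings Recording tibble (see [read_ema_table()]).
#' @param horizon A [horizon_config()]; `horizon$n` clips the series.
#' @param day_offset_hours Day-boundary offset in hours (default 0 =
#'   midnight); e.g. `4` makes a day run from 04:00 to 03:59.
#' @return A tibble with columns `user_id`, `item`, `day` (Date), `value`
#'   (that day's mean answer) and `t` (the item's interaction-day index),
#'   sorted by `(user_id, item, day)`.
#' @export
daily_series <- function(recordings, horizon = horizon_config(),
                         day_offset_hours = 0) {
  horizon <- as_horizon(horizon)
  items <- intersect(ema_items(), names(recordings))
  long <- recordings |>
    pivot_longer(all_of(items), names_to = "item", values_to = "value") |>
    filter(!is.na(.data$value)) |>
    mutate(day = as.Date(.data$timestamp - day_offset_hours * 3600, tz = "UTC"))
  kept_days <- long |>
    distinct(.data$user_id, .data$day) |>
    arrange(.data$user_id, .data$day) |>
    mutate(joint_t = row_number(), .by = "user_id") |>
    filter(.data$joint_t <= horizon$n)
  long |>
    inner_join(kept_days, by = c("user_id", "day")) |>
    summarise(
      value = mean(.data$value),
      .by = c("user_id", "item", "day")
    ) |>
    arrange(.data$user_id, .data$item, .data$day) |>
    mutate(t = row_number(), .by = c("user_id", "item"))
}

#' @rdname daily_series
#' @param item A single item name (`"q1"`..`"q7"`); [collapse_to_days()]
#'   restricts the daily series to that item.
#' @export
collapse_to_days <- function(recordings, item, horizon = horizon_config(),
                             day_offset_hours = 0) {
  if (!item %in% ema_items()) abort("unknown EMA item")
  daily_series(recordings, horizon, day_offset_hours) |>
    filter(.data$item == !!item)
}

#' Total interaction days, ignoring the horizon
#'
#' Counts every calendar day with at least one answered item (the `NumDays`
#' quantity), without clipping at the observation period.
#'
#' @inheritParams daily_series
#' @return Tibble with columns `user_id`, `num_days`.
#' @export
interaction_days <- function(recordings, day_offset_hours = 0) {
  items <- intersect(ema_items(), names(recordings))
  recordings |>
    pivot_longer(all_of(items), names_to = "item", values_to = "value") |>
    filter(!is.na(.data$value)) |>
    mutate(day = as.Date(.data$timestamp - day_offset_hours * 3600, tz = "UTC")) |>
    distinct(.data$user_id, .data$day) |>
    summarise(num_days = n(), .by = "user_id")
}

#' Days until first break
#'
#' Length of the initial run of adjacent calendar days in a strictly
#' increasing date sequence: the largest `m` such that `dates[1..m]` are
#' consecutive.
#'
#' @param dates Strictly increasing vector of `Date`s (a series' active days).
#' @return Integer, at least 1.
#' @examples
#' d <- as.Date("2014-04-10")
#' first_days(c(d, d + 1, d + 2, d + 4)) # 3
#' first_days(c(d, d + 2)) # 1
#' @export
first_days <- function(dates) {
  if (length(dates) == 0) {
    abort("no interaction: FirstDays is undefined for an empty series")
  }
  d <- as.integer(as.Date(dates))
  if (is.unsorted(d, strictly = TRUE)) {
    abort("`dates` must be strictly increasing")
  }
  as.integer(sum(cumprod(c(1L, diff(d) == 1L))))
}

#' Per-user adherence profiles
#'
#' For each user computes, within the `N`-day horizon: the interaction
#' duration (`max` over items of the per-item series length), `FirstDays`
#' (`max` over items of the per-item days-until-first-break), the dichotomous
#' `Return` label (`Yes` iff duration exceeds `FirstDays`, i.e. the user
#' resumed after the first break), and the horizon-free `num_days`. A user
#' whose `Return` is `No` necessarily has `duration == first_days`.
#'
#' @inheritParams daily_series
#' @return A tibble with columns `user_id`, `duration`, `first_days`, `return`
#'   (factor `No`/`Yes`), `num_days`, and one `first_days_qJ` column per item
#'   (`NA` where the user never answered the item).
#' @export
adherence_profiles <- function(recordings, horizon = horizon_config(),
                               day_offset_hours = 0) {
  horizon <- as_horizon(horizon)
  daily <- daily_series(recordings, horizon, day_offset_hours)
  users_in <- unique(recordings$user_id)
  silent <- setdiff(users_in, unique(daily$user_id))
  if (length(silent) > 0) {
    abort(sprintf("user(s) with no EMA entry: %s",
                  paste(head(silent, 5), collapse = ", ")))
  }
  per_item <- daily |>
    summarise(
      n = n(), fd = first_days(.data$day),
      .by = c("user_id", "item")
    )
  prof <- per_item |>
    summarise(
      duration = max(.data$n), first_days = max(.data$fd),
      .by = "user_id"
    ) |>
    mutate(return = factor(
      ifelse(.data$duration > .data$first_days, "Yes", "No"),
      levels = c("No", "Yes")
    ))
  fd_wide <- per_item |>
    mutate(item = paste0("first_days_", .data$item)) |>
    select("user_id", "item", "fd") |>
    pivot_wider(names_from = "item", values_from = "fd")
  for (item in ema_items()) {
    col <- paste0("first_days_", item)
    if (!col %in% names(fd_wide)) fd_wide[[col]] <- NA_integer_
  }
  prof |>
    left_join(interaction_days(recordings, day_offset_hours), by = "user_id") |>
    left_join(fd_wide, by = "user_id") |>
    select(
      "user_id", "duration", "first_days", "return", "num_days",
      all_of(paste0("first_days_", ema_items()))
    )
}

#' Interaction-duration histograms
#'
#' Plain mode counts users per duration value. Cumulative mode counts, for
#' each minimum `m = 1 .. tau_early + 1`, the users whose duration is at least
#' `m` — the "at least m EMA entries" condensation, which is non-increasing
#' in `m`.
#'
#' @param profiles Profile tibble from [adherence_profiles()].
#' @param cumulative Logical; build the condensed ("at least") histogram?
#' @param horizon A [horizon_config()]; bounds the cumulative axis.
#' @return A tibble with columns `duration` (or `min_duration`) and `n_users`.
#' @export
duration_histogram <- function(profiles, cumulative = FALSE,
                               horizon = horizon_config()) {
  horizon <- as_horizon(horizon)
  if (!cumulative) {
    return(profiles |> count(duration = .data$duration, name = "n_users"))
  }
  if (nrow(profiles) == 0) {
    return(tibble(min_duration = integer(), n_users = integer()))
  }
  m <- seq_len(horizon$tau_early + 1L)
  tibble(
    min_duration = m,
    n_users = map_int(m, function(v) sum(profiles$duration >= v))
  )
}

#' Plot an interaction-duration histogram
#'
#' @inheritParams duration_histogram
#' @return A ggplot object.
#' @export
plot_duration_histogram <- function(profiles, cumulative = FALSE,
                                    horizon = horizon_config()) {
  h <- duration_histogram(profiles, cumulative, horizon)
  xcol <- if (cumulative) "min_duration" else "duration"
  xlab <- if (cumulative) {
    "Minimum number of EMA entry days"
  } else {
    "Interaction duration (days)"
  }
  ggplot2::ggplot(h, ggplot2::aes(x = .data[[xcol]], y = .data$n_users)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = xlab, y = "Users") +
    ggplot2::theme_minimal()
}
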