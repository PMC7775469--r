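#' Majority-class prior of a stratum
#'
#' The likelihood of the majority `Return` class given the two class counts;
#' reported rounded half-up to two decimals by the summary writers. A tie
#' counts class `No` as the majority (conservative towards predicting
#' dropout), which leaves the value at exactly 0.5.
#'
#' @param n_no,n_yes Non-negative class counts (vectorised).
#' @return Numeric in `[0.5, 1]`.
#' @examples
#' majority_prior(22, 158) # ~0.878 -> reported 0.88
#' majority_prior(87, 97) # ~0.527 -> reported 0.53
#' @export
majority_prior <- function(n_no, n_yes) {
  if (any(n_no + n_yes < 1)) abort("a stratum needs at least one member")
  pmax(n_no, n_yes) / (n_no + n_yes)
}

#' Build the per-item length strata
#'
#' For each EMA item, every user with a non-empty series for that item falls
#' into exactly one stratum according to the item-level days-until-first-break
#' `FirstDays_{u,j}`: stratum `k` for `k <= tau_early`, else the pooled
#' `>= tau_early + 1` stratum. The `Return` label is item-level too: `No` iff
#' the series ends with the first run (`n == FirstDays`), `Yes` iff the user
#' resumed the item later (`n > FirstDays`). Each member contributes its first
#' `min(FirstDays, tau_early + 1)` per-day means, so all series within a
#' stratum have equal length (`k`, or `tau_early + 1` for the pooled stratum,
#' by truncation).
#'
#' @param daily Per-day series tibble from [daily_series()].
#' @param horizon A [horizon_config()].
#' @return A tibble with one row per (user, item) membership: `user_id`,
#'   `item`, `k` (integer stratum; `tau_early + 1` is the pooled stratum),
#'   `pooled` (logical), `n`, `fd`, `series` (list of numeric vectors),
#'   `label` (factor `No`/`Yes`).
#' @export
build_strata <- function(daily, horizon = horizon_config()) {
  horizon <- as_horizon(horizon)
  tau <- horizon$tau_early
  daily |>
    arrange(.data$user_id, .data$item, .data$day) |>
    summarise(
      n = n(),
      fd = first_days(.data$day),
      series = list(.data$value[seq_len(min(first_days(.data$day), tau + 1L))]),
      .by = c("user_id", "item")
    ) |>
    mutate(
      k = pmin(.data$fd, tau + 1L),
      pooled = .data$fd > tau,
      label = factor(ifelse(.data$n > .data$fd, "Yes", "No"),
                     levels = c("No", "Yes"))
    )
}

#' Extract one stratum dataset
#'
#' @inheritParams build_strata
#' @param k Stratum index in `1..tau_early`, or `tau_early + 1` for the pooled
#'   stratum.
#' @param item EMA item name.
#' @return A tibble of class `ema_stratum` (columns as in [build_strata()]),
#'   possibly with zero rows, with attributes `item`, `k` and `priors`
#'   (`c(n_no, n_yes)`).
#' @export
build_stratum <- function(daily, k, item, horizon = horizon_config()) {
  horizon <- as_horizon(horizon)
  if (!item %in% ema_items()) abort("unknown EMA item")
  if (!k %in% seq_len(horizon$tau_early + 1L)) {
    abort("`k` must lie in 1..tau_early+1")
  }
  all_strata <- build_strata(daily, horizon)
  out <- all_strata[all_strata$item == item & all_strata$k == k, , drop = FALSE]
  as_stratum(out, item, k)
}

as_stratum <- function(tbl, item, k) {
  structure(
    tbl,
    item = item, k = as.integer(k),
    priors = c(
      n_no = sum(tbl$label == "No"),
      n_yes = sum(tbl$label == "Yes")
    ),
    class = c("ema_stratum", class(tbl))
  )
}

#' Stratum summary in the counts-and-priors layout
#'
#' One row per (item, stratum): class counts, a `"No vs. Yes"` display string
#' and the majority prior rounded half-up to two decimals.
#'
#' @param strata Membership tibble from [build_strata()].
#' @param horizon A [horizon_config()].
#' @return A tibble with columns `item`, `k`, `n_no`, `n_yes`, `counts`,
#'   `prior`.
#' @export
strata_summary <- function(strata, horizon = horizon_config()) {
  horizon <- as_horizon(horizon)
  strata |>
    summarise(
      n_no = sum(.data$label == "No"),
      n_yes = sum(.data$label == "Yes"),
      .by = c("item", "k")
    ) |>
    arrange(.data$item, .data$k) |>
    mutate(
      counts = sprintf("%d vs. %d", .data$n_no, .data$n_yes),
      prior = round_half_up(majority_prior(.data$n_no, .data$n_yes), 2)
    )
}

#' @rdname strata_summary
#' @return [format_strata_summary()]: a wide tibble, one row per item and one
#'   column per stratum, cells like `"22 vs. 158 (0.88)"`.
#' @export
format_strata_summary <- function(strata, horizon = horizon_config()) {
  horizon <- as_horizon(horizon)
  tau <- horizon$tau_early
  strata_summary(strata, horizon) |>
    mutate(
      cell = sprintf("%s (%.2f)", .data$counts, .data$prior),
      stratum = ifelse(.data$k > tau, sprintf(">=%d", tau + 1L),
                       as.character(.data$k))
    ) |>
    select("item", "stratum", "cell") |>
    pivot_wider(names_from = "stratum", values_from = "cell")
}

#' Unordered feature table of a stratum
#'
#' Rows are users, columns the `k` per-day means; for classifiers that are not
#' time-series aware the column identity carries no temporal meaning.
#'
#' @param stratum A stratum tibble ([build_stratum()] or one group of
#'   [build_strata()]).
#' @return A list with `x` (numeric matrix, users by days) and `y` (the label
#'   factor).
#' @export
to_feature_table <- function(stratum) {
  if (nrow(stratum) == 0) {
    return(list(x = matrix(numeric(), nrow = 0, ncol = 0),
                y = factor(character(), levels = c("No", "Yes"))))
  }
  list(x = do.call(rbind, stratum$series), y = stratum$label)
}
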