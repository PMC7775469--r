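#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation grid
#'
#' One row per (algorithm, item, stratum) entry, including skipped
#' combinations with their reason.
#'
#' @param x An `ema_grid` from [run_grid()].
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.ema_grid <- function(x, ...) {
  as_tibble(x)
}

#' Summarise an evaluation grid in one row
#'
#' @param x An `ema_grid`.
#' @param ... Unused.
#' @return A one-row tibble: entry counts, retained count and fraction (of
#'   evaluated entries), and the best improvement in percentage units.
#' @export
glance.ema_grid <- function(x, ...) {
  evaluated <- sum(is.na(x$skip_reason))
  retained <- sum(x$retained, na.rm = TRUE)
  tibble(
    n_entries = nrow(x),
    n_evaluated = evaluated,
    n_skipped = nrow(x) - evaluated,
    n_retained = retained,
    retained_fraction = if (evaluated > 0) retained / evaluated else NA_real_,
    max_improvement = if (evaluated > 0) {
      max(x$improvement, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}

#' Tidy a rule list
#'
#' @param x An `ema_rules` tibble from [hotspot_induce()].
#' @param ... Unused.
#' @return A plain tibble without the conditions list column.
#' @export
tidy.ema_rules <- function(x, ...) {
  as_tibble(x) |> select(-"conditions")
}

#' Summarise a rule list in one row
#'
#' @param x An `ema_rules` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the rule count, complete-case population,
#'   base rate and maximum lift.
#' @export
glance.ema_rules <- function(x, ...) {
  tibble(
    n_rules = nrow(x),
    n_total = attr(x, "n_total"),
    n_dropped_incomplete = attr(x, "n_dropped_incomplete"),
    base_rate = attr(x, "base_rate"),
    max_lift = if (nrow(x) > 0) max(x$lift) else NA_real_
  )
}

#' Plot an evaluation grid
#'
#' Tile map of accuracy improvement over the majority prior per (algorithm,
#' item, stratum); retained entries are outlined.
#'
#' @param object An `ema_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ema_grid <- function(object, ...) {
  d <- as_tibble(object) |> filter(is.na(.data$skip_reason))
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$k), y = .data$item, fill = .data$improvement
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = d |> filter(.data$retained),
      colour = "black", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick") +
    ggplot2::labs(
      x = "FirstDays stratum", y = "EMA item",
      fill = "Improvement (pp)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a rule list
#'
#' Lift against support, point size by precision.
#'
#' @param object An `ema_rules` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ema_rules <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(
    x = .data$support, y = .data$lift, size = .data$precision
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Support", y = "Lift", size = "Precision") +
    ggplot2::theme_minimal()
}
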