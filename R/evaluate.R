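#' Holdout split configuration
#'
#' @param train_fraction Fraction of each class assigned to training
#'   (default 2/3, the 2:1 split).
#' @param seed Integer seed driving the split's own RNG stream (default 145);
#'   the global RNG state is left untouched.
#' @return A list of class `split_config`.
#' @export
split_config <- function(train_fraction = 2 / 3, seed = 145L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1")
  }
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_config")
}

#' Stratified holdout split
#'
#' Splits a labelled dataset into training and test parts, preserving the
#' class proportions up to integer rounding: within each class, a seeded
#' permutation assigns `round(n_class * train_fraction)` members (half-up,
#' clamped so that classes of size two or more contribute to both parts) to
#' training. A class with a single member goes entirely to training with a
#' warning. Deterministic given the seed.
#'
#' @param data A tibble with a `label` column (e.g. a stratum from
#'   [build_strata()]).
#' @param config A [split_config()].
#' @return A list with tibbles `train` and `test`.
#' @export
stratified_holdout <- function(data, config = split_config()) {
  stopifnot(inherits(config, "split_config"))
  n <- nrow(data)
  if (n == 0) abort("cannot split an empty dataset")
  idx_by_class <- split(seq_len(n), droplevels(factor(data$label)))
  train_idx <- withr::with_seed(config$seed, {
    unlist(lapply(idx_by_class, function(ids) {
      k <- length(ids)
      if (k == 1) {
        warn("class with a single member assigned entirely to training")
        return(ids)
      }
      n_tr <- floor(k * config$train_fraction + 0.5)
      n_tr <- min(max(n_tr, 1L), k - 1L)
      sample(ids)[seq_len(n_tr)]
    }), use.names = FALSE)
  })
  list(
    train = data[sort(train_idx), , drop = FALSE],
    test = data[setdiff(seq_len(n), train_idx), , drop = FALSE]
  )
}

#' Classification accuracy
#'
#' Fraction of exact matches between predictions and reference labels.
#'
#' @param predictions,labels Equal-length vectors (coerced to character).
#' @return Numeric in `[0, 1]`.
#' @export
classification_accuracy <- function(predictions, labels) {
  if (length(labels) == 0) abort("accuracy is undefined on an empty test set")
  if (length(predictions) != length(labels)) {
    abort("`predictions` and `labels` differ in length")
  }
  mean(as.character(predictions) == as.character(labels))
}

#' Gaussian naive Bayes fit-and-predict
#'
#' Class-conditional univariate Gaussians per feature (variance floored at
#' `1e-9`) with class priors from the training counts; prediction maximises
#' the log posterior, ties breaking towards the first class level. A training
#' set with a single class predicts that class everywhere.
#'
#' @param train_x,test_x Numeric feature matrices (rows = observations).
#' @param train_y Training labels.
#' @return Character vector of predicted labels for `test_x`.
#' @export
naive_bayes_fit_predict <- function(train_x, train_y, test_x) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  y <- droplevels(factor(train_y))
  classes <- levels(y)
  if (length(classes) == 1) return(rep(classes, nrow(test_x)))
  scores <- vapply(classes, function(cl) {
    xc <- train_x[y == cl, , drop = FALSE]
    mu <- colMeans(xc)
    v <- apply(xc, 2, function(col) {
      s2 <- if (length(col) > 1) var(col) else 0
      max(s2, 1e-9)
    })
    ll <- rep(log(nrow(xc) / nrow(train_x)), nrow(test_x))
    for (j in seq_len(ncol(test_x))) {
      ll <- ll + dnorm(test_x[, j], mu[j], sqrt(v[j]), log = TRUE)
    }
    ll
  }, numeric(nrow(test_x)))
  scores <- matrix(scores, nrow = nrow(test_x))
  classes[max.col(scores, ties.method = "first")]
}

#' Classifier plug-ins for the evaluation grid
#'
#' An algorithm is a list of class `ema_algorithm` with a display `name`, a
#' `min_len` (smallest admissible series length) and a
#' `predict(train_series, train_label, test_series)` function returning
#' character labels. [alg_1nn()] wraps the elastic-distance
#' one-nearest-neighbour family; [alg_naive_bayes()] runs Gaussian naive
#' Bayes on the order-free feature view of the same series. Any external
#' classifier can slot into [run_grid()] through this interface.
#'
#' @param distance Distance name for [distance_spec()].
#' @param msm_cost MSM split/merge cost.
#' @return An `ema_algorithm` object.
#' @export
alg_1nn <- function(distance = c("ED", "DTW", "DDTW", "CID", "MSM"),
                    msm_cost = 0.1) {
  spec <- distance_spec(match.arg(distance), msm_cost)
  structure(
    list(
      name = paste0("1NN-", spec$name),
      min_len = spec$min_len,
      predict = function(train_series, train_label, test_series) {
        nn1_classify(
          list(series = train_series, label = train_label),
          test_series, spec
        )
      }
    ),
    class = "ema_algorithm"
  )
}

#' @rdname alg_1nn
#' @export
alg_naive_bayes <- function() {
  structure(
    list(
      name = "NB",
      min_len = 1L,
      predict = function(train_series, train_label, test_series) {
        naive_bayes_fit_predict(
          do.call(rbind, train_series), train_label,
          do.call(rbind, test_series)
        )
      }
    ),
    class = "ema_algorithm"
  )
}

#' @rdname alg_1nn
#' @export
default_algorithms <- function(msm_cost = 0.1) {
  algs <- c(
    lapply(c("ED", "DTW", "DDTW", "CID", "MSM"), alg_1nn, msm_cost = msm_cost),
    list(alg_naive_bayes())
  )
  setNames(algs, vapply(algs, `[[`, "", "name"))
}

#' Evaluate classifiers over all (item, stratum) datasets
#'
#' For every EMA item, stratum and algorithm: performs one stratified holdout
#' split (shared across algorithms within a stratum), fits, predicts, and
#' scores accuracy against the stratum's majority-class prior. Combinations
#' that cannot be evaluated (one class absent, empty test set, series shorter
#' than the algorithm's minimum) are recorded with a skip reason rather than
#' dropped. The whole grid is deterministic given the split seed.
#'
#' @param strata Membership tibble from [build_strata()].
#' @param algorithms List of `ema_algorithm` objects (default: the five 1NN
#'   distances plus naive Bayes).
#' @param split A [split_config()].
#' @param horizon A [horizon_config()].
#' @param baseline `"stratum"` (default) scores improvement against each
#'   stratum's own majority prior; `"fixed"` scores every entry against
#'   `fixed_baseline` (the reporting convention that anchors the improvement
#'   threshold at one reference stratum's prior).
#' @param fixed_baseline Baseline accuracy used when `baseline = "fixed"`.
#' @return A tibble of class `ema_grid` with one row per (algorithm, item,
#'   stratum): counts, `baseline`, `accuracy`, `improvement` (percentage
#'   units), `retained`, `skip_reason`.
#' @export
run_grid <- function(strata, algorithms = default_algorithms(),
                     split = split_config(), horizon = horizon_config(),
                     baseline = c("stratum", "fixed"), fixed_baseline = 0.92) {
  horizon <- as_horizon(horizon)
  baseline <- match.arg(baseline)
  stopifnot(inherits(split, "split_config"))
  algorithms <- if (inherits(algorithms, "ema_algorithm")) {
    list(algorithms)
  } else {
    algorithms
  }
  for (a in algorithms) stopifnot(inherits(a, "ema_algorithm"))

  groups <- strata |>
    mutate(.len = lengths(.data$series)) |>
    tidyr::nest(data = !c("item", "k")) |>
    arrange(.data$item, .data$k)

  rows <- list()
  for (g in seq_len(nrow(groups))) {
    dat <- groups$data[[g]]
    item <- groups$item[[g]]
    k <- groups$k[[g]]
    n_no <- sum(dat$label == "No")
    n_yes <- sum(dat$label == "Yes")
    len <- dat$.len[[1]]
    base_row <- tibble(
      item = item, k = k, n_no = n_no, n_yes = n_yes,
      n_train = NA_integer_, n_test = NA_integer_,
      baseline = NA_real_, accuracy = NA_real_, skip_reason = NA_character_
    )

    skip_all <- NULL
    if (n_no == 0 || n_yes == 0) {
      skip_all <- "single class"
    }
    parts <- NULL
    if (is.null(skip_all)) {
      parts <- suppressWarnings(stratified_holdout(dat, split))
      if (nrow(parts$test) == 0) skip_all <- "empty test set"
    }
    prior <- if (n_no + n_yes > 0) majority_prior(n_no, n_yes) else NA_real_
    base_val <- if (baseline == "stratum") prior else fixed_baseline

    for (alg in algorithms) {
      row <- base_row
      row$algorithm <- alg$name
      if (!is.null(skip_all)) {
        row$skip_reason <- skip_all
      } else if (len < alg$min_len) {
        row$skip_reason <- sprintf("min length %d", alg$min_len)
        row$n_train <- nrow(parts$train)
        row$n_test <- nrow(parts$test)
      } else {
        pred <- alg$predict(
          parts$train$series, parts$train$label, parts$test$series
        )
        row$n_train <- nrow(parts$train)
        row$n_test <- nrow(parts$test)
        row$baseline <- base_val
        row$accuracy <- classification_accuracy(pred, parts$test$label)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- bind_rows(rows) |>
    mutate(
      improvement = 100 * (.data$accuracy - .data$baseline),
      retained = !is.na(.data$improvement) &
        .data$improvement >= horizon$tau_improve - 1e-9
    ) |>
    select(
      "algorithm", "item", "k", "n_no", "n_yes", "n_train", "n_test",
      "baseline", "accuracy", "improvement", "retained", "skip_reason"
    )
  structure(out,
    horizon = horizon, baseline_mode = baseline,
    class = c("ema_grid", class(out))
  )
}

#' Retain grid entries that beat the prior by the improvement threshold
#'
#' Recomputes `improvement = 100 * (accuracy - baseline)` and keeps entries
#' with improvement of at least `tau_improve` percentage units; skipped
#' entries can never be retained.
#'
#' @param grid An `ema_grid` from [run_grid()].
#' @param horizon A [horizon_config()] supplying `tau_improve` (defaults to
#'   the grid's own horizon).
#' @return The retained subset of the grid (same columns).
#' @export
improvement_filter <- function(grid, horizon = NULL) {
  horizon <- as_horizon(horizon %||% attr(grid, "horizon"))
  out <- grid |>
    mutate(
      improvement = 100 * (.data$accuracy - .data$baseline),
      retained = !is.na(.data$improvement) &
        .data$improvement >= horizon$tau_improve - 1e-9
    ) |>
    filter(.data$retained)
  out
}

#' Grid rendered as an algorithm-by-stratum table
#'
#' One row per (algorithm, item); one column per stratum, holding the
#' accuracy (2 decimals) where the model was retained, a cross where it was
#' evaluated but discarded, and a dash where the combination was skipped.
#'
#' @param grid An `ema_grid`.
#' @return A wide tibble.
#' @export
grid_table <- function(grid) {
  horizon <- attr(grid, "horizon") %||% horizon_config()
  tau <- horizon$tau_early
  grid |>
    as_tibble() |>
    mutate(
      cell = case_when(
        !is.na(.data$skip_reason) ~ "-",
        .data$retained ~ sprintf("%.2f", .data$accuracy),
        TRUE ~ "x"
      ),
      stratum = ifelse(.data$k > tau, sprintf(">=%d", tau + 1L),
                       as.character(.data$k))
    ) |>
    select("algorithm", "item", "stratum", "cell") |>
    pivot_wider(names_from = "stratum", values_from = "cell")
}
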