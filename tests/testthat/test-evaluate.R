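labelled_data <- function(n_no, n_yes, len = 2) {
  tibble::tibble(
    series = replicate(n_no + n_yes, runif(len), simplify = FALSE),
    label = factor(rep(c("No", "Yes"), c(n_no, n_yes)),
                   levels = c("No", "Yes"))
  )
}

test_that("the 2:1 stratified holdout preserves class proportions", {
  withr::with_seed(10, d <- labelled_data(3, 6))
  parts <- stratified_holdout(d)
  expect_equal(sum(parts$train$label == "Yes"), 4)
  expect_equal(sum(parts$train$label == "No"), 2)
  expect_equal(sum(parts$test$label == "Yes"), 2)
  expect_equal(sum(parts$test$label == "No"), 1)
})

test_that("the split is deterministic given its seed", {
  withr::with_seed(10, d <- labelled_data(10, 20))
  a <- stratified_holdout(d, split_config(seed = 145))
  b <- stratified_holdout(d, split_config(seed = 145))
  expect_identical(a, b)
  c2 <- stratified_holdout(d, split_config(seed = 146))
  expect_false(identical(a, c2))
})

test_that("train fractions stay within one member of the target", {
  withr::with_seed(20, {
    for (i in 1:100) {
      n_no <- sample(2:30, 1)
      n_yes <- sample(2:30, 1)
      d <- labelled_data(n_no, n_yes)
      parts <- stratified_holdout(d)
      expect_lte(abs(sum(parts$train$label == "No") - n_no * 2 / 3), 1)
      expect_lte(abs(sum(parts$train$label == "Yes") - n_yes * 2 / 3), 1)
      expect_gt(nrow(parts$test), 0)
    }
  })
})

test_that("a singleton class goes to training with a warning", {
  withr::with_seed(30, d <- labelled_data(1, 6))
  expect_warning(parts <- stratified_holdout(d), "single member")
  expect_true(all(parts$test$label == "Yes"))
  expect_equal(sum(parts$train$label == "No"), 1)
})

test_that("accuracy is the exact-match fraction", {
  expect_equal(classification_accuracy(c("Y", "Y"), c("Y", "Y")), 1)
  expect_equal(
    classification_accuracy(c("Y", "N", "N"), c("Y", "Y", "N")), 2 / 3
  )
  expect_error(classification_accuracy(character(), character()), "empty")
})

test_that("a majority-vote predictor scores the majority prior on average", {
  withr::with_seed(40, {
    accs <- replicate(300, {
      labels <- sample(c("No", "Yes"), 50, replace = TRUE, prob = c(0.7, 0.3))
      classification_accuracy(rep("No", 50), labels)
    })
    expect_lt(abs(mean(accs) - 0.7), 0.01)
  })
})

test_that("the improvement filter applies the tau threshold inclusively", {
  grid <- tibble::tibble(
    algorithm = "A", item = "q1", k = 1:3,
    baseline = c(0.53, 0.92, 0.92), accuracy = c(0.61, 0.95, 1.00),
    improvement = NA_real_, retained = NA, skip_reason = NA_character_
  )
  kept <- improvement_filter(grid, horizon_config())
  expect_equal(kept$k, c(1L, 3L))
  expect_equal(kept$improvement, c(8, 8), tolerance = 1e-9)
})

test_that("naive Bayes separates well-separated Gaussian clusters", {
  withr::with_seed(50, {
    tr_x <- rbind(
      matrix(rnorm(200, 0, 0.4), ncol = 2),
      matrix(rnorm(200, 3, 0.4), ncol = 2)
    )
    tr_y <- rep(c("No", "Yes"), each = 100)
    te_x <- rbind(
      matrix(rnorm(200, 0, 0.4), ncol = 2),
      matrix(rnorm(200, 3, 0.4), ncol = 2)
    )
    te_y <- rep(c("No", "Yes"), each = 100)
    acc <- classification_accuracy(
      naive_bayes_fit_predict(tr_x, tr_y, te_x), te_y
    )
    expect_gte(acc, 0.95)
  })
})

test_that("naive Bayes degrades to the class prior on identical classes", {
  withr::with_seed(60, {
    accs <- replicate(30, {
      tr_x <- matrix(rnorm(300), ncol = 2)
      tr_y <- rep(c("No", "Yes"), c(100, 50))
      te_x <- matrix(rnorm(300), ncol = 2)
      te_y <- sample(c("No", "Yes"), 150, TRUE, prob = c(2, 1) / 3)
      classification_accuracy(naive_bayes_fit_predict(tr_x, tr_y, te_x), te_y)
    })
    # indistinguishable features: the model mostly predicts the majority
    # class, so accuracy hovers near the 2/3 prior
    expect_lt(abs(mean(accs) - 2 / 3), 0.08)
  })
})

test_that("naive Bayes survives degenerate training sets", {
  pred <- naive_bayes_fit_predict(
    matrix(c(0, 1), ncol = 1), c("No", "Yes"), matrix(c(0, 1), ncol = 1)
  )
  expect_equal(pred, c("No", "Yes"))
  single <- naive_bayes_fit_predict(
    matrix(0.5, ncol = 1), "Yes", matrix(c(0, 9), ncol = 1)
  )
  expect_equal(single, c("Yes", "Yes"))
})

test_that("naive Bayes agrees with an independent reference implementation", {
  withr::with_seed(70, {
    tr_x <- matrix(rnorm(120, rep(c(0, 1), each = 30)), ncol = 2)
    tr_y <- factor(rep(c("No", "Yes"), each = 30))
    te_x <- matrix(rnorm(60), ncol = 2)
    fit <- e1071::naiveBayes(data.frame(tr_x), tr_y)
    ref <- as.character(predict(fit, data.frame(te_x)))
    expect_equal(naive_bayes_fit_predict(tr_x, tr_y, te_x), ref)
  })
})

test_that("the grid covers items by strata and records skips", {
  withr::with_seed(80, {
    g <- generate_cohort(synth_config(n_users = 150, seed = 3))
    st <- build_strata(daily_series(g$cohort$recordings))
    grid <- run_grid(st, algorithms = list(alg_1nn("ED"), alg_1nn("DDTW")))
  })
  per_alg <- table(tidy(grid)$algorithm)
  expect_true(all(per_alg <= 70))
  # DDTW cannot run on one- or two-day series
  ddtw_short <- tidy(grid) |>
    dplyr::filter(algorithm == "1NN-DDTW", k <= 2)
  expect_true(all(ddtw_short$skip_reason == "min length 3"))
  # single-class strata are skipped with that reason
  single_cls <- tidy(grid) |>
    dplyr::filter(n_no == 0 | n_yes == 0)
  if (nrow(single_cls) > 0) {
    expect_true(all(single_cls$skip_reason == "single class"))
  }
})

test_that("the grid is reproducible at a fixed split seed", {
  withr::with_seed(90, {
    g <- generate_cohort(synth_config(n_users = 120, seed = 4))
    st <- build_strata(daily_series(g$cohort$recordings))
  })
  g1 <- run_grid(st, algorithms = list(alg_1nn("ED"), alg_naive_bayes()))
  g2 <- run_grid(st, algorithms = list(alg_1nn("ED"), alg_naive_bayes()))
  expect_identical(as.data.frame(g1), as.data.frame(g2))
})

test_that("grid tables render retained, discarded and skipped cells", {
  withr::with_seed(95, {
    g <- generate_cohort(synth_config(n_users = 150, seed = 5))
    st <- build_strata(daily_series(g$cohort$recordings))
    grid <- run_grid(st, algorithms = list(alg_1nn("CID")))
  })
  tab <- grid_table(grid)
  expect_true("algorithm" %in% names(tab))
  cells <- unlist(tab[setdiff(names(tab), c("algorithm", "item"))])
  expect_true(all(is.na(cells) | cells %in% c("-", "x") |
                    grepl("^0\\.\\d{2}$|^1\\.00$", cells)))
})

test_that("the fixed baseline mode scores every entry against one prior", {
  withr::with_seed(99, {
    strata <- tibble::tibble(
      user_id = sprintf("u%02d", 1:20),
      item = "q1", k = 2L, n = 2L, fd = 2L, pooled = FALSE,
      series = replicate(20, runif(2), simplify = FALSE),
      label = factor(rep(c("No", "Yes"), 10), levels = c("No", "Yes"))
    )
  })
  grid <- run_grid(strata, algorithms = list(alg_1nn("ED")),
                   baseline = "fixed", fixed_baseline = 0.92)
  expect_equal(tidy(grid)$baseline, 0.92)
})
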