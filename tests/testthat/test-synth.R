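test_that("generation is a pure function of its configuration", {
  cfg <- synth_config(n_users = 60, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$recordings, b$cohort$recordings)
  expect_identical(a$cohort$registrations, b$cohort$registrations)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(synth_config(n_users = 60, seed = 43))
  expect_false(identical(a$cohort$recordings, c2$cohort$recordings))
})

test_that("degenerate configurations are rejected before generation", {
  expect_error(synth_config(p_respond = 0), "p_respond")
  expect_error(synth_config(p_stop = -0.1), "probabilities")
  expect_error(synth_config(first_run_probs = c(0.5, 0.4)), "summing to 1")
})

test_that("p_stop = 1 collapses every engaged first run to a single day", {
  g <- generate_cohort(synth_config(
    n_users = 150, seed = 5, first_run_probs = NULL, p_stop = 1
  ))
  expect_true(all(g$truth$first_run == 1))
  prof <- adherence_profiles(g$cohort$recordings)
  # non-returners break after day one; returners may show longer item-level
  # runs inside their second activity block
  expect_true(all(prof$first_days[prof$return == "No"] == 1))
})

test_that("every synthetic user has at least one EMA entry", {
  g <- generate_cohort(synth_config(n_users = 100, seed = 9))
  rec_users <- unique(g$cohort$recordings$user_id)
  expect_setequal(rec_users, g$cohort$registrations$user_id)
  expect_true(validate_cohort(g$cohort)$clean)
  # registration invariants hold by construction
  reg <- g$cohort$registrations
  both <- !is.na(reg$ageAtOnset) & !is.na(reg$ageAtRegistration)
  expect_true(all(reg$ageAtOnset[both] <= reg$ageAtRegistration[both]))
})

test_that("first-run lengths match the geometric model at scale", {
  g <- generate_cohort(synth_config(
    n_users = 2000, seed = 11, first_run_probs = NULL, p_stop = 0.55
  ))
  runs <- g$truth$first_run[!g$truth$single]
  m <- mean(runs)
  se <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(m - 1 / 0.55), 3 * se)
})

test_that("generated cohorts reproduce their configured rates at scale", {
  g <- generate_cohort(synth_config(n_users = 2000, seed = 12))
  truth <- g$truth
  # one-off fraction
  p_single_hat <- mean(truth$single)
  expect_lt(abs(p_single_hat - 0.34), 3 * sqrt(0.34 * 0.66 / 2000))
  # return rate by first-run stratum follows the configured profile
  prof <- default_p_return()
  for (k in 1:3) {
    sub <- truth[!truth$single & truth$first_run == k, ]
    se <- sqrt(prof[k] * (1 - prof[k]) / nrow(sub))
    expect_lt(abs(mean(sub$returned) - prof[k]), 3.5 * se)
  }
  # prompts per active day: 1 + Binomial(2, 0.6) has mean 2.2
  rec <- g$cohort$recordings
  per_day <- dplyr::count(
    dplyr::mutate(rec, day = as.Date(timestamp, tz = "UTC")),
    user_id, day
  )
  engaged <- truth$user_id[!truth$single]
  expect_lt(abs(mean(per_day$n[per_day$user_id %in% engaged]) - 2.2), 0.05)
})

test_that("the duration histogram is skewed with its mode at one day", {
  g <- generate_cohort(synth_config(n_users = 2000, seed = 13))
  prof <- adherence_profiles(g$cohort$recordings)
  h <- duration_histogram(prof)
  expect_equal(h$duration[which.max(h$n_users)], 1)
  # the count collapses after day one and a non-trivial 10+ tail remains
  expect_gt(h$n_users[1], 3 * max(h$n_users[-1]))
  expect_gt(sum(h$n_users[h$duration >= 10]), 0)
})

test_that("the adherence pipeline recovers the planted return labels", {
  g <- generate_cohort(synth_config(n_users = 400, seed = 14))
  prof <- adherence_profiles(g$cohort$recordings)
  joined <- dplyr::inner_join(prof, g$truth, by = "user_id")
  # the generative flag and the computed label agree wherever the first
  # break falls inside the horizon
  inside <- joined[joined$first_run < 30, ]
  expect_equal(as.character(inside$return) == "Yes", inside$returned)
})

test_that("a planted rule controls marginal, precision and recovery", {
  cond <- dplyr::bind_rows(
    rule_condition("tf5", "eq", 2), rule_condition("tf10", "eq", 0)
  )
  cfg <- plant_rule(synth_config(n_users = 2500, seed = 15), cond,
                    precision = 1, support = 0.02)
  g <- generate_cohort(cfg)
  reg <- g$cohort$registrations
  matched <- reg$tf5 == 2 & reg$tf10 == 0
  matched[is.na(matched)] <- FALSE
  expect_lt(abs(mean(matched) - 0.02), 3 * sqrt(0.02 * 0.98 / 2500))
  expect_true(all(g$truth$returned[matched]))
  expect_identical(which(matched), which(g$truth$rule_matched))
})

test_that("infeasible planted-rule targets are rejected", {
  cond <- rule_condition("tf5", "eq", 2)
  expect_error(plant_rule(synth_config(), cond, 1, 0), "positive")
  expect_error(plant_rule(synth_config(), cond, 0.5, 0.6), "infeasible")
})

test_that("a zero item effect leaves item-return association null", {
  cfg <- plant_item_effect(synth_config(n_users = 2000, seed = 16),
                           "q5", c(2, 4), 0)
  g <- generate_cohort(cfg)
  truth <- g$truth
  sub <- truth[!truth$single & truth$first_run >= 2 & truth$first_run <= 4, ]
  r <- cor(sub$q5_mu, sub$returned)
  expect_lt(abs(r), 3 / sqrt(nrow(sub)))
})

test_that("a strong q5 effect is recoverable and leaves q3 untouched", {
  hits_q5 <- 0
  hits_q3 <- 0
  for (s in 1:8) {
    cfg <- plant_item_effect(synth_config(n_users = 1200, seed = 100 + s),
                             "q5", c(2, 4), 8)
    truth <- generate_cohort(cfg)$truth
    sub <- truth[!truth$single & truth$first_run >= 2 &
                   truth$first_run <= 4, ]
    f5 <- glm(returned ~ q5_mu, binomial, data = sub)
    f3 <- glm(returned ~ q3_mu, binomial, data = sub)
    z5 <- summary(f5)$coefficients["q5_mu", "z value"]
    z3 <- summary(f3)$coefficients["q3_mu", "z value"]
    hits_q5 <- hits_q5 + (z5 > 2)
    hits_q3 <- hits_q3 + (abs(z3) > 2)
  }
  expect_gte(hits_q5, 7)
  expect_lte(hits_q3, 2)
})

test_that("unknown items cannot carry a planted effect", {
  expect_error(plant_item_effect(synth_config(), "q9", c(2, 4), 1),
               "unknown EMA item")
})
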