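test_that("lift is precision over the base rate, as in the printed tables", {
  base <- 465 / 842
  expect_equal(round_half_up(rule_lift(1.00, base)), 1.81)
  expect_equal(round_half_up(rule_lift(0.74, base)), 1.34)
  expect_equal(round_half_up(rule_lift(0.64, base)), 1.16)
  expect_equal(round_half_up(rule_lift(0.93, base)), 1.68)
})

test_that("rule metrics follow the support/precision/lift identities", {
  feats <- tibble::tibble(
    a = factor(c(2, 2, 2, 0, 0, 1, 1, 1, 0, 2)),
    b = factor(c(1, 1, 0, 0, 1, 1, 0, 0, 1, 1))
  )
  labels <- c("Yes", "Yes", "No", "No", "Yes", "No", "No", "Yes", "Yes", "No")
  m <- rule_metrics(rule_condition("a", "eq", 2), feats, labels)
  expect_equal(m$n_matched, 4L)
  expect_equal(m$support, 2 / 10)
  expect_equal(m$precision, 2 / 4)
  expect_equal(m$lift, (2 / 4) / (5 / 10))
  # an antecedent matching everything has precision = P(Yes) and lift 1
  all_m <- rule_metrics(
    rule_condition("a", "eq", 2),
    tibble::tibble(a = factor(rep(2, 10))), labels
  )
  expect_equal(all_m$precision, 0.5)
  expect_equal(all_m$lift, 1)
  expect_error(
    rule_metrics(rule_condition("b", "eq", 7), feats, labels),
    "no rows"
  )
})

test_that("the exact p-value matches the hypergeometric closed form", {
  # 10 matched, all Yes, background 50/50 of 100
  expect_equal(rule_pvalue(10, 10, 50, 100),
               choose(50, 10) / choose(100, 10))
  # the whole population as antecedent is never enriched
  expect_equal(rule_pvalue(50, 100, 50, 100), 1)
  # class ratio equal to the background: no enrichment signal
  expect_gt(rule_pvalue(5, 10, 50, 100), 0.5)
})

test_that("the exact p-value equals the one-sided Fisher test", {
  withr::with_seed(100, {
    for (i in 1:20) {
      n <- 60
      n_yes <- sample(10:50, 1)
      n_m <- sample(1:n, 1)
      a <- sample(max(0, n_m + n_yes - n):min(n_m, n_yes), 1)
      tab <- matrix(c(a, n_m - a, n_yes - a, n - n_m - n_yes + a), 2)
      expect_equal(
        rule_pvalue(a, n_m, n_yes, n),
        stats::fisher.test(tab, alternative = "greater")$p.value
      )
    }
  })
})

planted_table <- function(n = 600, seed = 1) {
  withr::with_seed(seed, {
    feats <- tibble::tibble(
      a = factor(sample(0:2, n, TRUE)),
      b = factor(sample(0:2, n, TRUE)),
      c = factor(sample(0:1, n, TRUE))
    )
    labels <- sample(c("Yes", "No"), n, TRUE)
    # plant: a = 2 & b = 0 implies Yes, deterministically
    hit <- feats$a == "2" & feats$b == "0"
    labels[hit] <- "Yes"
    list(feats = feats, labels = labels, hit = hit)
  })
}

test_that("a deterministic planted rule is recovered with precision 1", {
  p <- planted_table()
  rules <- hotspot_induce(p$feats, p$labels)
  target <- rules[rules$rule == "a = 2 & b = 0", ]
  expect_equal(nrow(target), 1)
  expect_equal(target$precision, 1)
  expect_equal(target$n_matched, sum(p$hit))
  expect_lt(target$p_value, 0.05)
  # the identity lift = precision / P(Yes) holds to machine precision
  expect_equal(rules$lift, rules$precision / attr(rules, "base_rate"))
  # sorted by lift, then precision, then support, descending
  expect_true(all(diff(rules$lift) <= 1e-12))
})

test_that("rule length is capped by the configuration", {
  p <- planted_table()
  r1 <- hotspot_induce(p$feats, p$labels, mining_config(max_length = 1))
  expect_true(all(r1$length == 1))
})

test_that("support never increases when a condition is added", {
  p <- planted_table(n = 300, seed = 7)
  rules <- hotspot_induce(p$feats, p$labels,
                          mining_config(alpha = 1, min_support = 0.02))
  two <- rules[rules$length == 2, ]
  one <- rules[rules$length == 1, ]
  for (i in seq_len(nrow(two))) {
    conds <- two$conditions[[i]]
    for (j in 1:2) {
      parent <- rule_metrics(conds[j, ], p$feats, p$labels)
      expect_lte(two$support[i], parent$support + 1e-12)
    }
  }
})

test_that("rules over identical user sets are kept but share an id", {
  feats <- tibble::tibble(
    a = factor(c(rep(1, 8), rep(0, 12))),
    b = factor(c(rep(1, 8), rep(2, 12)))
  )
  labels <- c(rep("Yes", 8), rep(c("Yes", "No"), 6))
  rules <- hotspot_induce(feats, labels,
                          mining_config(min_support = 0.05, alpha = 0.5))
  a_rule <- rules[rules$rule == "a = 1", ]
  b_rule <- rules[rules$rule == "b = 1", ]
  expect_equal(nrow(a_rule), 1)
  expect_equal(nrow(b_rule), 1)
  expect_equal(a_rule$matched_set, b_rule$matched_set)
})

test_that("label-independent attributes rarely yield significant rules", {
  withr::with_seed(123, {
    n_pass <- replicate(10, {
      n <- 800
      feats <- tibble::tibble(
        a = factor(sample(0:1, n, TRUE)),
        b = factor(sample(0:1, n, TRUE)),
        c = factor(sample(0:1, n, TRUE))
      )
      labels <- sample(c("Yes", "No"), n, TRUE)
      nrow(hotspot_induce(feats, labels, mining_config(min_support = 0.05)))
    })
    # the support floor plus the exact test keep null discoveries rare,
    # though the uncorrected alpha admits the occasional lone rule
    expect_gte(sum(n_pass == 0), 4)
    expect_lte(mean(n_pass), 1.5)
  })
})

test_that("numeric attributes mine thresholds in both directions", {
  withr::with_seed(11, {
    n <- 400
    feats <- tibble::tibble(age = sample(20:80, n, TRUE))
    labels <- ifelse(feats$age > 65 & runif(n) < 0.9, "Yes",
                     sample(c("Yes", "No"), n, TRUE))
  })
  rules <- hotspot_induce(feats, labels)
  expect_gt(nrow(rules), 0)
  expect_true(any(grepl("^age > 6", rules$rule)))
})

test_that("complete cases only: rows with missing attributes are dropped", {
  feats <- tibble::tibble(
    a = factor(c(1, 1, NA, 0, 0, 1, 0, 1)),
    b = factor(c(0, NA, 1, 1, 0, 0, 1, 1))
  )
  labels <- rep(c("Yes", "No"), 4)
  expect_message(
    rules <- hotspot_induce(feats, labels, mining_config(alpha = 1)),
    "Dropped 2"
  )
  expect_equal(attr(rules, "n_total"), 6)
})

test_that("NumDays is the horizon-free day count", {
  prof <- tibble::tibble(user_id = c("a", "b"), num_days = c(31L, 1L))
  nd <- numdays_features(prof)
  expect_equal(nd$NumDays, c(31, 1))
  # against a brute-force scan of a fixture
  rec <- make_recordings(data.frame(
    user = "a", day = c(1:31, 40), q2 = runif(32)
  ))
  prof2 <- adherence_profiles(rec)
  expect_equal(numdays_features(prof2)$NumDays, 32)
})

test_that("rounded reporting reproduces the published arithmetic", {
  rendered <- render_rules(structure(
    tibble::tibble(
      rule = "x = 1", length = 1L, support = 0.0551, precision = 0.7449,
      lift = 0.7449 / (465 / 842), p_value = 0.001, n_matched = 46L,
      matched_set = 1L, conditions = list(rule_condition("x", "eq", 1))
    ),
    class = c("ema_rules", class(tibble::tibble())),
    base_rate = 465 / 842, n_total = 842, n_dropped_incomplete = 0,
    config = mining_config()
  ))
  expect_equal(rendered$support, 0.06)
  expect_equal(rendered$precision, 0.74)
  expect_equal(rendered$lift, 1.35)
})
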