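#' Default return-probability profile by first-run length
#'
#' The probability of returning after the first break varies strongly with
#' how long the first run lasted: users who broke after a single day mostly
#' come back, the majority reverses by day two, and long uninterrupted runs
#' almost always end for good. This default profile is indexed by
#' `min(first_run, 10)`.
#'
#' @return Numeric vector of length 10.
#' @export
default_p_return <- function() {
  c(
    158 / 180, 97 / 184, 35 / 93, 22 / 70, 12 / 52,
    3 / 37, 2 / 34, 3 / 37, 4 / 56, 41 / 99
  )
}

#' Default first-run length profile of engaged users
#'
#' Probability of each days-until-first-break value among users with more
#' than one recording; the last entry is the pooled mass of runs of ten or
#' more days. One-off visitors are governed by `p_single` instead.
#'
#' @return Numeric vector of length 10 summing to 1.
#' @export
default_first_run_probs <- function() {
  c(180, 184, 93, 70, 52, 37, 34, 37, 56, 99) / 842
}

#' Synthetic cohort configuration
#'
#' Parameters of the generative model behind [generate_cohort()]. A user is
#' either a one-off visitor (probability `p_single`: one answered prompt on
#' one day, never returns — the dominant mass of the heavily right-skewed
#' duration distribution) or an engaged user whose behaviour is: a first run
#' of adjacent active days of length `1 + Geometric(p_stop)` (so `p_stop` is
#' the mass at a single day), a Bernoulli return-after-break decision whose
#' baseline probability depends on the first-run length through `p_return`
#' (optionally shifted on the log-odds scale by planted effects), and — for
#' returners — a break of `1 + Geometric(p_gap)` days followed by a second
#' run of `1 + Geometric(p_stop_return)` adjacent days. On each active day
#' the user answers `1 + Binomial(prompts_per_day - 1, p_respond)` prompts;
#' within a prompt each item is skipped independently with probability
#' `item_skip` (one random item is kept if all would be skipped, since an
#' unanswered prompt is no EMA entry). VAS answers fluctuate around a
#' per-user latent level drawn from `Beta(item_shape1, item_shape2)` with
#' Gaussian noise `value_noise_sd`, clipped to `[0, 1]`; `q1` answers are
#' Bernoulli draws from a per-user latent rate with the same prior.
#'
#' @param n_users Number of users (default 800).
#' @param seed Integer seed; generation is a pure function of the config.
#' @param prompts_per_day Daily prompt count (default 3).
#' @param p_respond Per-prompt response probability beyond the first
#'   guaranteed one (default 0.6); must be positive.
#' @param p_single Probability of a one-off visitor (default 0.34).
#' @param first_run_probs Distribution of the engaged users' first-run
#'   length over `1..length(first_run_probs)` days; the last mass continues
#'   with a geometric(`p_stop`) tail. Default [default_first_run_probs()].
#'   `NULL` selects a pure shifted-geometric run length
#'   `1 + Geometric(p_stop)`.
#' @param p_stop Geometric stop parameter: the whole first-run distribution
#'   when `first_run_probs` is `NULL`, otherwise only its tail beyond the
#'   profile (default 0.55).
#' @param p_return Return probability after the first break: either a scalar
#'   (constant across first-run lengths) or a vector indexed by
#'   `min(first_run, length(p_return))`; default [default_p_return()].
#' @param p_gap Geometric parameter of the break length (default 0.5).
#' @param p_stop_return Geometric stop parameter of the post-return run
#'   (default 0.3).
#' @param item_skip Per-item skip probability within a prompt (default 0.1).
#' @param item_shape1,item_shape2 Beta prior of the per-user latent item
#'   levels (default 2, 2).
#' @param value_noise_sd Within-user day-to-day noise of VAS answers
#'   (default 0.1).
#' @param minitf_probs Category probabilities of the MiniTF items over codes
#'   0/1/2 (default uniform).
#' @param minitf_missing,tschq_missing Missing-cell rates of the registration
#'   tables (defaults 0.03 and 0.05).
#' @param start_window Users start uniformly within this many days of
#'   `epoch` (default 365).
#' @param epoch First possible calendar start date.
#' @param item_effects List of planted item effects (see
#'   [plant_item_effect()]).
#' @param planted_rule Planted registration rule (see [plant_rule()]).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_users = 800L, seed = 1L, prompts_per_day = 3L,
                         p_respond = 0.6, p_single = 0.34,
                         first_run_probs = default_first_run_probs(),
                         p_stop = 0.55,
                         p_return = default_p_return(),
                         p_gap = 0.5, p_stop_return = 0.3, item_skip = 0.1,
                         item_shape1 = 2, item_shape2 = 2,
                         value_noise_sd = 0.1,
                         minitf_probs = c(1, 1, 1) / 3,
                         minitf_missing = 0.03, tschq_missing = 0.05,
                         start_window = 365L,
                         epoch = as.Date("2014-04-10"),
                         item_effects = list(), planted_rule = NULL) {
  probs <- c(p_respond, p_single, p_stop, p_return, p_gap, p_stop_return,
             item_skip, minitf_missing, tschq_missing)
  if (length(p_return) < 1) abort("`p_return` must have at least one entry")
  if (!is.null(first_run_probs)) {
    if (any(first_run_probs < 0) || abs(sum(first_run_probs) - 1) > 1e-8) {
      abort("`first_run_probs` must be probabilities summing to 1")
    }
  }
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (p_respond == 0) abort("degenerate config: p_respond = 0 generates no prompts")
  if (p_stop <= 0 || p_gap <= 0 || p_stop_return <= 0) {
    abort("geometric parameters must be positive")
  }
  if (n_users < 1) abort("`n_users` must be >= 1")
  if (length(minitf_probs) != 3 || abs(sum(minitf_probs) - 1) > 1e-8) {
    abort("`minitf_probs` must be three probabilities summing to 1")
  }
  structure(
    list(
      n_users = as.integer(n_users), seed = as.integer(seed),
      prompts_per_day = as.integer(prompts_per_day), p_respond = p_respond,
      p_single = p_single, first_run_probs = first_run_probs,
      p_stop = p_stop, p_return = p_return, p_gap = p_gap,
      p_stop_return = p_stop_return, item_skip = item_skip,
      item_shape1 = item_shape1, item_shape2 = item_shape2,
      value_noise_sd = value_noise_sd, minitf_probs = minitf_probs,
      minitf_missing = minitf_missing, tschq_missing = tschq_missing,
      start_window = as.integer(start_window), epoch = as.Date(epoch),
      item_effects = item_effects, planted_rule = planted_rule
    ),
    class = "synth_config"
  )
}

#' Plant a registration rule into a synthetic cohort
#'
#' Adds a sub-population of expected marginal probability
#' `support / precision` whose members carry the antecedent attribute values
#' and return after their first break with probability `precision`;
#' non-members are resampled away from the antecedent so the measured
#' precision of the planted antecedent matches the target in expectation.
#'
#' @param config A [synth_config()].
#' @param conditions Condition tibble ([rule_condition()] rows) over
#'   registration attributes.
#' @param precision Target precision in `(0, 1]`.
#' @param support Target support in `(0, precision]` (so the implied match
#'   probability is a valid probability).
#' @return The modified config.
#' @export
plant_rule <- function(config, conditions, precision, support) {
  stopifnot(inherits(config, "synth_config"))
  if (support <= 0) abort("`support` must be positive")
  if (precision <= 0 || precision > 1) abort("`precision` must lie in (0, 1]")
  if (support > precision) {
    abort("infeasible: `support` may not exceed `precision`")
  }
  config$planted_rule <- list(
    conditions = as_tibble(conditions), precision = precision,
    support = support, p_match = support / precision
  )
  config
}

#' Plant an early-interaction item effect
#'
#' For users whose first run length falls in `k_range`, shifts the log-odds
#' of returning by `beta * (m - 0.5)`, where `m` is the user's realised mean
#' daily value of `item` over the first run (0.5, the latent prior mean, if
#' the item was never answered). This couples the return label to exactly the
#' values a stratum classifier sees.
#'
#' @param config A [synth_config()].
#' @param item EMA item name (`"q1"`..`"q7"`).
#' @param k_range Integer range `c(min, max)` of first-run lengths affected.
#' @param beta Effect size on the return log-odds per unit of item mean.
#' @return The modified config.
#' @export
plant_item_effect <- function(config, item, k_range, beta) {
  stopifnot(inherits(config, "synth_config"))
  if (!item %in% ema_items()) abort("unknown EMA item")
  k_range <- as.integer(range(k_range))
  config$item_effects <- c(
    config$item_effects,
    list(list(item = item, k_min = k_range[1], k_max = k_range[2],
              beta = beta))
  )
  config
}

draw_registrations <- function(config) {
  n <- config$n_users
  ids <- sprintf("u%05d", seq_len(n))
  tf <- matrix(
    sample(0:2, 12 * n, replace = TRUE, prob = config$minitf_probs),
    nrow = n
  )
  tf[matrix(runif(12 * n) < config$minitf_missing, nrow = n)] <- NA_integer_
  # demographics loosely shaped like an adult tinnitus app cohort
  age_reg <- pmin(pmax(round(rnorm(n, 44, 13)), 18), 90)
  years_since <- pmin(round(rgamma(n, shape = 0.8, scale = 11)), age_reg - 1)
  age_onset <- pmax(age_reg - years_since, 0)
  reg <- tibble(
    user_id = ids,
    sex = sample(c(1L, 2L), n, replace = TRUE, prob = c(0.28, 0.72)),
    ageAtRegistration = as.numeric(age_reg),
    ageAtOnset = as.numeric(age_onset),
    onsetrelation = sample(1:5, n, replace = TRUE),
    familyHistory = sample(1:2, n, replace = TRUE, prob = c(0.3, 0.7)),
    variability = sample(1:4, n, replace = TRUE)
  )
  for (tf_i in seq_len(12)) reg[[paste0("tf", tf_i)]] <- tf[, tf_i]
  for (f in tschq_fields()) {
    miss <- runif(n) < config$tschq_missing
    reg[[f]][miss] <- NA
  }
  reg$minitf_score <- ifelse(
    rowSums(is.na(reg[minitf_items()])) == 0,
    rowSums(reg[minitf_items()]), NA_real_
  )
  reg
}

force_condition <- function(reg, i, cond, satisfy) {
  col <- cond$attribute
  val <- cond$value
  if (cond$kind == "eq") {
    typed <- if (is.numeric(reg[[col]])) {
      v <- as.numeric(val)
      if (is.integer(reg[[col]])) as.integer(v) else v
    } else {
      val
    }
    if (satisfy) {
      reg[[col]][i] <- typed
    } else {
      domain <- unique(stats::na.omit(reg[[col]]))
      alt <- setdiff(domain, typed)
      if (length(alt) > 0) reg[[col]][i] <- sample(rep(alt, 2), 1)
    }
  } else {
    v <- as.numeric(val)
    cur <- reg[[col]][i]
    above <- cond$kind == "gt"
    if (!satisfy) above <- !above
    if (above) {
      reg[[col]][i] <- max(cur, v + 1, na.rm = TRUE)
    } else {
      reg[[col]][i] <- min(cur, v, na.rm = TRUE)
    }
  }
  reg
}

apply_planted_rule <- function(reg, config) {
  pr <- config$planted_rule
  if (is.null(pr)) {
    return(list(reg = reg, matched = rep(FALSE, nrow(reg)),
                forced_return = rep(NA, nrow(reg))))
  }
  n <- nrow(reg)
  matched <- runif(n) < pr$p_match
  nc <- nrow(pr$conditions)
  for (i in which(matched)) {
    for (ci in seq_len(nc)) {
      reg <- force_condition(reg, i, pr$conditions[ci, ], satisfy = TRUE)
    }
  }
  # keep the antecedent's marginal at p_match: background users matching by
  # chance are nudged off the first condition
  bg_mask <- conditions_mask(reg, pr$conditions)
  bg_mask[is.na(bg_mask)] <- FALSE
  for (i in which(bg_mask & !matched)) {
    reg <- force_condition(reg, i, pr$conditions[1, ], satisfy = FALSE)
  }
  if (any(matched)) {
    # matched users must be complete cases on the mined attributes
    for (col in unique(pr$conditions$attribute)) {
      nas <- matched & is.na(reg[[col]])
      if (any(nas)) reg[[col]][nas] <- reg[[col]][which(matched)[1]]
    }
    reg$minitf_score <- ifelse(
      rowSums(is.na(reg[minitf_items()])) == 0,
      rowSums(reg[minitf_items()]), NA_real_
    )
  }
  forced <- rep(NA, n)
  forced[matched] <- runif(sum(matched)) < pr$precision
  list(reg = reg, matched = matched, forced_return = forced)
}

#' Generate a synthetic EMA cohort with ground truth
#'
#' Realises the processes described under [synth_config()]: byte-identical
#' for a given config (including its seed), every user has at least one EMA
#' entry, and `export_end` is placed one horizon beyond the last recording so
#' no synthetic user is right-censored.
#'
#' @param config A [synth_config()].
#' @param horizon A [horizon_config()]; only used to place `export_end`.
#' @return A list with `cohort` (an [ema_cohort()]) and `truth`, a tibble
#'   holding per user: `first_run`, `returned` (the generative flag),
#'   `gap`, `second_run`, `rule_matched`, and the latent item levels
#'   `q1_rate`, `q2_mu`..`q7_mu`.
#' @export
generate_cohort <- function(config, horizon = horizon_config()) {
  stopifnot(inherits(config, "synth_config"))
  horizon <- as_horizon(horizon)
  withr::with_seed(config$seed, generate_cohort_impl(config, horizon))
}

generate_cohort_impl <- function(config, horizon) {
  n <- config$n_users
  reg <- draw_registrations(config)
  planted <- apply_planted_rule(reg, config)
  reg <- planted$reg

  start_offset <- sample.int(config$start_window, n, replace = TRUE) - 1L
  single <- runif(n) < config$p_single
  # planted-rule members follow their forced return coin, so they are always
  # engaged users
  single[planted$matched] <- FALSE
  first_run <- if (is.null(config$first_run_probs)) {
    1L + rgeom(n, config$p_stop)
  } else {
    L <- length(config$first_run_probs)
    f <- sample.int(L, n, replace = TRUE, prob = config$first_run_probs)
    ifelse(f == L, L + rgeom(n, config$p_stop), f)
  }
  first_run <- ifelse(single, 1L, first_run)
  latent_q1 <- rbeta(n, config$item_shape1, config$item_shape2)
  latent_vas <- matrix(rbeta(6L * n, config$item_shape1, config$item_shape2),
                       nrow = n)
  colnames(latent_vas) <- paste0("q", 2:7)

  user_vec <- list(); ts_vec <- list()
  vals <- lapply(ema_items(), function(i) list())
  names(vals) <- ema_items()
  returned <- logical(n); gaps <- rep(NA_integer_, n)
  second_run <- rep(NA_integer_, n)

  gen_days <- function(u, day_offsets, one_prompt = FALSE) {
    n_days <- length(day_offsets)
    out_user <- character(0); out_ts <- numeric(0)
    out_vals <- matrix(NA_real_, nrow = 0, ncol = 7)
    day_means <- matrix(NA_real_, nrow = n_days, ncol = 7)
    for (d in seq_len(n_days)) {
      n_rec <- if (one_prompt) {
        1L
      } else {
        1L + rbinom(1L, config$prompts_per_day - 1L, config$p_respond)
      }
      hours <- sort(runif(n_rec, 8, 22))
      day_date <- config$epoch + start_offset[u] + day_offsets[d]
      stamps <- as.numeric(as.POSIXct(day_date, tz = "UTC")) + hours * 3600
      rec_vals <- matrix(NA_real_, nrow = n_rec, ncol = 7)
      for (r in seq_len(n_rec)) {
        keep <- runif(7) >= config$item_skip
        if (!any(keep)) keep[sample.int(7, 1)] <- TRUE
        if (keep[1]) rec_vals[r, 1] <- rbinom(1L, 1L, latent_q1[u])
        for (j in 2:7) {
          if (keep[j]) {
            rec_vals[r, j] <- pmin(pmax(
              latent_vas[u, j - 1] + rnorm(1L, 0, config$value_noise_sd), 0
            ), 1)
          }
        }
      }
      day_means[d, ] <- colMeans(rec_vals, na.rm = TRUE)
      out_user <- c(out_user, rep(reg$user_id[u], n_rec))
      out_ts <- c(out_ts, stamps)
      out_vals <- rbind(out_vals, rec_vals)
    }
    list(user = out_user, ts = out_ts, vals = out_vals, day_means = day_means)
  }

  p_ret_base <- function(f) {
    config$p_return[min(f, length(config$p_return))]
  }

  for (u in seq_len(n)) {
    f <- first_run[u]
    run1 <- gen_days(u, seq_len(f) - 1L, one_prompt = single[u])

    eta <- qlogis(p_ret_base(f))
    for (eff in config$item_effects) {
      if (f >= eff$k_min && f <= eff$k_max) {
        j <- match(eff$item, ema_items())
        m <- mean(run1$day_means[, j], na.rm = TRUE)
        if (is.nan(m)) m <- 0.5
        eta <- eta + eff$beta * (m - 0.5)
      }
    }
    ret <- if (single[u]) {
      FALSE
    } else if (!is.na(planted$forced_return[u])) {
      planted$forced_return[u]
    } else {
      runif(1) < plogis(eta)
    }
    returned[u] <- ret

    parts <- list(run1)
    if (ret) {
      gaps[u] <- 1L + rgeom(1L, config$p_gap)
      second_run[u] <- 1L + rgeom(1L, config$p_stop_return)
      offsets2 <- f + gaps[u] + seq_len(second_run[u]) - 1L
      parts[[2]] <- gen_days(u, offsets2)
    }
    for (p in parts) {
      user_vec[[length(user_vec) + 1L]] <- p$user
      ts_vec[[length(ts_vec) + 1L]] <- p$ts
      for (j in seq_len(7)) {
        vals[[j]][[length(vals[[j]]) + 1L]] <- p$vals[, j]
      }
    }
  }

  recordings <- tibble(
    user_id = unlist(user_vec),
    timestamp = as.POSIXct(unlist(ts_vec), origin = "1970-01-01", tz = "UTC")
  )
  for (j in seq_len(7)) recordings[[ema_items()[j]]] <- unlist(vals[[j]])
  recordings <- arrange(recordings, .data$user_id, .data$timestamp)

  export_end <- max(as.Date(recordings$timestamp, tz = "UTC")) + horizon$n
  cohort <- ema_cohort(recordings, reg, export_end)

  truth <- tibble(
    user_id = reg$user_id,
    single = single,
    first_run = as.integer(first_run),
    returned = returned,
    gap = gaps,
    second_run = second_run,
    rule_matched = planted$matched,
    q1_rate = latent_q1
  )
  for (j in 2:7) truth[[paste0("q", j, "_mu")]] <- latent_vas[, j - 1]
  list(cohort = cohort, truth = truth)
}
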