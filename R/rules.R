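#' Rule-mining configuration
#'
#' Constraints of the breadth-limited rule search: minimum rule support
#' (joint probability of antecedent and consequent), maximum antecedent
#' length, maximum number of child expansions kept per rule, minimum gain in
#' precision a child must achieve over its parent, and the (uncorrected)
#' significance level of the one-sided exact test.
#'
#' @param min_support Support lower boundary (default 0.01).
#' @param max_length Maximum antecedent length (default 2).
#' @param max_children Maximum child rules per parent (default 800).
#' @param min_precision_gain Minimum precision gain of a child over its
#'   parent (default 0.01).
#' @param alpha Significance level, without multiple-testing correction
#'   (default 0.05).
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(min_support = 0.01, max_length = 2L,
                          max_children = 800L, min_precision_gain = 0.01,
                          alpha = 0.05) {
  if (min_support <= 0) abort("`min_support` must be positive")
  if (max_length < 1) abort("`max_length` must be >= 1")
  if (max_children < 1) abort("`max_children` must be >= 1")
  if (min_precision_gain < 0) abort("`min_precision_gain` must be >= 0")
  structure(
    list(
      min_support = min_support, max_length = as.integer(max_length),
      max_children = as.integer(max_children),
      min_precision_gain = min_precision_gain, alpha = alpha
    ),
    class = "mining_config"
  )
}

#' A single antecedent condition
#'
#' Categorical attributes support equality tests; numeric attributes support
#' `>` and `<=` thresholds drawn from the observed values.
#'
#' @param attribute Attribute (column) name.
#' @param kind One of `"eq"`, `"gt"`, `"le"`.
#' @param value Category label (for `eq`) or numeric threshold.
#' @return A one-row tibble with columns `attribute`, `kind`, `value`.
#' @export
rule_condition <- function(attribute, kind = c("eq", "gt", "le"), value) {
  kind <- match.arg(kind)
  tibble(attribute = attribute, kind = kind, value = as.character(value))
}

condition_mask <- function(features, cond) {
  col <- features[[cond$attribute]]
  if (is.null(col)) abort(sprintf("unknown attribute '%s'", cond$attribute))
  switch(cond$kind,
    eq = as.character(col) == cond$value,
    gt = as.numeric(col) > as.numeric(cond$value),
    le = as.numeric(col) <= as.numeric(cond$value)
  )
}

conditions_mask <- function(features, conditions) {
  masks <- lapply(seq_len(nrow(conditions)), function(i) {
    condition_mask(features, conditions[i, ])
  })
  Reduce(`&`, masks)
}

render_condition <- function(attribute, kind, value) {
  op <- c(eq = "=", gt = ">", le = "<=")[[kind]]
  sprintf("%s %s %s", attribute, op, value)
}

render_antecedent <- function(conditions) {
  paste(
    mapply(render_condition, conditions$attribute, conditions$kind,
           conditions$value),
    collapse = " & "
  )
}

#' Support, precision and lift of a rule
#'
#' For the consequent `Return = Yes`: `support` is the joint probability of
#' matching the antecedent and returning, `precision` the return rate among
#' antecedent matches, and `lift` the precision relative to the population
#' base rate `P(Yes)`. Rows with missing values in any analysed attribute
#' must be removed beforehand (the mining entry point does this).
#'
#' @param conditions A condition tibble ([rule_condition()] rows).
#' @param features Complete-case feature tibble.
#' @param labels `Return` labels (`"Yes"`/`"No"`, factor or character, or
#'   logical where `TRUE` means Yes).
#' @return A one-row tibble: `support`, `precision`, `lift`, `n_matched`.
#' @export
rule_metrics <- function(conditions, features, labels) {
  h <- as_yes(labels)
  m <- conditions_mask(features, conditions)
  n <- length(h)
  n_matched <- sum(m)
  if (n_matched == 0) {
    abort("antecedent matches no rows; precision is undefined")
  }
  support <- sum(m & h) / n
  precision <- sum(m & h) / n_matched
  tibble(
    support = support, precision = precision,
    lift = rule_lift(precision, mean(h)), n_matched = n_matched
  )
}

#' @rdname rule_metrics
#' @param precision Rule precision `P(Yes | antecedent)`.
#' @param base_rate Population base rate `P(Yes)`.
#' @return [rule_lift()]: the ratio `precision / base_rate`.
#' @export
rule_lift <- function(precision, base_rate) {
  if (any(base_rate <= 0)) abort("`base_rate` must be positive")
  precision / base_rate
}

as_yes <- function(labels) {
  if (is.logical(labels)) return(labels)
  as.character(labels) == "Yes"
}

#' One-sided exact enrichment p-value of a rule
#'
#' Hypergeometric tail probability of the 2x2 table (antecedent membership by
#' `Return`), testing enrichment of `Return = Yes` among matches — the
#' one-sided Fisher exact test. Degenerate margins give `p = 1`.
#'
#' @param n_matched_yes Matches with `Return = Yes`.
#' @param n_matched Total antecedent matches (at least 1).
#' @param n_yes Total `Return = Yes` in the population.
#' @param n_total Population size.
#' @return p-value in `(0, 1]`.
#' @export
rule_pvalue <- function(n_matched_yes, n_matched, n_yes, n_total) {
  stopifnot(n_matched >= 1, n_matched <= n_total, n_yes <= n_total)
  phyper(n_matched_yes - 1, n_yes, n_total - n_yes, n_matched,
         lower.tail = FALSE)
}

enumerate_conditions <- function(features) {
  conds <- list()
  for (attr in names(features)) {
    col <- features[[attr]]
    if (is.numeric(col)) {
      vals <- sort(unique(col))
      # "> max" matches nothing and is dropped; every other observed value
      # yields both directions, so adjacent thresholds can coexist
      for (v in vals) {
        if (v < max(vals)) {
          conds[[length(conds) + 1L]] <- list(attribute = attr, kind = "gt",
                                              value = as.character(v))
        }
        conds[[length(conds) + 1L]] <- list(attribute = attr, kind = "le",
                                            value = as.character(v))
      }
    } else {
      for (v in sort(unique(as.character(col)))) {
        conds[[length(conds) + 1L]] <- list(attribute = attr, kind = "eq",
                                            value = v)
      }
    }
  }
  conds
}

#' Induce classification rules for `Return = Yes`
#'
#' Breadth-limited greedy search over mixed categorical/numeric antecedents
#' in the style of hot-spot rule discovery. Level 1 enumerates every single
#' condition (categorical equalities; `>` and `<=` at every distinct observed
#' numeric value) whose rule support reaches `min_support`. Each surviving
#' rule is expanded by one further condition; at most `max_children`
#' candidate expansions (ranked by precision) are kept per parent, and every
#' expansion must improve precision over its parent by at least
#' `min_precision_gain`. The final list is filtered by the one-sided exact
#' test at `alpha`, deduplicated on exact condition sets only (rules matching
#' identical user sets are kept and share a `matched_set` id), and sorted by
#' lift, then precision, then support, all descending.
#'
#' Rows with a missing value in any analysed attribute are removed first; the
#' base rate `P(Yes)` is computed on the remaining complete-case population.
#'
#' @param features Feature tibble (factors/characters mine as categorical,
#'   numerics as thresholds; see [registration_features()]).
#' @param labels `Return` labels parallel to `features` rows.
#' @param config A [mining_config()].
#' @return A tibble of class `ema_rules`: `rule`, `length`, `support`,
#'   `precision`, `lift`, `p_value`, `n_matched`, `matched_set`, plus a
#'   `conditions` list column; attributes `base_rate`, `n_total`,
#'   `n_dropped_incomplete`, `config`.
#' @export
hotspot_induce <- function(features, labels, config = mining_config()) {
  stopifnot(inherits(config, "mining_config"))
  features <- as_tibble(features)
  features$user_id <- NULL
  h_all <- as_yes(labels)
  keep <- stats::complete.cases(features) & !is.na(h_all)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d row(s) with missing values", n_dropped))
  }
  features <- features[keep, , drop = FALSE]
  h <- h_all[keep]
  n <- length(h)
  empty <- empty_rules(base_rate = NA_real_, n_total = n,
                       n_dropped = n_dropped, config = config)
  if (n == 0) return(empty)
  base_rate <- mean(h)

  conds <- enumerate_conditions(features)
  C <- length(conds)
  if (C == 0) return(empty_rules(base_rate, n, n_dropped, config))
  M <- matrix(FALSE, nrow = n, ncol = C)
  for (j in seq_len(C)) {
    M[, j] <- condition_mask(features, as_tibble(conds[[j]]))
  }
  n_match <- colSums(M)
  n_match_yes <- colSums(M & h)
  supp <- n_match_yes / n
  prec <- ifelse(n_match > 0, n_match_yes / n_match, NA_real_)

  level1 <- which(supp >= config$min_support & n_match >= 1)
  rules <- lapply(level1, function(j) {
    list(ids = j, n_matched = n_match[j], n_matched_yes = n_match_yes[j],
         support = supp[j], precision = prec[j])
  })

  if (config$max_length >= 2 && length(level1) > 0) {
    # pair counts via cross-products: A_all[i, j] = |rows matching i and j|
    Mnum <- M * 1
    A_all <- crossprod(Mnum)
    A_yes <- crossprod(Mnum, Mnum * h)
    seen <- new.env(hash = TRUE)
    attrs <- vapply(conds, `[[`, "", "attribute")
    kinds <- vapply(conds, `[[`, "", "kind")
    for (p in level1) {
      cand <- setdiff(seq_len(C), p)
      # two equalities on one attribute are contradictory by construction
      cand <- cand[!(attrs[cand] == attrs[p] & kinds[cand] == "eq" &
                       kinds[p] == "eq")]
      if (length(cand) == 0) next
      nm2 <- A_all[p, cand]
      a2 <- A_yes[p, cand]
      stopifnot(all(nm2 <= n_match[p])) # support anti-monotonicity
      s2 <- a2 / n
      p2 <- ifelse(nm2 > 0, a2 / nm2, NA_real_)
      ok <- nm2 >= 1 & s2 >= config$min_support &
        p2 >= prec[p] + config$min_precision_gain
      cand <- cand[ok]
      if (length(cand) == 0) next
      ord <- order(-p2[ok])
      cand <- cand[ord][seq_len(min(length(cand), config$max_children))]
      for (q in cand) {
        key <- paste(sort(c(p, q)), collapse = "|")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        rules[[length(rules) + 1L]] <- list(
          ids = sort(c(p, q)), n_matched = A_all[p, q],
          n_matched_yes = A_yes[p, q],
          support = A_yes[p, q] / n, precision = A_yes[p, q] / A_all[p, q]
        )
      }
    }
  }

  if (length(rules) == 0) return(empty_rules(base_rate, n, n_dropped, config))
  tab <- tibble(
    conditions = map(rules, function(r) {
      bind_rows(lapply(conds[r$ids], as_tibble))
    }),
    length = map_int(rules, function(r) length(r$ids)),
    n_matched = map_int(rules, function(r) as.integer(r$n_matched)),
    n_matched_yes = map_int(rules, function(r) as.integer(r$n_matched_yes)),
    support = map_dbl(rules, "support"),
    precision = map_dbl(rules, "precision")
  ) |>
    mutate(
      lift = rule_lift(.data$precision, base_rate),
      p_value = rule_pvalue(.data$n_matched_yes, .data$n_matched,
                            sum(h), n)
    ) |>
    filter(.data$p_value < config$alpha)
  if (nrow(tab) == 0) return(empty_rules(base_rate, n, n_dropped, config))

  # matched-set identity: rules covering the same users share an id
  mask_key <- map_chr(tab$conditions, function(cc) {
    paste(which(conditions_mask(features, cc)), collapse = ",")
  })
  tab$matched_set <- match(mask_key, unique(mask_key))
  tab$rule <- map_chr(tab$conditions, render_antecedent)
  out <- tab |>
    arrange(desc(.data$lift), desc(.data$precision), desc(.data$support)) |>
    select(
      "rule", "length", "support", "precision", "lift", "p_value",
      "n_matched", "matched_set", "conditions"
    )
  structure(out,
    base_rate = base_rate, n_total = n, n_dropped_incomplete = n_dropped,
    config = config, class = c("ema_rules", class(out))
  )
}

empty_rules <- function(base_rate, n_total, n_dropped, config) {
  out <- tibble(
    rule = character(), length = integer(), support = numeric(),
    precision = numeric(), lift = numeric(), p_value = numeric(),
    n_matched = integer(), matched_set = integer(), conditions = list()
  )
  structure(out,
    base_rate = base_rate, n_total = n_total,
    n_dropped_incomplete = n_dropped, config = config,
    class = c("ema_rules", class(out))
  )
}

#' Rounded, human-readable rule listing
#'
#' Support, precision and lift rounded half-up to two decimals, in the sorted
#' order of the mined list.
#'
#' @param rules An `ema_rules` tibble.
#' @return A tibble with columns `rule`, `support`, `precision`, `lift`,
#'   `p_value`, `n_matched`.
#' @export
render_rules <- function(rules) {
  rules |>
    as_tibble() |>
    transmute(
      rule = .data$rule,
      support = round_half_up(.data$support, 2),
      precision = round_half_up(.data$precision, 2),
      lift = round_half_up(.data$lift, 2),
      p_value = signif(.data$p_value, 3),
      n_matched = .data$n_matched
    )
}

#' Horizon-free interaction-day feature
#'
#' The `NumDays` column for rule mining: total days of interaction regardless
#' of the observation horizon (a 31-day user keeps 31).
#'
#' @param profiles Profile tibble from [adherence_profiles()].
#' @return Tibble with columns `user_id`, `NumDays`.
#' @export
numdays_features <- function(profiles) {
  tibble(user_id = profiles$user_id, NumDays = as.numeric(profiles$num_days))
}

#' Typed feature table for rule mining
#'
#' Selects registration attributes and casts them for the miner: MiniTF items
#' and the TSCHQ category codes become factors (mined as equalities), ages,
#' the MiniTF total score and `NumDays` stay numeric (mined as thresholds).
#'
#' @param registrations Registration tibble.
#' @param which `"minitf"`, `"tschq"` or both.
#' @param numdays Optional tibble from [numdays_features()], joined on
#'   `user_id`.
#' @param score Include the numeric `minitf_score` column? Default `FALSE`
#'   (the items themselves carry the signal; the total is available for
#'   separate analyses).
#' @return A feature tibble with a leading `user_id` column.
#' @export
registration_features <- function(registrations,
                                  which = c("minitf", "tschq"),
                                  numdays = NULL, score = FALSE) {
  which <- match.arg(which, several.ok = TRUE)
  out <- tibble(user_id = registrations$user_id)
  if ("minitf" %in% which) {
    for (tf in minitf_items()) out[[tf]] <- factor(registrations[[tf]])
    if (score) out$minitf_score <- as.numeric(registrations$minitf_score)
  }
  if ("tschq" %in% which) {
    for (f in c("sex", "onsetrelation", "familyHistory", "variability")) {
      out[[f]] <- factor(registrations[[f]])
    }
    out$ageAtRegistration <- as.numeric(registrations$ageAtRegistration)
    out$ageAtOnset <- as.numeric(registrations$ageAtOnset)
  }
  if (!is.null(numdays)) out <- left_join(out, numdays, by = "user_id")
  out
}
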