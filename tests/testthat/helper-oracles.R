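# Independent reference implementations used to validate the package's
# algorithms. These deliberately avoid the package's dynamic programs:
# distances are checked by exhaustive enumeration, adherence by a literal
# day-by-day scan.

# DTW oracle: enumerate every monotone warping path through the |x| x |y|
# grid and take the minimum summed squared cost.
oracle_dtw <- function(x, y) {
  n <- length(x)
  m <- length(y)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + (x[i] - y[j])^2
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}

# MSM oracle: plain top-down recursion over the three edit operations
# (move, split, merge) straight from their definitions, no memoisation.
oracle_msm_edit <- function(u, v, w, c) {
  if ((v <= u && u <= w) || (v >= u && u >= w)) {
    c
  } else {
    c + min(abs(u - v), abs(u - w))
  }
}

oracle_msm <- function(x, y, c) {
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(abs(x[1] - y[1]))
    cands <- numeric(0)
    if (i > 1 && j > 1) {
      cands <- c(cands, rec(i - 1, j - 1) + abs(x[i] - y[j]))
    }
    if (i > 1) {
      cands <- c(cands, rec(i - 1, j) + oracle_msm_edit(x[i], x[i - 1], y[j], c))
    }
    if (j > 1) {
      cands <- c(cands, rec(i, j - 1) + oracle_msm_edit(y[j], x[i], y[j - 1], c))
    }
    min(cands)
  }
  rec(length(x), length(y))
}

# all sequences of the given lengths over a small alphabet
enumerate_sequences <- function(alphabet, lengths) {
  out <- list()
  for (L in lengths) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    for (r in seq_len(nrow(grid))) {
      out[[length(out) + 1L]] <- as.numeric(grid[r, ])
    }
  }
  out
}

# Adherence oracle: per user, scan calendar days one by one and accumulate
# the four quantities directly from the definitions.
oracle_profile <- function(recordings, n_horizon = 30) {
  items <- paste0("q", 1:7)
  users <- sort(unique(recordings$user_id))
  out <- list()
  for (u in users) {
    rec <- recordings[recordings$user_id == u, , drop = FALSE]
    day <- as.Date(rec$timestamp, tz = "UTC")
    answered <- function(j, d) any(!is.na(rec[[j]][day == d]))
    all_days <- sort(unique(day[rowSums(!is.na(rec[items])) > 0]))
    num_days <- length(all_days)
    kept <- all_days[seq_len(min(num_days, n_horizon))]
    durations <- integer(0)
    fds <- integer(0)
    for (j in items) {
      jd <- kept[vapply(kept, function(d) answered(j, d), logical(1))]
      if (length(jd) == 0) next
      durations <- c(durations, length(jd))
      fd <- 1L
      while (fd < length(jd) && jd[fd + 1] == jd[fd] + 1) fd <- fd + 1L
      fds <- c(fds, fd)
    }
    out[[u]] <- data.frame(
      user_id = u, duration = max(durations), first_days = max(fds),
      ret = max(durations) > max(fds), num_days = num_days
    )
  }
  do.call(rbind, out)
}

# random small recording fixtures for property tests
random_recordings <- function(n_users = 5, max_days = 40, p_day = 0.3,
                              p_item = 0.7) {
  rows <- list()
  origin <- as.Date("2015-01-01")
  for (u in seq_len(n_users)) {
    days <- which(runif(max_days) < p_day)
    if (length(days) == 0) days <- sample.int(max_days, 1)
    for (d in days) {
      for (r in seq_len(sample(1:2, 1))) {
        vals <- ifelse(runif(7) < p_item, round(runif(7), 3), NA_real_)
        if (all(is.na(vals))) vals[1] <- 1
        vals[1] <- ifelse(is.na(vals[1]), NA_real_, round(vals[1]))
        row <- data.frame(
          user_id = sprintf("u%02d", u),
          timestamp = as.POSIXct(origin + d, tz = "UTC") + r * 3600
        )
        for (j in 1:7) row[[paste0("q", j)]] <- vals[j]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, user_id, timestamp)
}

make_recordings <- function(df) {
  # df: user, day (integer), item values in ... columns q1..q7 optional
  origin <- as.Date("2015-06-01")
  out <- tibble::tibble(
    user_id = df$user,
    timestamp = as.POSIXct(origin + df$day, tz = "UTC") + 12 * 3600 +
      seq_len(nrow(df))
  )
  for (j in paste0("q", 1:7)) {
    out[[j]] <- if (j %in% names(df)) df[[j]] else NA_real_
  }
  out
}
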