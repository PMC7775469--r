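#' Time-series distance specification
#'
#' Names one of the implemented elastic distances together with its
#' parameters and minimum series length: `ED` (Euclidean), `DTW` (dynamic
#' time warping with squared local cost, unconstrained window, path-sum
#' report), `DDTW` (DTW on derivative-transformed series; needs at least 3
#' points), `CID` (complexity-invariant distance; needs at least 2 points)
#' and `MSM` (move-split-merge edit distance with cost `msm_cost`).
#'
#' @param name One of `"ED"`, `"DTW"`, `"DDTW"`, `"CID"`, `"MSM"`.
#' @param msm_cost Split/merge cost for MSM (default 0.1, must be positive).
#' @return A list of class `distance_spec` with `name`, `msm_cost`,
#'   `min_len`.
#' @export
distance_spec <- function(name = c("ED", "DTW", "DDTW", "CID", "MSM"),
                          msm_cost = 0.1) {
  name <- match.arg(name)
  if (msm_cost <= 0) abort("`msm_cost` must be positive")
  min_len <- c(ED = 1L, DTW = 1L, DDTW = 3L, CID = 2L, MSM = 1L)[[name]]
  structure(list(name = name, msm_cost = msm_cost, min_len = min_len),
            class = "distance_spec")
}

check_series <- function(x, arg = "x", min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    abort(sprintf("`%s` must be a numeric series of length >= %d", arg, min_len))
  }
  if (anyNA(x)) abort(sprintf("`%s` contains missing values", arg))
}

#' Euclidean distance between equal-length series
#'
#' @param x,y Numeric vectors of equal length (at least 1).
#' @return Non-negative scalar.
#' @examples
#' ts_euclidean(c(0, 0), c(3, 4)) # 5
#' @export
ts_euclidean <- function(x, y) {
  check_series(x); check_series(y, "y")
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ed_cpp(as.numeric(x), as.numeric(y))
}

#' Dynamic time warping distance
#'
#' Minimum over monotone warping paths of the summed squared pointwise costs
#' `(x_i - y_j)^2`; computed by the standard O(|x||y|) dynamic program with no
#' warping-window constraint and reported as the path sum (no square root).
#' Lengths may differ.
#'
#' @param x,y Numeric vectors of length at least 1.
#' @return Non-negative scalar; 0 iff a perfect warping alignment exists.
#' @examples
#' ts_dtw(0, 3) # 9
#' @export
ts_dtw <- function(x, y) {
  check_series(x); check_series(y, "y")
  dtw_cpp(as.numeric(x), as.numeric(y))
}

#' Derivative transform of a series
#'
#' Interior points get `d_i = ((x_i - x_{i-1}) + (x_{i+1} - x_{i-1})/2) / 2`
#' (the average of the backward slope and the surrounding chord slope);
#' endpoints copy their neighbour's derivative, so the output has the input's
#' length. The derivative-DTW distance is DTW applied to these transforms.
#'
#' @param x Numeric vector of length at least 3.
#' @return Numeric vector of the same length.
#' @examples
#' ts_derivative(c(0, 1, 2)) # all 1: a linear series has constant slope
#' @export
ts_derivative <- function(x) {
  if (length(x) < 3) abort("DDTW requires >= 3 points")
  check_series(x, min_len = 3L)
  deriv_cpp(as.numeric(x))
}

#' Complexity-invariant distance
#'
#' Euclidean distance inflated by the complexity ratio
#' `CF = max(CE(x), CE(y)) / min(CE(x), CE(y))` with
#' `CE(z) = sqrt(sum (z_{i+1} - z_i)^2)`. Two flat series have `CF = 1`
#' (plain ED); when exactly one complexity vanishes the denominator is
#' floored at `1e-9`. Always at least the Euclidean distance.
#'
#' @param x,y Numeric vectors of equal length, at least 2.
#' @return Non-negative scalar.
#' @export
ts_cid <- function(x, y) {
  check_series(x, min_len = 2L); check_series(y, "y", min_len = 2L)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  cid_cpp(as.numeric(x), as.numeric(y))
}

#' Move-split-merge edit distance
#'
#' Edit distance whose operations are moves (cost `|x_i - y_j|`) and
#' splits/merges (cost `c` when the inserted or removed value lies between
#' its two neighbours, else `c` plus the distance to the nearer neighbour),
#' computed by the standard dynamic program. A metric for any `c > 0`.
#'
#' @param x,y Numeric vectors of length at least 1 (may differ).
#' @param c Split/merge cost (default 0.1).
#' @return Non-negative scalar.
#' @examples
#' ts_msm(1, 2) # 1: a single move
#' @export
ts_msm <- function(x, y, c = 0.1) {
  check_series(x); check_series(y, "y")
  if (c <= 0) abort("`c` must be positive")
  msm_cpp(as.numeric(x), as.numeric(y), c)
}

#' Distance between two series under a specification
#'
#' @param x,y Numeric series.
#' @param spec A [distance_spec()].
#' @return Non-negative scalar.
#' @export
ts_distance <- function(x, y, spec = distance_spec("DTW")) {
  stopifnot(inherits(spec, "distance_spec"))
  switch(spec$name,
    ED = ts_euclidean(x, y),
    DTW = ts_dtw(x, y),
    DDTW = ts_dtw(ts_derivative(x), ts_derivative(y)),
    CID = ts_cid(x, y),
    MSM = ts_msm(x, y, spec$msm_cost)
  )
}

method_code <- function(name) {
  c(ED = 1L, DTW = 2L, DDTW = 3L, CID = 4L, MSM = 5L)[[name]]
}

#' Pairwise distance matrix between two sets of equal-length series
#'
#' @param a,b Lists of numeric vectors (or numeric matrices, one series per
#'   row), all of one common length.
#' @param spec A [distance_spec()].
#' @return A `length(a)` by `length(b)` matrix.
#' @export
pairwise_distances <- function(a, b, spec = distance_spec("DTW")) {
  stopifnot(inherits(spec, "distance_spec"))
  A <- if (is.matrix(a)) a else do.call(rbind, a)
  B <- if (is.matrix(b)) b else do.call(rbind, b)
  if (ncol(A) != ncol(B)) abort("series sets must share one length")
  if (ncol(A) < spec$min_len) {
    abort(sprintf("%s needs series of length >= %d", spec$name, spec$min_len))
  }
  pairwise_cpp(A, B, method_code(spec$name), spec$msm_cost)
}

#' 1-nearest-neighbour label prediction
#'
#' Predicts, for each test series, the label of its minimum-distance training
#' series; distance ties break deterministically towards the earliest
#' training index. If the stratum's series are shorter than the distance's
#' minimum length the result is a "skipped" marker (all-`NA` labels with a
#' `skipped` attribute), not an error.
#'
#' @param train A stratum tibble (columns `series`, `label`) or a list with
#'   elements `series` and `label`; must be non-empty.
#' @param test_series List of numeric vectors (same length as the training
#'   series).
#' @param spec A [distance_spec()].
#' @return Character vector of predicted labels, or an all-`NA` vector with
#'   attributes `skipped = TRUE` and `reason` when the distance does not
#'   apply.
#' @export
nn1_classify <- function(train, test_series, spec = distance_spec("DTW")) {
  stopifnot(inherits(spec, "distance_spec"))
  labels <- as.character(train$label)
  series <- train$series
  if (length(series) == 0) abort("empty training set")
  if (!is.list(test_series)) test_series <- list(test_series)
  len <- length(series[[1]])
  if (len < spec$min_len) {
    return(structure(rep(NA_character_, length(test_series)),
      skipped = TRUE,
      reason = sprintf("min length %d", spec$min_len)
    ))
  }
  d <- pairwise_distances(test_series, series, spec)
  labels[max.col(-d, ties.method = "first")]
}
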