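#' Replace near-constant plateaus by their mean
#'
#' Greedy left-to-right smoothing of a predicted series: maximal runs whose
#' range (max - min) stays within \code{tol} are replaced by their mean.
#' Removes the small-amplitude jitter of the network output while leaving
#' jumps above the tolerance intact.
#'
#' @param v numeric series.
#' @param tol plateau tolerance (default 0.01).
#' @return smoothed series, same length.
#' @export
merge_plateaus <- function(v, tol = 0.01) {
  n <- length(v)
  if (n == 0) return(v)
  out <- v
  i <- 1L
  while (i <= n) {
    lo <- v[i]; hi <- v[i]
    j <- i
    while (j < n) {
      nlo <- min(lo, v[j + 1L]); nhi <- max(hi, v[j + 1L])
      if (nhi - nlo > tol) break
      lo <- nlo; hi <- nhi
      j <- j + 1L
    }
    out[i:j] <- mean(v[i:j])
    i <- j + 1L
  }
  out
}

#' Sliding median filter
#'
#' Centred median with odd window; at the boundaries the window shrinks to
#' the available frames (no invented padding values, which would create
#' spurious edge changepoints).
#'
#' @param v numeric series.
#' @param window odd window size (default 3).
#' @return filtered series.
#' @export
median_filter <- function(v, window = 3L) {
  stopifnot(window %% 2 == 1, window >= 1)
  n <- length(v)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    stats::median(v[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Smooth a predicted continuous series
#'
#' The plateau merge followed by the window-3 median filter, applied to the
#' predicted alpha series and the predicted K series (in log10(K+1) space).
#'
#' @param v numeric series.
#' @param tol plateau tolerance.
#' @param window median window.
#' @return smoothed series.
#' @export
smooth_series <- function(v, tol = 0.01, window = 3L) {
  median_filter(merge_plateaus(v, tol), window)
}

#' Enforce the minimum state duration
#'
#' Any state segment lasting fewer than \code{min_len} consecutive frames is
#' invalid and takes the value of its preceding segment (a short leading
#' segment takes the following segment's value); applied left-to-right until
#' a fixed point.
#'
#' @param s integer state series.
#' @param min_len minimum segment length in frames (default 3).
#' @return corrected state series.
#' @export
enforce_min_state_duration <- function(s, min_len = 3L) {
  n <- length(s)
  if (n == 0) return(s)
  repeat {
    r <- rle(as.vector(s))
    if (length(r$lengths) == 1 || all(r$lengths >= min_len)) break
    i <- which(r$lengths < min_len)[1]
    r$values[i] <- if (i == 1L) r$values[i + 1L] else r$values[i - 1L]
    s <- inverse.rle(r)
  }
  s
}

#' Min-max normalise a series to \[0, 1\]
#'
#' A constant series maps to all zeros (nothing to detect).
#'
#' @param v numeric series.
#' @return normalised series.
#' @export
minmax_norm <- function(v) {
  r <- range(v)
  if (r[2] == r[1]) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

# L2 segment cost from prefix sums: sum of squared deviations from the
# segment mean over frames (i+1)..j (0-based boundaries i < j)
.l2_cost <- function(cs, cs2, i, j) {
  n <- j - i
  s <- cs[j + 1L] - cs[i + 1L]
  s2 <- cs2[j + 1L] - cs2[i + 1L]
  s2 - s * s / n
}

#' Penalized least-squares changepoint segmentation (PELT)
#'
#' Exact minimisation of the within-segment sum of squared deviations plus
#' a per-changepoint penalty, by dynamic programming with PELT pruning
#' (pruning never changes the optimum for this cost). The series is min-max
#' normalised first so one penalty serves every variable. Changepoints
#' follow the half-open convention: a changepoint at frame c splits into
#' \[0, c) and \[c, T).
#'
#' @param v numeric series.
#' @param penalty per-changepoint penalty (default 0.3).
#' @param min_size minimum segment length in frames (default 3).
#' @param normalise min-max normalise before segmenting (default TRUE).
#' @return sorted integer vector of changepoint frames (possibly empty).
#' @export
pelt_segment <- function(v, penalty = 0.3, min_size = 3L, normalise = TRUE) {
  n <- length(v)
  if (n < 2L * min_size) return(integer(0))
  if (normalise) v <- minmax_norm(v)
  cs <- c(0, cumsum(v))
  cs2 <- c(0, cumsum(v^2))
  # F[t+1] = optimal cost of v[1..t] (+ penalty per changepoint)
  F <- rep(Inf, n + 1L)
  F[1] <- -penalty
  last <- integer(n + 1L)
  cand <- 0L  # candidate last-changepoint positions (0-based)
  # a candidate dominated at time t is only truly unusable once the
  # dominating position t itself becomes admissible, min_size steps later;
  # removing it earlier could change the optimum near the constraint
  remove_at <- rep(Inf, 1L)
  for (t in min_size:n) {
    alive <- t < remove_at
    cand <- cand[alive]
    remove_at <- remove_at[alive]
    ok <- t - cand >= min_size
    costs <- F[cand[ok] + 1L] + penalty +
      vapply(cand[ok], function(s) .l2_cost(cs, cs2, s, t), numeric(1))
    b <- which.min(costs)
    F[t + 1L] <- costs[b]
    last[t + 1L] <- cand[ok][b]
    dominated <- ok
    dominated[ok] <- costs - penalty > F[t + 1L]
    remove_at[dominated] <- pmin(remove_at[dominated], t + min_size)
    cand <- c(cand, t)
    remove_at <- c(remove_at, Inf)
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    s <- last[t + 1L]
    if (s == 0L) break
    cps <- c(s, cps)
    t <- s
  }
  cps
}

#' Changepoints of a discrete state series
#'
#' Every frame at which the (already duration-corrected) state label
#' changes, in the half-open 0-based convention.
#'
#' @param s integer state series.
#' @return sorted integer vector of changepoint frames.
#' @export
state_changepoints <- function(s) {
  n <- length(s)
  if (n < 2) return(integer(0))
  which(s[-1] != s[-n])
}

#' Merge changepoint sets around an anchor
#'
#' Anchor points (typically the K-derived changepoints, where the labeller
#' is most reliable) are kept verbatim; a point from another set is added
#' only if no already-retained point lies within \code{window} frames.
#' Candidate sets are processed in the order given.
#'
#' @param anchor integer vector of anchor changepoints.
#' @param others list of additional changepoint vectors (e.g. alpha, state).
#' @param window dedup window in frames (default 5).
#' @return sorted merged changepoint vector.
#' @export
merge_changepoint_sets <- function(anchor, others = list(), window = 5L) {
  kept <- sort(unique(as.integer(anchor)))
  for (set in others) {
    for (p in sort(unique(as.integer(set)))) {
      if (length(kept) == 0 || min(abs(kept - p)) > window) {
        kept <- sort(c(kept, p))
      }
    }
  }
  kept
}

#' Segmentation parameters
#'
#' @param penalty PELT per-changepoint penalty.
#' @param min_size minimum segment length in frames.
#' @param dedup_window merge dedup window in frames.
#' @param cp_vars variables contributing changepoints: subset of
#'   c("K", "alpha", "state"); the first entry is the anchor set. The
#'   default alpha+K (K anchored) gave the best combined detection in
#'   evaluation.
#' @return list of class \code{seg_params}.
#' @export
seg_params <- function(penalty = 0.3, min_size = 3L, dedup_window = 5L,
                       cp_vars = c("K", "alpha")) {
  stopifnot(penalty >= 0, min_size >= 1,
            all(cp_vars %in% c("K", "alpha", "state")))
  structure(list(penalty = penalty, min_size = as.integer(min_size),
                 dedup_window = as.integer(dedup_window), cp_vars = cp_vars),
            class = "seg_params")
}

#' Post-process predictions and detect changepoints
#'
#' Full inference-side pipeline for one trajectory: smooth the continuous
#' series, enforce the minimum state duration, run penalized segmentation
#' per variable, and merge the changepoint sets around the anchor variable.
#'
#' @param alpha_hat predicted alpha series (or NULL).
#' @param logK_hat predicted K series in log10(K+1) space (or NULL).
#' @param s_hat predicted state series (or NULL).
#' @param params a \code{\link{seg_params}}.
#' @param tol plateau-merge tolerance.
#' @return list with the smoothed series (\code{alpha}, \code{logK},
#'   \code{state}), the per-variable changepoint sets and the merged
#'   \code{changepoints}.
#' @export
postprocess_predictions <- function(alpha_hat = NULL, logK_hat = NULL,
                                    s_hat = NULL, params = seg_params(),
                                    tol = 0.01) {
  sm <- list(alpha = NULL, logK = NULL, state = NULL)
  sets <- list()
  if (!is.null(logK_hat)) {
    sm$logK <- smooth_series(logK_hat, tol)
    sets$K <- pelt_segment(sm$logK, params$penalty, params$min_size)
  }
  if (!is.null(alpha_hat)) {
    sm$alpha <- smooth_series(alpha_hat, tol)
    sets$alpha <- pelt_segment(sm$alpha, params$penalty, params$min_size)
  }
  if (!is.null(s_hat)) {
    sm$state <- enforce_min_state_duration(s_hat)
    sets$state <- state_changepoints(sm$state)
  }
  use <- params$cp_vars[params$cp_vars %in% names(sets)]
  merged <- if (length(use) == 0) integer(0) else {
    merge_changepoint_sets(sets[[use[1]]],
                           unname(sets[use[-1]]),
                           params$dedup_window)
  }
  list(alpha = sm$alpha, logK = sm$logK, state = sm$state,
       cp_sets = sets, changepoints = merged)
}
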