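# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with straight-line loops, not via the package
# implementations.

# feature matrix computed literally from the definitions
brute_features <- function(x, y) {
  T <- length(x)
  zn <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  xn <- zn(x); yn <- zn(y)
  d <- numeric(T)
  for (t in 1:T) d[t] <- sqrt((x[t] - x[1])^2 + (y[t] - y[1])^2)
  step <- numeric(T - 1)
  for (t in 1:(T - 1)) step[t] <- sqrt((x[t + 1] - x[t])^2 + (y[t + 1] - y[t])^2)
  stepn <- zn(step)
  ang <- numeric(max(T - 2, 0))
  if (T >= 3) for (t in 1:(T - 2)) {
    u <- c(x[t + 1] - x[t], y[t + 1] - y[t])
    v <- c(x[t + 2] - x[t + 1], y[t + 2] - y[t + 1])
    if (sqrt(sum(u^2)) == 0 || sqrt(sum(v^2)) == 0) {
      ang[t] <- 0
    } else {
      ang[t] <- atan2(u[1] * v[2] - u[2] * v[1], sum(u * v))
    }
  }
  str1 <- numeric(T); str2 <- numeric(T)
  for (t in 2:T) {
    net <- sqrt((xn[t] - xn[1])^2 + (yn[t] - yn[1])^2)
    pl <- 0; pl2 <- 0
    for (j in 2:t) {
      pl <- pl + sqrt((xn[j] - xn[j - 1])^2 + (yn[j] - yn[j - 1])^2)
      pl2 <- pl2 + (xn[j] - xn[j - 1])^2 + (yn[j] - yn[j - 1])^2
    }
    str1[t] <- if (pl > 0) net / pl else 0
    str2[t] <- if (pl2 > 0) net^2 / pl2 else 0
  }
  Fof <- function(v) {
    out <- numeric(length(v) - 1)
    for (t in 1:(length(v) - 1)) out[t] <- log(max(abs(v[t + 1] - v[t]), 1e-12))
    out
  }
  pad <- function(v) c(v, numeric(T - length(v)))
  rbind(xn, yn, d, pad(stepn), pad(ang), str1, str2,
        pad(Fof(xn)), pad(Fof(yn)), pad(Fof(stepn)))
}

# exhaustive penalized-L2 segmentation: enumerate every admissible
# changepoint set for short series
brute_segment <- function(v, penalty = 0.3, min_size = 3L,
                          normalise = TRUE) {
  n <- length(v)
  if (normalise) {
    r <- range(v)
    v <- if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0, n)
  }
  segcost <- function(i, j) { # frames i..j, 1-based inclusive
    s <- v[i:j]
    sum((s - mean(s))^2)
  }
  best <- list(cost = Inf, cps = integer(0))
  interior <- seq_len(n - 1)  # candidate 0-based cps are 1..n-1
  for (k in 0:((n %/% min_size) - 1)) {
    if (k == 0) {
      cand <- list(integer(0))
    } else {
      cand <- utils::combn(interior, k, simplify = FALSE)
    }
    for (cps in cand) {
      bounds <- c(0L, cps, n)
      lens <- diff(bounds)
      if (any(lens < min_size)) next
      cost <- penalty * k
      for (i in seq_len(length(bounds) - 1))
        cost <- cost + segcost(bounds[i] + 1L, bounds[i + 1L])
      if (cost < best$cost - 1e-12) best <- list(cost = cost, cps = cps)
    }
  }
  best
}

# objective value of a given segmentation (for optimum-vs-optimum checks)
seg_objective <- function(v, cps, penalty = 0.3, normalise = TRUE) {
  n <- length(v)
  if (normalise) {
    r <- range(v)
    v <- if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0, n)
  }
  bounds <- c(0L, cps, n)
  cost <- penalty * length(cps)
  for (i in seq_len(length(bounds) - 1)) {
    s <- v[(bounds[i] + 1L):bounds[i + 1L]]
    cost <- cost + sum((s - mean(s))^2)
  }
  cost
}

# minimum-cost assignment by enumeration over all injective mappings of the
# smaller side into the larger
brute_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr >= 1, nc >= 1)
  if (nr <= nc) {
    perms <- all_injections(nr, nc)
    best <- NULL; bc <- Inf
    for (p in perms) {
      cc <- sum(cost[cbind(seq_len(nr), p)])
      if (cc < bc) { bc <- cc; best <- p }
    }
    list(cost = bc, rows = seq_len(nr), cols = best)
  } else {
    r <- brute_assignment(t(cost))
    list(cost = r$cost, rows = r$cols, cols = r$rows)
  }
}

all_injections <- function(k, n) {
  # all ordered selections of k distinct values from 1..n
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in remaining) rec(c(prefix, v), setdiff(remaining, v))
  }
  rec(integer(0), seq_len(n))
  out
}

# sliding-median oracle with shrunken end windows
brute_median3 <- function(v) {
  n <- length(v)
  out <- numeric(n)
  for (i in 1:n) out[i] <- stats::median(v[max(1, i - 1):min(n, i + 1)])
  out
}

# geometric changepoint-free check helpers
seg_lengths <- function(track) {
  diff(c(0L, track$changepoints, length(track$x)))
}

label_invariants_ok <- function(track) {
  a <- track$alpha; K <- track$K; s <- track$state
  all(seg_lengths(track) >= 3) &&
    all(a >= 0 & a <= 2) && all(K >= 0 & K <= 1e6) &&
    all(s %in% 0:3) &&
    all(a[s == 0] == 0) && all(a[s == 3] >= 1.9) &&
    all(a[s == 1] < 1.9)
}
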