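# output smoothing, minimum state duration, PELT segmentation and merging

test_that("plateau merging replaces tolerance-bounded runs by their mean", {
  expect_equal(merge_plateaus(rep(2.5, 8)), rep(2.5, 8))
  expect_equal(merge_plateaus(c(0, 0.005, 0.01, 1.0, 1.0)),
               c(0.005, 0.005, 0.005, 1.0, 1.0))
  v <- cumsum(rep(0.5, 10))
  expect_equal(merge_plateaus(v), v)  # every jump exceeds the tolerance
})

test_that("median filter matches the brute-force sliding median", {
  expect_equal(median_filter(c(1, 9, 1))[2], 1)
  v <- c(1, 2, 3, 4, 5)
  expect_equal(median_filter(v)[2:4], v[2:4])
  set.seed(50)
  for (i in 1:20) {
    v <- rnorm(sample(3:30, 1))
    expect_equal(median_filter(v), brute_median3(v))
  }
})

test_that("smoothing pipeline is idempotent on plateau-dominated output", {
  # the regime the smoother targets: near-constant plateaus whose jitter
  # sits below the merge tolerance, separated by jumps well above it
  set.seed(51)
  for (i in 1:50) {
    level <- cumsum(stats::runif(3, 0.05, 1))
    v <- rep(level, each = 25) + rnorm(75, sd = 0.001)
    once <- smooth_series(v)
    expect_equal(smooth_series(once), once, tolerance = 1e-12)
  }
})

test_that("short state segments inherit their neighbours", {
  expect_equal(enforce_min_state_duration(c(2, 2, 2, 3, 2, 2)),
               rep(2, 6))
  expect_equal(enforce_min_state_duration(c(0, 0, 0, 1, 1, 1)),
               c(0, 0, 0, 1, 1, 1))
  # a short leading segment takes the following state
  expect_equal(enforce_min_state_duration(c(3, 2, 2, 2, 2)), rep(2, 5))
  # fixed point: no remaining segment under three frames
  set.seed(52)
  for (i in 1:100) {
    s <- sample(0:3, 30, replace = TRUE)
    out <- enforce_min_state_duration(s)
    expect_true(all(rle(out)$lengths >= 3) || length(rle(out)$lengths) == 1)
    expect_length(out, length(s))
  }
})

test_that("a clean step is segmented exactly at its edge", {
  v <- c(rep(0, 100), rep(1, 100))
  expect_equal(pelt_segment(v), 100L)
  expect_equal(pelt_segment(rep(0.7, 50)), integer(0))
  expect_equal(pelt_segment(c(0, 1)), integer(0))  # too short to split
})

test_that("PELT equals exhaustive dynamic programming on short series", {
  set.seed(53)
  for (i in 1:500) {
    n <- sample(6:12, 1)
    v <- rnorm(n) + sample(0:1, n, replace = TRUE) * 2
    got <- pelt_segment(v)
    want <- brute_segment(v)
    expect_equal(seg_objective(v, got), want$cost, tolerance = 1e-9)
  }
})

test_that("state changepoints are the label change frames", {
  expect_equal(state_changepoints(rep(2, 10)), integer(0))
  expect_equal(state_changepoints(c(2, 2, 2, 0, 0, 0)), 3L)
  set.seed(54)
  for (i in 1:50) {
    s <- inverse.rle(list(lengths = sample(3:6, 4, TRUE),
                          values = sample(0:3, 4, TRUE)))
    expect_equal(state_changepoints(s), which(diff(s) != 0))
  }
})

test_that("merging keeps anchors and window-separated additions", {
  expect_equal(merge_changepoint_sets(50L, list(52L)), 50L)
  expect_equal(merge_changepoint_sets(50L, list(100L)), c(50L, 100L))
  expect_equal(merge_changepoint_sets(integer(0), list(integer(0))),
               integer(0))
  # points retained from different sets are never within the window
  set.seed(55)
  for (i in 1:50) {
    a <- sort(sample(1:100, 5))
    b <- sort(sample(1:100, 5))
    out <- merge_changepoint_sets(a, list(b), window = 5)
    added <- setdiff(out, a)
    for (p in added) expect_gt(min(abs(setdiff(out, p) - p)), 5)
    expect_true(all(a %in% out))
  }
})

test_that("prediction post-processing wires the stages together", {
  set.seed(56)
  alpha_hat <- c(rep(0.5, 60), rep(1.5, 60)) + rnorm(120, sd = 0.003)
  logk_hat <- c(rep(1, 60), rep(2.5, 60)) + rnorm(120, sd = 0.003)
  s_hat <- c(rep(2L, 60), rep(3L, 59), 2L)
  pp <- postprocess_predictions(alpha_hat, logk_hat, s_hat)
  expect_equal(pp$changepoints, 60L)
  expect_equal(pp$cp_sets$K, 60L)
  expect_equal(pp$cp_sets$alpha, 60L)
  # the trailing 1-frame state flip is removed before state changepoints
  expect_equal(pp$cp_sets$state, 60L)
  expect_true(all(rle(pp$state)$lengths >= 3))
})
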