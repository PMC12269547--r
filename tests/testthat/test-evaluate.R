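# scoring: pointwise errors, state metrics, changepoint pairing

test_that("mae and male are two-level averages", {
  expect_equal(mae(list(c(1, 1), c(2, 2)), list(c(1, 1), c(2, 2))), 0)
  # per-trajectory means 0.1 and 0.3 average to 0.2
  expect_equal(mae(list(c(1.1, 1.1), c(2.3)), list(c(1, 1), c(2))), 0.2)
  # constant per-frame error is invariant to trajectory length
  expect_equal(mae(list(rep(1.5, 7)), list(rep(1, 7))),
               mae(list(rep(1.5, 100)), list(rep(1, 100))))
  # K of 0 predicted at log-space 1 is one log unit off
  expect_equal(male(list(rep(1, 4)), list(rep(0, 4)), log_input = FALSE),
               male(list(rep(k_to_log(1), 4)), list(rep(0, 4)),
                    log_input = TRUE))
  expect_equal(male(list(rep(9, 3)), list(rep(0, 3))), 1)
})

test_that("mae agrees with flat averaging only for equal lengths", {
  set.seed(60)
  p <- lapply(1:5, function(i) rnorm(20))
  g <- lapply(1:5, function(i) rnorm(20))
  flat <- mean(abs(unlist(p) - unlist(g)))
  expect_equal(mae(p, g), flat)
})

test_that("state metrics row-normalise and average present classes", {
  perfect <- state_metrics(c(0L, 1L, 2L, 3L), c(0L, 1L, 2L, 3L))
  expect_equal(unname(perfect$confusion), diag(4))
  expect_equal(perfect$avg_class_accuracy, 1)
  # two-class toy: 8/10 and 6/10 correct -> 0.7; absent classes dropped
  gt <- c(rep(0L, 10), rep(1L, 10))
  pred <- c(rep(0L, 8), 1L, 1L, rep(1L, 6), rep(0L, 4))
  sm <- state_metrics(pred, gt)
  expect_equal(sm$avg_class_accuracy, 0.7)
  expect_true(all(is.na(sm$confusion[3:4, ])))
  rs <- rowSums(sm$confusion[1:2, ])
  expect_equal(unname(rs), c(1, 1))
})

test_that("assignment solver matches enumeration on random instances", {
  set.seed(61)
  for (i in 1:200) {
    nr <- sample(1:4, 1); nc <- sample(1:4, 1)
    cost <- matrix(runif(nr * nc), nr, nc)
    got <- solve_assignment(cost)
    ok <- which(!is.na(got))
    gc <- sum(cost[cbind(ok, got[ok])])
    expect_equal(gc, brute_assignment(cost)$cost, tolerance = 1e-9)
  }
})

test_that("changepoint pairing is tolerance-gated and never crosses", {
  p <- pair_changepoints(100, 102)
  expect_equal(p$TP, 1L)
  p <- pair_changepoints(100, 110)
  expect_equal(unlist(p[c("TP", "FN", "FP")]), c(TP = 0L, FN = 1L, FP = 1L))
  # optimal assignment does not cross-pair
  p <- pair_changepoints(c(50, 60), c(59, 49))
  expect_equal(p$pairs[, "gt"], c(50, 60))
  expect_equal(p$pairs[, "pred"], c(49, 59))
  # the 5-frame gate is strict
  expect_equal(pair_changepoints(100, 105)$TP, 0L)
  expect_equal(pair_changepoints(100, 104)$TP, 1L)
})

test_that("pairing agrees with brute-force enumeration for small sets", {
  set.seed(62)
  for (i in 1:200) {
    gt <- sort(sample(1:60, sample(0:4, 1)))
    pr <- sort(sample(1:60, sample(0:4, 1)))
    got <- pair_changepoints(gt, pr)
    if (length(gt) == 0 || length(pr) == 0) {
      expect_equal(got$TP, 0L)
      next
    }
    cost <- outer(gt, pr, function(a, b) (a - b)^2)
    ba <- brute_assignment(cost)
    tp <- sum(abs(gt[ba$rows] - pr[ba$cols]) < 5)
    expect_equal(got$TP, tp)
    expect_equal(got$FN, length(gt) - tp)
    expect_equal(got$FP, length(pr) - tp)
  }
})

test_that("jaccard and rmse implement their formulas", {
  expect_equal(jaccard(1, 1, 0), 0.5)
  expect_equal(jaccard(3, 0, 0), 1)
  expect_equal(jaccard(0, 2, 0), 0)
  expect_equal(jaccard(0, 0, 0), 1)
  pairs <- rbind(c(10, 12), c(50, 47))
  expect_equal(cp_rmse(pairs), sqrt(13 / 2))
  expect_equal(cp_rmse(rbind(c(5, 5))), 0)
  expect_true(is.na(cp_rmse(matrix(numeric(0), 0, 2))))
})

test_that("score aggregation is invariant to trajectory order", {
  set.seed(63)
  tracks <- sim_ssm_batch(6, T_range = c(20, 30))
  preds <- lapply(tracks, function(t) {
    T <- length(t$x)
    list(alpha = t$alpha + rnorm(T, sd = 0.1),
         logK = k_to_log(t$K) + rnorm(T, sd = 0.1),
         s = t$state,
         changepoints = t$changepoints)
  })
  r1 <- score_predictions(tracks, preds)
  ord <- sample(6)
  r2 <- score_predictions(tracks[ord], preds[ord])
  expect_equal(r1$mae_alpha, r2$mae_alpha)
  expect_equal(r1$male_K, r2$male_K)
  expect_equal(r1$avg_class_accuracy, r2$avg_class_accuracy)
  expect_equal(r1$jaccard, r2$jaccard)
})
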