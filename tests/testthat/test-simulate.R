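# the five biological trajectory models and dataset assembly

test_that("single-state tracks have no changepoints and the right state", {
  set.seed(10)
  tr <- simulate_ssm(sim_config("SSM"))
  expect_length(tr$changepoints, 0)
  tr <- simulate_ssm(sim_config("SSM", alpha_range = c(1.95, 1.95)))
  expect_true(all(tr$state == 3L))
  tr <- simulate_ssm(sim_config("SSM", alpha_range = c(1.0, 1.0)))
  expect_true(all(tr$state == 2L))
})

test_that("SSM ensemble MSD follows 4Kt^alpha", {
  set.seed(11)
  cfg <- sim_config("SSM", T = 30, alpha_range = c(1, 1), K_range = c(1, 1),
                    fov = 1e6)
  msd <- 0
  n <- 1000
  for (i in seq_len(n)) {
    tr <- simulate_ssm(cfg)
    msd <- msd + (tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2
  }
  msd <- (msd / n)[-1]
  fit <- stats::lm(log(msd) ~ log(1:29))
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.05)
  expect_equal(exp(unname(stats::coef(fit)[1])), 4, tolerance = 0.1)
})

test_that("multi-state transitions follow the Markov matrix", {
  set.seed(12)
  # identity matrix: never leaves the initial state
  cfg <- sim_config("MSM", trans_matrix = diag(2))
  tr <- simulate_msm(cfg)
  expect_length(tr$changepoints, 0)
  # raw chain transition count before min-duration enforcement matches the
  # geometric dwell expectation 199 * p
  P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  raw <- replicate(1000, {
    ch <- difftrack:::markov_state_chain(P, 200)
    sum(diff(ch) != 0)
  })
  expect_equal(mean(raw), 199 * 0.05, tolerance = 1 / (199 * 0.05))
  # emitted segments always last >= 3 frames
  set.seed(13)
  for (i in 1:20) {
    tr <- simulate_msm(sim_config("MSM"))
    expect_true(all(seg_lengths(tr) >= 3))
  }
})

test_that("trapped particles freeze with zeroed labels", {
  set.seed(14)
  trap <- matrix(c(64, 64), 1, 2)
  cfg <- sim_config("QTM", unbinding_prob = 0, trap_radius = 1, n_traps = 1)
  tr <- simulate_qtm(cfg, start = c(64, 64), traps = trap)
  expect_true(all(tr$state == 0L))
  expect_true(all(tr$alpha == 0) && all(tr$K == 0))
  expect_true(all(diff(tr$x) == 0) && all(diff(tr$y) == 0))
})

test_that("a trapless landscape degenerates to single-state motion", {
  set.seed(15)
  cfg <- sim_config("QTM", unbinding_prob = 0.05, trap_radius = 1)
  tr <- simulate_qtm(cfg, traps = matrix(numeric(0), 0, 2))
  expect_length(tr$changepoints, 0)
  expect_true(all(tr$state %in% c(2L, 3L)))
})

test_that("trap escape is governed by a geometric dwell law", {
  set.seed(16)
  # the dwell-time sampler itself: mean 1/p
  d <- replicate(2000, difftrack:::sample_dwell(0.1))
  expect_equal(mean(d), 10, tolerance = 0.07)
  # realized trapped dwells in simulation: geometric thinned by the 3-frame
  # minimum, i.e. memorylessly shifted to mean 2 + 1/p
  cfg <- sim_config("QTM", T = 200, unbinding_prob = 0.1, trap_radius = 2,
                    n_traps = 300)
  dwells <- c()
  for (i in 1:400) {
    tr <- simulate_qtm(cfg)
    r <- rle(tr$state == 0L)
    ends <- cumsum(r$lengths)
    # completed trapped segments only (not cut by the trajectory end)
    keep <- r$values & ends < length(tr$x)
    dwells <- c(dwells, r$lengths[keep])
  }
  expect_gt(length(dwells), 300)
  expect_equal(mean(dwells), 12, tolerance = 0.1)
})

test_that("confinement keeps the particle inside until transmitted", {
  set.seed(17)
  comp <- matrix(c(64, 64), 1, 2)
  cfg <- sim_config("TCM", transition_prob = 0, n_compartments = 1,
                    compartment_radius = 8)
  tr <- simulate_tcm(cfg, start = c(64, 64), compartments = comp)
  expect_true(all(tr$state == 1L))
  expect_true(all(tr$alpha < 1.9))
  expect_true(max(sqrt((tr$x - 64)^2 + (tr$y - 64)^2)) <= 8 + 1e-9)
})

test_that("dimers co-diffuse while bound and respect dwell laws", {
  set.seed(18)
  # far apart with tiny K: never bind, labels stay at the free parameters
  cfg <- sim_config("DIM", unbinding_prob = 0.05, interaction_radius = 0.5,
                    K_range = c(1e-6, 1e-6), fov = 128)
  pr <- simulate_dim(cfg, start = matrix(c(10, 110, 10, 110), 2, 2))
  for (tr in pr) expect_length(tr$changepoints, 0)
  # while bound the displacement sequences are identical
  set.seed(19)
  found <- FALSE
  for (i in 1:50) {
    cfg <- sim_config("DIM", unbinding_prob = 0.05, interaction_radius = 5,
                      K_range = c(0.5, 5))
    pr <- simulate_dim(cfg, start = matrix(c(64, 65, 64, 65), 2, 2))
    bound <- pr[[1]]$alpha == pr[[2]]$alpha & pr[[1]]$K == pr[[2]]$K &
      pr[[1]]$K != 0
    idx <- which(bound[-1] & bound[-length(bound)]) + 1L
    if (length(idx) > 3) {
      found <- TRUE
      expect_equal(diff(pr[[1]]$x)[idx - 1L], diff(pr[[2]]$x)[idx - 1L],
                   tolerance = 1e-12)
    }
  }
  expect_true(found)
})

test_that("emitted label series satisfy their invariants", {
  set.seed(20)
  for (model in c("SSM", "MSM", "QTM", "TCM")) {
    for (i in 1:10) {
      tr <- simulate_track(sim_config(model))
      expect_true(label_invariants_ok(tr), label = paste(model, "invariants"))
    }
  }
  for (i in 1:5) {
    pr <- simulate_dim(sim_config("DIM"))
    for (tr in pr) expect_true(label_invariants_ok(tr))
  }
})

test_that("field-of-view truncation keeps only long-enough prefixes", {
  tr <- make_track(x = c(1:25, 200, 27:30), y = rep(1, 30))
  out <- apply_fov(tr, fov = 128)
  expect_length(out$x, 25)
  tr2 <- make_track(x = c(1:10, 200, 12:30), y = rep(1, 30))
  expect_null(apply_fov(tr2, fov = 128))
})

test_that("two-segment sweep tracks carry exactly one midpoint changepoint", {
  set.seed(21)
  tr <- simulate_two_segment(0.5, 1, 1.5, 1, T = 200)
  expect_equal(tr$changepoints, 100L)
  expect_equal(tr$alpha, c(rep(0.5, 100), rep(1.5, 100)))
  # identical segments still record the reset point
  tr0 <- simulate_two_segment(1, 1, 1, 1, T = 200)
  expect_equal(tr0$changepoints, 100L)
})

test_that("same seed reproduces the identical dataset", {
  ds1 <- build_dataset(scale_factor = 6 / 5.2e6, seed = 99)
  ds2 <- build_dataset(scale_factor = 6 / 5.2e6, seed = 99)
  expect_identical(ds1, ds2)
})
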