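# architecture, losses, gradients and the training loop

test_that("parameter counts match the derived wiring", {
  set.seed(40)
  reg <- build_model("alpha")
  expect_equal(n_parameters(reg), 513991L)
  cls <- build_model("state")
  expect_equal(n_parameters(cls) - n_parameters(reg), 3L * 395L)
  expect_lt(abs(n_parameters(reg) - 513000) / 513000, 0.01)
})

test_that("forward pass returns per-frame outputs of the input length", {
  set.seed(41)
  tracks <- sim_ssm_batch(3, T_range = c(20, 35))
  m <- build_model("alpha", hidden = 8)
  b <- pad_and_batch(lapply(tracks, function(t) compute_features(t$x, t$y)))
  out <- net_forward(m, b)
  expect_equal(dim(out), c(3, 1, max(b$lengths)))
  ms <- build_model("state", hidden = 8)
  p <- predict_series(ms, tracks[[1]]$x, tracks[[1]]$y)
  expect_equal(ncol(p$logprobs), length(tracks[[1]]$x))
  # per-frame probabilities sum to one
  expect_equal(colSums(exp(p$logprobs)), rep(1, ncol(p$logprobs)),
               tolerance = 1e-6)
})

test_that("sequence losses implement the masked two-level averages", {
  gt <- rbind(rep(0.5, 10), c(rep(1, 6), rep(0, 4)))
  lens <- c(10L, 6L)
  expect_equal(loss_alpha(gt, gt, lens), 0)
  expect_equal(loss_alpha(gt + 0.5, gt, lens), 0.5)
  # per-trajectory MAEs 0.2 and 0.4 average to 0.3
  p <- gt
  p[1, ] <- gt[1, ] + 0.2
  p[2, 1:6] <- gt[2, 1:6] + 0.4
  expect_equal(loss_alpha(p, gt, lens), 0.3)
  # K loss in log10(K+1) space
  expect_equal(loss_K(matrix(2, 1, 5), matrix(1, 1, 5), 5L), 1)
  expect_equal(k_to_log(9) - k_to_log(0), 1)
  # uniform classifier: log 4, doubled by a weight of 2 on the true class
  lp <- array(log(0.25), dim = c(1, 4, 8))
  labs <- matrix(0L, 1, 8)
  expect_equal(loss_state(lp, labs, 8L), log(4))
  expect_equal(loss_state(lp, labs, 8L, w = c(2, 1, 1, 1)), 2 * log(4))
  perfect <- array(-Inf, dim = c(1, 4, 8))
  perfect[1, 1, ] <- 0
  expect_equal(loss_state(perfect, labs, 8L), 0)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  dims <- list(n_feat = 10L, hidden = 5L, n_out = 1L)
  m <- build_model("alpha", hidden = 5)
  B <- 2; Tm <- 7
  X <- array(rnorm(B * 10 * Tm), c(B, 10, Tm))
  lens <- c(7L, 5L)
  X[2, , 6:7] <- 0
  targ <- matrix(rnorm(B * Tm), B, Tm)
  r <- difftrack:::net_loss_grad_cpp(m$theta, dims, X, lens, targ, "alpha",
                                     rep(1, 4), dropout = 0)
  f <- function(th) difftrack:::net_loss_grad_cpp(
    th, dims, X, lens, targ, "alpha", rep(1, 4), dropout = 0,
    training = FALSE, want_grad = FALSE)$loss
  idx <- sample(length(m$theta), 40)
  h <- 1e-6
  for (k in idx) {
    tp <- m$theta; tp[k] <- tp[k] + h
    tm <- m$theta; tm[k] <- tm[k] - h
    fd <- (f(tp) - f(tm)) / (2 * h)
    expect_lt(abs(fd - r$grad[k]) / max(1e-6, abs(fd)), 1e-3)
  }
})

test_that("batched and single-trajectory inference agree", {
  set.seed(43)
  tracks <- sim_ssm_batch(5, T_range = c(20, 60))
  m <- build_model("K", hidden = 16)
  singles <- lapply(tracks, function(t) predict_series(m, t$x, t$y))
  batched <- predict_tracks(m, tracks, batch = 5)
  for (i in seq_along(tracks))
    expect_equal(batched[[i]], singles[[i]], tolerance = 1e-5)
})

test_that("losses decrease over optimisation steps on an overfit set", {
  set.seed(44)
  tracks <- sim_ssm_batch(64, T_range = c(20, 25), K_range = c(0.01, 100))
  cfg <- train_config(epochs = 25, batch = 32, augment = FALSE, dropout = 0)
  m <- train_model(tracks, tracks[1:8], "alpha", config = cfg)
  h <- m$history
  # 25 epochs x 2 batches = 50 optimisation steps
  expect_lt(mean(tail(h$train_loss, 3)), mean(head(h$train_loss, 3)))
  expect_lt(min(h$train_loss), h$train_loss[1] * 0.8)
})

test_that("the plateau scheduler decays the learning rate", {
  set.seed(45)
  tracks <- sim_ssm_batch(8, T_range = c(20, 22))
  # zero learning rate: losses never improve, so after `patience` epochs the
  # recorded rate must have been cut by the decay factor
  cfg <- train_config(epochs = 8, batch = 8, lr = 1e-20, patience = 3,
                      augment = FALSE, dropout = 0)
  m <- train_model(tracks, tracks, "alpha", config = cfg)
  expect_equal(m$history$lr[5], 1e-20 * 0.1)
})

test_that("checkpoints round-trip through disk", {
  set.seed(46)
  m <- build_model("alpha", hidden = 4)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$theta, m$theta)
  expect_equal(m2$config$task, "alpha")
  unlink(path)
})

test_that("class weights are inverse frequencies with mean one", {
  w <- class_weights(c(rep(0L, 10), rep(2L, 30)))
  expect_equal(w[1] / w[3], 3)
  expect_equal(mean(w[c(1, 3)]), 1)
  expect_equal(w[c(2, 4)], c(0, 0))
})
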