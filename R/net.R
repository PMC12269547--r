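#' Network configuration
#'
#' Architecture of the per-variable sequence labeller: three bidirectional
#' LSTM blocks (the first two with two stacked layers and inter-layer
#' dropout, the third with one layer), each emitting 128 features per frame
#' at the default hidden size of 64 per direction, followed by a rectified
#' linear activation, concatenation with the block input (skip connection)
#' and layer normalisation; a final per-frame linear head maps the 394-wide
#' representation to 1 output (alpha, or K in log10(K+1) space) or 4
#' log-probabilities (state).
#'
#' @param task "alpha", "K" or "state".
#' @param n_feat input feature count (10).
#' @param hidden hidden units per LSTM direction.
#' @return list of class \code{net_config}.
#' @export
net_config <- function(task = c("alpha", "K", "state"), n_feat = 10L,
                       hidden = 64L) {
  task <- match.arg(task)
  structure(list(task = task, n_feat = as.integer(n_feat),
                 hidden = as.integer(hidden),
                 n_out = if (task == "state") 4L else 1L),
            class = "net_config")
}

# layer input widths: two stacked layers per block for blocks 1-2, one for
# block 3; block outputs are concatenated with block inputs
net_layer_inputs <- function(cfg) {
  F <- cfg$n_feat; h <- cfg$hidden
  c(F, 2 * h, F + 2 * h, 2 * h, F + 4 * h)
}

# flat parameter layout, in the exact packing order of the C++ core
net_param_layout <- function(cfg) {
  h <- cfg$hidden
  ins <- net_layer_inputs(cfg)
  nm <- character(0); n <- integer(0); grp <- character(0)
  for (l in 1:5) for (dir in c("fwd", "bwd")) {
    nm <- c(nm, paste0("l", l, ".", dir, ".",
                       c("W_ih", "W_hh", "b_ih", "b_hh")))
    n <- c(n, ins[l] * 4 * h, h * 4 * h, 4 * h, 4 * h)
    grp <- c(grp, rep("lstm", 4))
  }
  cat_sizes <- cfg$n_feat + 2 * h * (1:3)
  for (b in 1:3) {
    nm <- c(nm, paste0("ln", b, c(".gamma", ".beta")))
    n <- c(n, cat_sizes[b], cat_sizes[b])
    grp <- c(grp, "ln_gamma", "ln_beta")
  }
  nm <- c(nm, "head.W", "head.b")
  n <- c(n, cat_sizes[3] * cfg$n_out, cfg$n_out)
  grp <- c(grp, "head", "head")
  data.frame(name = nm, n = n, group = grp, stringsAsFactors = FALSE)
}

#' Trainable parameter count
#'
#' @param model a model from \code{\link{build_model}}, or a
#'   \code{net_config}.
#' @return integer parameter count (513,991 for the default regression
#'   architecture; the classification head adds 3 x 395 = 1,185).
#' @export
n_parameters <- function(model) {
  cfg <- if (inherits(model, "net_config")) model else model$config
  sum(net_param_layout(cfg)$n)
}

#' Build an untrained sequence labeller
#'
#' Initialises all LSTM weights and biases uniformly in
#' \[-1/sqrt(h), 1/sqrt(h)\], layer-norm gains at 1 and shifts at 0, and the
#' head uniformly in \[-1/sqrt(in), 1/sqrt(in)\]. Uses the current R RNG
#' state, so runs reproduce under \code{set.seed}.
#'
#' @param task "alpha", "K" or "state".
#' @param hidden hidden units per LSTM direction.
#' @return list of class \code{difftrack_net} with elements \code{theta}
#'   (flat parameter vector) and \code{config}.
#' @export
build_model <- function(task = c("alpha", "K", "state"), hidden = 64L) {
  cfg <- net_config(match.arg(task), hidden = hidden)
  lay <- net_param_layout(cfg)
  h <- cfg$hidden
  k_lstm <- 1 / sqrt(h)
  k_head <- 1 / sqrt(cfg$n_feat + 6 * h)
  theta <- numeric(sum(lay$n))
  off <- 0L
  for (i in seq_len(nrow(lay))) {
    idx <- off + seq_len(lay$n[i])
    theta[idx] <- switch(lay$group[i],
      lstm = stats::runif(lay$n[i], -k_lstm, k_lstm),
      ln_gamma = 1,
      ln_beta = 0,
      head = stats::runif(lay$n[i], -k_head, k_head))
    off <- off + lay$n[i]
  }
  structure(list(theta = theta, config = cfg), class = "difftrack_net")
}

#' @export
print.difftrack_net <- function(x, ...) {
  cat(sprintf("<difftrack_net> task=%s hidden=%d parameters=%d\n",
              x$config$task, x$config$hidden, n_parameters(x)))
  invisible(x)
}

net_dims <- function(cfg) {
  list(n_feat = cfg$n_feat, hidden = cfg$hidden, n_out = cfg$n_out)
}

#' Forward pass
#'
#' Runs the network on a padded feature batch, returning per-frame outputs
#' (a (B, n_out, T) array; log-probabilities for the state task). Padded
#' frames give exactly zero.
#'
#' @param model a \code{difftrack_net}.
#' @param batch result of \code{\link{pad_and_batch}}.
#' @return numeric array (B, n_out, T).
#' @export
net_forward <- function(model, batch) {
  net_forward_cpp(model$theta, net_dims(model$config), batch$array,
                  as.integer(batch$lengths))
}

# --- losses (reference R implementations; the C++ core mirrors these) -----

masked_mae <- function(pred, gt, lengths) {
  B <- nrow(pred)
  per <- vapply(seq_len(B), function(j) {
    idx <- seq_len(lengths[j])
    mean(abs(pred[j, idx] - gt[j, idx]))
  }, numeric(1))
  mean(per)
}

#' Mean-absolute sequence loss for the anomalous exponent
#'
#' Per-trajectory mean absolute error over true (unpadded) frames, then
#' averaged over the batch.
#'
#' @param pred,gt numeric B x T matrices.
#' @param lengths integer vector of true lengths.
#' @return scalar loss.
#' @export
loss_alpha <- function(pred, gt, lengths) masked_mae(pred, gt, lengths)

#' Log-space sequence loss for the diffusion coefficient
#'
#' Mean absolute difference in log10(K+1) space; both arguments must
#' already be in that space (ground truth is converted once at data
#' loading, see \code{\link{k_to_log}}).
#'
#' @inheritParams loss_alpha
#' @return scalar loss.
#' @export
loss_K <- function(pred, gt, lengths) masked_mae(pred, gt, lengths)

#' Class-weighted negative log-likelihood for the state
#'
#' \eqn{-w_{y} \log p(y)} per frame, averaged per trajectory and then over
#' the batch.
#'
#' @param logprobs (B, 4, T) array of per-frame log-probabilities.
#' @param labels B x T integer matrix of states in 0..3.
#' @param lengths integer vector of true lengths.
#' @param w length-4 class weight vector.
#' @return scalar loss.
#' @export
loss_state <- function(logprobs, labels, lengths, w = rep(1, 4)) {
  B <- dim(logprobs)[1]
  per <- vapply(seq_len(B), function(j) {
    idx <- seq_len(lengths[j])
    lp <- vapply(idx, function(t) logprobs[j, labels[j, t] + 1L, t],
                 numeric(1))
    mean(-w[labels[j, idx] + 1L] * lp)
  }, numeric(1))
  mean(per)
}

#' Diffusion-coefficient log transform
#'
#' The network predicts and is scored on K in log10(K+1) space, which maps
#' the simulation range \[1e-12, 1e6\] onto roughly \[0, 6\].
#'
#' @param K diffusion coefficients (>= 0).
#' @return log10(K + 1).
#' @export
k_to_log <- function(K) log10(K + 1)

#' @rdname k_to_log
#' @param logK values in log10(K+1) space.
#' @export
log_to_k <- function(logK) 10^logK - 1

#' Inverse-frequency class weights
#'
#' @param states integer vector (or list of vectors) of state labels 0..3
#'   from the training split.
#' @return length-4 weight vector, normalised to mean 1 over the classes
#'   present; absent classes get weight 0.
#' @export
class_weights <- function(states) {
  s <- unlist(states, use.names = FALSE)
  counts <- tabulate(s + 1L, nbins = 4L)
  w <- ifelse(counts > 0, 1 / pmax(counts, 1), 0)
  present <- counts > 0
  w[present] <- w[present] / mean(w[present])
  w
}

# --- training -------------------------------------------------------------

#' Training configuration
#'
#' @param epochs maximum training epochs.
#' @param batch batch size.
#' @param lr initial Adam learning rate.
#' @param weight_decay L2 weight decay added to the gradient.
#' @param dropout inter-layer dropout in the first two blocks.
#' @param patience epochs without validation improvement before the
#'   learning rate is multiplied by \code{lr_factor}.
#' @param lr_factor learning-rate decay factor.
#' @param augment apply the training-time coordinate augmentations.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(epochs = 30L, batch = 32L, lr = 1e-3,
                         weight_decay = 2e-6, dropout = 0.1,
                         patience = 5L, lr_factor = 0.1, augment = TRUE) {
  stopifnot(epochs >= 1, batch >= 1, lr > 0, weight_decay >= 0,
            dropout >= 0, dropout < 1, patience >= 1, lr_factor > 0)
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, weight_decay = weight_decay, dropout = dropout,
                 patience = as.integer(patience), lr_factor = lr_factor,
                 augment = isTRUE(augment)),
            class = "train_config")
}

# extract per-frame regression/classification targets from a sim_track
track_targets <- function(track, task) {
  switch(task,
         alpha = track$alpha,
         K = k_to_log(track$K),
         state = as.integer(track$state))
}

# assemble one padded batch (features + targets) from a list of tracks
make_batch <- function(tracks, task, augment_p = 0) {
  feats <- vector("list", length(tracks))
  targs <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    x <- tr$x; y <- tr$y
    tg <- track_targets(tr, task)
    if (augment_p > 0) {
      a <- augment(x, y, p = augment_p)
      x <- a$x; y <- a$y
      tg <- tg[a$keep]
    }
    feats[[i]] <- compute_features(x, y)
    targs[[i]] <- tg
  }
  b <- pad_and_batch(feats)
  b$targets <- pad_targets(targs, Tmax = dim(b$array)[3])
  b
}

batch_loss_grad <- function(theta, cfg, b, w, dropout, want_grad = TRUE) {
  net_loss_grad_cpp(theta, net_dims(cfg), b$array, as.integer(b$lengths),
                    b$targets, cfg$task, w, dropout = dropout,
                    training = want_grad, want_grad = want_grad)
}

eval_loss <- function(theta, cfg, tracks, w, batch = 64L) {
  idx <- split(seq_along(tracks), ceiling(seq_along(tracks) / batch))
  tot <- 0
  for (ii in idx) {
    b <- make_batch(tracks[ii], cfg$task)
    r <- batch_loss_grad(theta, cfg, b, w, dropout = 0, want_grad = FALSE)
    tot <- tot + r$loss * length(ii)
  }
  tot / length(tracks)
}

#' Train a sequence labeller
#'
#' Adam with weight decay, class weights for the state task, optional
#' coordinate augmentations, and a plateau learning-rate schedule (decay by
#' \code{lr_factor} after \code{patience} epochs without validation
#' improvement). The parameters with the smallest validation loss are kept.
#'
#' @param train,val lists of \code{sim_track} objects.
#' @param task "alpha", "K" or "state".
#' @param config a \code{\link{train_config}}.
#' @param hidden hidden units per LSTM direction.
#' @param model optionally, a pre-built or pre-trained \code{difftrack_net}
#'   to continue from.
#' @param verbose print per-epoch losses.
#' @return a \code{difftrack_net} with the best-validation parameters, the
#'   training history in \code{$history} (epoch, train_loss, val_loss, lr)
#'   and the class weights used (state task).
#' @export
train_model <- function(train, val, task = c("alpha", "K", "state"),
                        config = train_config(), hidden = 64L,
                        model = NULL, verbose = FALSE) {
  task <- match.arg(task)
  if (is.null(model)) model <- build_model(task, hidden = hidden)
  cfg <- model$config
  w <- if (task == "state") {
    class_weights(lapply(train, function(t) t$state))
  } else rep(1, 4)

  theta <- model$theta
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  lr <- config$lr
  best_val <- Inf; best_theta <- theta
  since_improve <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  aug_p <- if (config$augment) 0.3 else 0

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(train))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch))
    tl <- 0
    for (ii in batches) {
      b <- make_batch(train[ii], task, augment_p = aug_p)
      r <- batch_loss_grad(theta, cfg, b, w, dropout = config$dropout)
      g <- r$grad + config$weight_decay * theta
      step <- step + 1L
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^step)
      vhat <- v / (1 - beta2^step)
      theta <- theta - lr * mhat / (sqrt(vhat) + eps)
      tl <- tl + r$loss * length(ii)
    }
    tl <- tl / length(train)
    vl <- eval_loss(theta, cfg, val, w)
    if (!is.finite(vl)) stop("validation loss is not finite; aborting")
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl,
                                   val_loss = vl, lr = lr))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f lr %.1e",
                      epoch, tl, vl, lr))
    if (vl < best_val) {
      best_val <- vl
      best_theta <- theta
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$patience) {
        lr <- lr * config$lr_factor
        since_improve <- 0L
      }
    }
  }
  structure(list(theta = best_theta, config = cfg, history = hist,
                 class_weights = w, train_config = config,
                 best_val = best_val),
            class = "difftrack_net")
}

#' Save / load a model checkpoint
#'
#' Serialises the flat parameter vector together with the architecture,
#' training configuration and history.
#'
#' @param model a \code{difftrack_net}.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "difftrack_net"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  obj$config <- structure(obj$config, class = "net_config")
  structure(obj, class = "difftrack_net")
}

#' Pointwise prediction for one trajectory
#'
#' Extracts features (no augmentation) and runs one forward pass. For
#' regression tasks returns the per-frame series; for the state task
#' returns the per-frame log-probabilities and the argmax labels.
#'
#' @param model a trained \code{difftrack_net}.
#' @param x,y coordinate vectors.
#' @return numeric vector of length T ("alpha": alpha_hat; "K": K_hat in
#'   log10(K+1) space), or for "state" a list with \code{logprobs}
#'   (4 x T) and \code{s_hat} (integer vector in 0..3).
#' @export
predict_series <- function(model, x, y) {
  b <- pad_and_batch(list(compute_features(x, y)))
  out <- net_forward(model, b)
  if (model$config$task == "state") {
    lp <- matrix(out[1, , ], nrow = 4)
    list(logprobs = lp, s_hat = as.integer(apply(lp, 2, which.max) - 1L))
  } else {
    as.numeric(out[1, 1, ])
  }
}

#' Batched pointwise prediction
#'
#' @param model a trained \code{difftrack_net}.
#' @param tracks list of \code{sim_track} objects (or any list with
#'   \code{x}, \code{y}).
#' @param batch batch size.
#' @return list (one element per track) of prediction series as in
#'   \code{\link{predict_series}}.
#' @export
predict_tracks <- function(model, tracks, batch = 64L) {
  out <- vector("list", length(tracks))
  idx <- split(seq_along(tracks), ceiling(seq_along(tracks) / batch))
  for (ii in idx) {
    b <- pad_and_batch(lapply(tracks[ii], function(t)
      compute_features(t$x, t$y)))
    yb <- net_forward(model, b)
    for (k in seq_along(ii)) {
      Tk <- b$lengths[k]
      out[[ii[k]]] <- if (model$config$task == "state") {
        lp <- matrix(yb[k, , seq_len(Tk)], nrow = 4)
        list(logprobs = lp, s_hat = as.integer(apply(lp, 2, which.max) - 1L))
      } else {
        as.numeric(yb[k, 1, seq_len(Tk)])
      }
    }
  }
  out
}
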