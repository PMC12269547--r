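#' Simulation configuration
#'
#' Builds a validated configuration for one of the five biological
#' trajectory models: single-state (SSM), multi-state (MSM), quenched-trap
#' (QTM), transient-confinement (TCM) and dimerization (DIM). Model-specific
#' parameters left \code{NULL} are sampled per trajectory from their
#' simulation ranges (see \code{\link{sim_param_ranges}}).
#'
#' @param model one of "SSM", "MSM", "QTM", "TCM", "DIM".
#' @param T trajectory length in frames (20-200).
#' @param fov field-of-view side length in pixels; particles start uniformly
#'   inside it and are truncated on exit by \code{\link{apply_fov}}.
#' @param alpha_range interval within \[0, 2\] from which free/segment
#'   anomalous exponents are drawn.
#' @param K_range interval within \[1e-12, 1e6\] (pixels^2/frame^alpha) from
#'   which diffusion coefficients are drawn, log-uniformly in log10(K+1).
#' @param n_states MSM: number of diffusive states (2 or 3), or NULL to sample.
#' @param trans_matrix MSM: row-stochastic transition matrix, or NULL to
#'   sample per-frame switching probabilities uniformly from \[0.01, 0.1\].
#' @param unbinding_prob QTM/DIM: per-frame escape probability in \[0, 0.1\],
#'   or NULL to sample.
#' @param trap_radius QTM: trap disc radius in pixels (\[0.5, 2\]), or NULL.
#' @param n_traps QTM: number of traps (100-300), or NULL.
#' @param interaction_radius DIM: binding radius in pixels (\[0.5, 5\]), or NULL.
#' @param transition_prob TCM: boundary transmittance in \[0, 0.3\], or NULL.
#' @param n_compartments TCM: number of compartments (30-50), or NULL.
#' @param compartment_radius TCM: compartment radius in pixels (\[5, 10\]), or NULL.
#' @param fixed_alpha,fixed_K when set, every segment draw of that variable
#'   returns this value instead of a fresh sample — used for datasets in
#'   which changepoints occur in only one of alpha or K.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(model = c("SSM", "MSM", "QTM", "TCM", "DIM"),
                       T = 200L, fov = 128,
                       alpha_range = c(0, 2),
                       K_range = c(1e-12, 1e6),
                       n_states = NULL, trans_matrix = NULL,
                       unbinding_prob = NULL,
                       trap_radius = NULL, n_traps = NULL,
                       interaction_radius = NULL,
                       transition_prob = NULL,
                       n_compartments = NULL, compartment_radius = NULL,
                       fixed_alpha = NULL, fixed_K = NULL) {
  model <- match.arg(model)
  T <- as.integer(T)
  stopifnot(T >= 20L, T <= 200L, fov > 0,
            length(alpha_range) == 2, alpha_range[1] >= 0, alpha_range[2] <= 2,
            alpha_range[1] <= alpha_range[2],
            length(K_range) == 2, K_range[1] >= 0, K_range[2] <= 1e6,
            K_range[1] <= K_range[2])
  rg <- sim_param_ranges()
  chk <- function(x, range, name) {
    if (!is.null(x) && (any(x < range[1]) || any(x > range[2])))
      stop(sprintf("%s outside simulation range [%g, %g]", name,
                   range[1], range[2]))
    x
  }
  if (!is.null(trans_matrix)) {
    trans_matrix <- as.matrix(trans_matrix)
    if (nrow(trans_matrix) != ncol(trans_matrix) ||
        any(trans_matrix < 0) ||
        any(abs(rowSums(trans_matrix) - 1) > 1e-8))
      stop("trans_matrix must be square and row-stochastic")
    if (is.null(n_states)) n_states <- nrow(trans_matrix)
  }
  structure(list(
    model = model, T = T, fov = fov,
    alpha_range = alpha_range, K_range = K_range,
    n_states = n_states, trans_matrix = trans_matrix,
    unbinding_prob = chk(unbinding_prob, rg$unbinding_prob, "unbinding_prob"),
    trap_radius = chk(trap_radius, rg$trap_radius, "trap_radius"),
    n_traps = if (is.null(n_traps)) NULL else as.integer(n_traps),
    interaction_radius = chk(interaction_radius, rg$interaction_radius,
                             "interaction_radius"),
    transition_prob = chk(transition_prob, rg$transition_prob,
                          "transition_prob"),
    n_compartments = if (is.null(n_compartments)) NULL
                     else as.integer(n_compartments),
    compartment_radius = chk(compartment_radius, rg$compartment_radius,
                             "compartment_radius"),
    fixed_alpha = chk(fixed_alpha, c(0, 2), "fixed_alpha"),
    fixed_K = chk(fixed_K, c(0, 1e6), "fixed_K")
  ), class = "sim_config")
}

#' Simulation parameter sampling ranges
#'
#' The per-model parameter ranges used when a \code{\link{sim_config}} field
#' is left unspecified, following the challenge simulation protocol.
#'
#' @return named list of ranges.
#' @export
sim_param_ranges <- function() {
  list(alpha = c(0, 2), K = c(1e-12, 1e6),
       n_states = c(2L, 3L),
       unbinding_prob = c(0, 0.1),
       trap_radius = c(0.5, 2), n_traps = c(100L, 300L),
       interaction_radius = c(0.5, 5),
       transition_prob = c(0, 0.3),
       n_compartments = c(30L, 50L), compartment_radius = c(5, 10),
       # per-frame switching probability used when sampling MSM transition
       # matrices (dwell times of 10-100 frames)
       msm_switch_prob = c(0.01, 0.1))
}

# --- parameter sampling helpers -------------------------------------------

sample_alpha <- function(range) stats::runif(1, range[1], range[2])

# log-uniform over log10(K + 1): an 18-decade range sampled uniformly would
# essentially never produce small K
sample_K <- function(range) {
  lo <- log10(range[1] + 1)
  hi <- log10(range[2] + 1)
  10^stats::runif(1, lo, hi) - 1
}

# s = 3 (directed) iff alpha >= 1.9, else free diffusion; trapping and
# confinement are assigned by the models themselves
state_from_alpha <- function(alpha) ifelse(alpha >= 1.9, 3L, 2L)

# confined alpha must stay below the directed-motion threshold
sample_alpha_confined <- function(range) {
  hi <- min(range[2], 1.9 - 1e-9)
  lo <- min(range[1], hi)
  stats::runif(1, lo, hi)
}

# config-aware draws honouring fixed_alpha / fixed_K overrides
maybe_alpha <- function(config, confined = FALSE) {
  if (!is.null(config$fixed_alpha)) {
    if (confined) return(min(config$fixed_alpha, 1.9 - 1e-9))
    return(config$fixed_alpha)
  }
  if (confined) sample_alpha_confined(config$alpha_range)
  else sample_alpha(config$alpha_range)
}

maybe_K <- function(config) {
  if (!is.null(config$fixed_K)) return(config$fixed_K)
  sample_K(config$K_range)
}

# geometric dwell time (number of frames spent in a state before a
# transition fires), support {1, 2, ...}, mean 1/p
sample_dwell <- function(p) {
  if (p <= 0) return(Inf)
  stats::rgeom(1, p) + 1
}

# --- label assembly -------------------------------------------------------

# changepoints in the half-open 0-based convention: frame c starts a new
# segment, so c is recorded whenever the label at frame c differs from c-1
label_changepoints <- function(alpha, K, state) {
  T <- length(alpha)
  if (T < 2) return(integer(0))
  chg <- (alpha[-1] != alpha[-T]) | (K[-1] != K[-T]) | (state[-1] != state[-T])
  which(chg)
}

make_sim_track <- function(x, y, alpha, K, state, model,
                           changepoints = NULL) {
  if (is.null(changepoints)) changepoints <- label_changepoints(alpha, K, state)
  structure(list(x = x, y = y,
                 alpha = alpha, K = K, state = as.integer(state),
                 changepoints = as.integer(changepoints),
                 model = model),
            class = "sim_track")
}

#' @export
print.sim_track <- function(x, ...) {
  cat(sprintf("<sim_track> model=%s T=%d changepoints=%d\n",
              x$model, length(x$x), length(x$changepoints)))
  invisible(x)
}

# merge segments shorter than min_len into their predecessor (a short
# leading segment takes the following segment's labels); operates on the
# joint (alpha, K, state) labelling and recomputes changepoints
enforce_min_segments <- function(track, min_len = 3L) {
  T <- length(track$alpha)
  repeat {
    cps <- label_changepoints(track$alpha, track$K, track$state)
    bounds <- c(0L, cps, T)
    lens <- diff(bounds)
    short <- which(lens < min_len)
    if (length(short) == 0 || length(lens) == 1) break
    i <- short[1]
    from <- bounds[i] + 1L       # 1-based start of the short segment
    to <- bounds[i + 1L]         # 1-based end
    src <- if (i == 1L) to + 1L else from - 1L  # donor frame
    track$alpha[from:to] <- track$alpha[src]
    track$K[from:to] <- track$K[src]
    track$state[from:to] <- track$state[src]
  }
  track$changepoints <- label_changepoints(track$alpha, track$K, track$state)
  track
}

# --- model simulators -----------------------------------------------------

#' Simulate a single-state trajectory
#'
#' One (alpha, K) pair for the whole trajectory; no changepoints. The state
#' is directed (s = 3) when alpha >= 1.9, free (s = 2) otherwise.
#'
#' @param config a \code{\link{sim_config}} with \code{model = "SSM"}.
#' @return a \code{sim_track}.
#' @export
simulate_ssm <- function(config) {
  alpha <- maybe_alpha(config)
  K <- maybe_K(config)
  T <- config$T
  seg <- simulate_segment(alpha, K, T - 1L)
  p0 <- stats::runif(2, 0, config$fov)
  make_sim_track(x = p0[1] + c(0, cumsum(seg$dx)),
                 y = p0[2] + c(0, cumsum(seg$dy)),
                 alpha = rep(alpha, T), K = rep(K, T),
                 state = rep(state_from_alpha(alpha), T),
                 model = "SSM")
}

# frame-indexed Markov state chain; states 1..N, P row-stochastic
markov_state_chain <- function(P, T) {
  N <- nrow(P)
  s <- integer(T)
  s[1] <- sample.int(N, 1)
  for (t in 2:T) {
    s[t] <- sample.int(N, 1, prob = P[s[t - 1], ])
  }
  s
}

sample_trans_matrix <- function(N) {
  rg <- sim_param_ranges()$msm_switch_prob
  P <- matrix(0, N, N)
  for (i in 1:N) {
    q <- stats::runif(1, rg[1], rg[2])       # total switching probability
    w <- stats::runif(N - 1)
    P[i, -i] <- q * w / sum(w)
    P[i, i] <- 1 - q
  }
  P
}

#' Simulate a multi-state trajectory
#'
#' A per-frame Markov chain over 2 or 3 diffusive states, each carrying its
#' own (alpha, K); dwells shorter than 3 frames are merged into their
#' predecessor before displacement synthesis, and each segment's fGN is
#' drawn independently (memory resets at changepoints).
#'
#' @param config a \code{\link{sim_config}} with \code{model = "MSM"}.
#' @return a \code{sim_track}.
#' @export
simulate_msm <- function(config) {
  N <- config$n_states
  if (is.null(N)) N <- sample(2:3, 1)
  P <- config$trans_matrix
  if (is.null(P)) P <- sample_trans_matrix(N)
  T <- config$T
  alphas <- replicate(N, maybe_alpha(config))
  Ks <- replicate(N, maybe_K(config))
  chain <- markov_state_chain(P, T)
  tr <- make_sim_track(x = numeric(T), y = numeric(T),
                       alpha = alphas[chain], K = Ks[chain],
                       state = state_from_alpha(alphas[chain]),
                       model = "MSM")
  tr <- enforce_min_segments(tr)
  # synthesise displacements segment by segment
  p0 <- stats::runif(2, 0, config$fov)
  x <- numeric(T); y <- numeric(T)
  x[1] <- p0[1]; y[1] <- p0[2]
  bounds <- c(0L, tr$changepoints, T)
  for (i in seq_len(length(bounds) - 1L)) {
    from <- bounds[i] + 1L; to <- bounds[i + 1L]
    # steps into frames from..to (frame `from` is this segment's first frame;
    # the step entering it already uses the segment's parameters), except the
    # very first frame of the trajectory which has no incoming step
    lo <- if (i == 1L) 2L else from
    if (lo > to) next
    n <- to - lo + 1L
    seg <- simulate_segment(tr$alpha[lo], tr$K[lo], n)
    x[lo:to] <- x[lo - 1L] + cumsum(seg$dx)
    y[lo:to] <- y[lo - 1L] + cumsum(seg$dy)
  }
  tr$x <- x; tr$y <- y
  tr
}

# lazily consumed fGN displacement stream for event-driven models
new_stream <- function(alpha, K, n) {
  if (n < 1) return(list(dx = numeric(0), dy = numeric(0), i = 1L))
  seg <- simulate_segment(alpha, K, n)
  list(dx = seg$dx, dy = seg$dy, i = 1L)
}

#' Simulate a quenched-trap trajectory
#'
#' Traps are discs placed uniformly in the field of view (they may overlap).
#' A particle entering a trap binds with probability 1; while trapped the
#' position is frozen and alpha = K = s = 0. Each trapped frame escapes with
#' the unbinding probability; after an escape the particle does not rebind
#' until it has left the trap disc. Transitions are suppressed while the
#' current behavioural segment is shorter than 3 frames.
#'
#' @param config a \code{\link{sim_config}} with \code{model = "QTM"}.
#' @param start optional starting position (length-2 numeric), e.g. to place
#'   the particle inside a trap.
#' @param traps optional 2-column matrix of trap centres overriding random
#'   placement.
#' @return a \code{sim_track}.
#' @export
simulate_qtm <- function(config, start = NULL, traps = NULL) {
  rg <- sim_param_ranges()
  p_unb <- config$unbinding_prob %||% stats::runif(1, rg$unbinding_prob[1],
                                                   rg$unbinding_prob[2])
  r_trap <- config$trap_radius %||% stats::runif(1, rg$trap_radius[1],
                                                 rg$trap_radius[2])
  n_traps <- config$n_traps %||%
    sample(rg$n_traps[1]:rg$n_traps[2], 1)
  if (is.null(traps)) {
    traps <- cbind(stats::runif(n_traps, 0, config$fov),
                   stats::runif(n_traps, 0, config$fov))
  }
  alpha_f <- maybe_alpha(config)
  K_f <- maybe_K(config)
  s_f <- state_from_alpha(alpha_f)
  T <- config$T
  x <- numeric(T); y <- numeric(T)
  p <- if (is.null(start)) stats::runif(2, 0, config$fov) else start
  x[1] <- p[1]; y[1] <- p[2]
  alpha <- numeric(T); K <- numeric(T); state <- integer(T)

  in_trap <- function(px, py) {
    if (nrow(traps) == 0) return(FALSE)
    any((traps[, 1] - px)^2 + (traps[, 2] - py)^2 <= r_trap^2)
  }
  trapped <- in_trap(p[1], p[2])
  escape_pending <- FALSE  # released but still inside the trap disc
  seg_age <- 1L
  stream <- new_stream(alpha_f, K_f, T - 1L)
  set_label <- function(t, trap) {
    if (trap) c(0, 0, 0L) else c(alpha_f, K_f, s_f)
  }
  lab <- set_label(1L, trapped)
  alpha[1] <- lab[1]; K[1] <- lab[2]; state[1] <- lab[3]

  for (t in 2:T) {
    if (trapped) {
      if (seg_age >= 3L && stats::runif(1) < p_unb) {
        trapped <- FALSE
        escape_pending <- TRUE
        stream <- new_stream(alpha_f, K_f, T - t + 1L)
        seg_age <- 0L
      }
    }
    if (trapped) {
      x[t] <- x[t - 1L]; y[t] <- y[t - 1L]
    } else {
      x[t] <- x[t - 1L] + stream$dx[stream$i]
      y[t] <- y[t - 1L] + stream$dy[stream$i]
      stream$i <- stream$i + 1L
      inside <- in_trap(x[t], y[t])
      if (escape_pending && !inside) escape_pending <- FALSE
      if (!escape_pending && inside && seg_age >= 3L) {
        trapped <- TRUE
        seg_age <- 0L
      }
    }
    seg_age <- seg_age + 1L
    lab <- set_label(t, trapped)
    alpha[t] <- lab[1]; K[t] <- lab[2]; state[t] <- lab[3]
  }
  enforce_min_segments(
    make_sim_track(x, y, alpha, K, state, model = "QTM"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# non-overlapping disc placement by rejection sampling; gives up on a disc
# after max_try attempts and returns what fits
place_compartments <- function(n, radius, fov, max_try = 2000L) {
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    for (k in seq_len(max_try)) {
      p <- stats::runif(2, 0, fov)
      if (nrow(centers) == 0 ||
          all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 >
              (2 * radius)^2)) {
        centers <- rbind(centers, p)
        break
      }
    }
  }
  centers
}

#' Simulate a transient-confinement trajectory
#'
#' Non-overlapping compartment discs; inside a compartment the confined
#' (alpha, K) applies with s = 1. A step crossing the wall from inside is
#' transmitted with the transition probability and otherwise reflected back
#' radially; entry from outside is unhindered. Transitions are suppressed
#' while the current segment is shorter than 3 frames.
#'
#' @param config a \code{\link{sim_config}} with \code{model = "TCM"}.
#' @param start optional starting position.
#' @param compartments optional 2-column matrix of compartment centres.
#' @return a \code{sim_track}.
#' @export
simulate_tcm <- function(config, start = NULL, compartments = NULL) {
  rg <- sim_param_ranges()
  p_tr <- config$transition_prob %||% stats::runif(1, rg$transition_prob[1],
                                                   rg$transition_prob[2])
  radius <- config$compartment_radius %||%
    stats::runif(1, rg$compartment_radius[1], rg$compartment_radius[2])
  n_comp <- config$n_compartments %||%
    sample(rg$n_compartments[1]:rg$n_compartments[2], 1)
  if (is.null(compartments))
    compartments <- place_compartments(n_comp, radius, config$fov)
  alpha_f <- maybe_alpha(config)
  K_f <- maybe_K(config)
  s_f <- state_from_alpha(alpha_f)
  alpha_c <- maybe_alpha(config, confined = TRUE)
  K_c <- maybe_K(config)
  T <- config$T
  x <- numeric(T); y <- numeric(T)
  p <- if (is.null(start)) stats::runif(2, 0, config$fov) else start
  x[1] <- p[1]; y[1] <- p[2]
  alpha <- numeric(T); K <- numeric(T); state <- integer(T)

  comp_of <- function(px, py) {
    if (nrow(compartments) == 0) return(0L)
    d2 <- (compartments[, 1] - px)^2 + (compartments[, 2] - py)^2
    i <- which.min(d2)
    if (d2[i] <= radius^2) i else 0L
  }
  cur <- comp_of(p[1], p[2])
  confined <- cur > 0L
  seg_age <- 1L
  stream <- if (confined) new_stream(alpha_c, K_c, T - 1L)
            else new_stream(alpha_f, K_f, T - 1L)
  lab <- if (confined) c(alpha_c, K_c, 1L) else c(alpha_f, K_f, s_f)
  alpha[1] <- lab[1]; K[1] <- lab[2]; state[1] <- lab[3]

  for (t in 2:T) {
    dx <- stream$dx[stream$i]; dy <- stream$dy[stream$i]
    stream$i <- stream$i + 1L
    nx <- x[t - 1L] + dx; ny <- y[t - 1L] + dy
    if (confined) {
      cc <- compartments[cur, ]
      d <- sqrt((nx - cc[1])^2 + (ny - cc[2])^2)
      crossing <- d > radius
      if (crossing && seg_age >= 3L && stats::runif(1) < p_tr) {
        confined <- FALSE
        stream <- new_stream(alpha_f, K_f, T - t + 1L)
        seg_age <- 0L
      } else if (crossing) {
        # radial reflection at the wall
        scale <- max(2 * radius - d, 0) / d
        nx <- cc[1] + (nx - cc[1]) * scale
        ny <- cc[2] + (ny - cc[2]) * scale
      }
    } else {
      hit <- comp_of(nx, ny)
      if (hit > 0L && seg_age >= 3L) {
        confined <- TRUE
        cur <- hit
        stream <- new_stream(alpha_c, K_c, T - t + 1L)
        seg_age <- 0L
      }
    }
    x[t] <- nx; y[t] <- ny
    seg_age <- seg_age + 1L
    lab <- if (confined) c(alpha_c, K_c, 1L) else c(alpha_f, K_f, s_f)
    alpha[t] <- lab[1]; K[t] <- lab[2]; state[t] <- lab[3]
  }
  enforce_min_segments(
    make_sim_track(x, y, alpha, K, state, model = "TCM"))
}

#' Simulate a dimerizing pair of trajectories
#'
#' Two particles diffuse freely with their own (alpha, K); when their
#' separation falls within the interaction radius they bind (probability 1)
#' and subsequently share identical displacements drawn with the dimer's
#' (alpha, K). Each bound frame unbinds with the unbinding probability;
#' after unbinding the pair does not rebind until their separation exceeds
#' the interaction radius. Both particles are returned as labelled tracks.
#'
#' @param config a \code{\link{sim_config}} with \code{model = "DIM"}.
#' @param start optional 2x2 matrix of starting positions (one row per
#'   particle).
#' @return list of two \code{sim_track} objects.
#' @export
simulate_dim <- function(config, start = NULL) {
  rg <- sim_param_ranges()
  p_unb <- config$unbinding_prob %||% stats::runif(1, rg$unbinding_prob[1],
                                                   rg$unbinding_prob[2])
  r_int <- config$interaction_radius %||%
    stats::runif(1, rg$interaction_radius[1], rg$interaction_radius[2])
  free <- lapply(1:2, function(i)
    list(alpha = maybe_alpha(config),
         K = maybe_K(config)))
  alpha_d <- maybe_alpha(config)
  K_d <- maybe_K(config)
  T <- config$T
  if (is.null(start))
    start <- matrix(stats::runif(4, 0, config$fov), 2, 2)
  x <- matrix(0, T, 2); y <- matrix(0, T, 2)
  x[1, ] <- start[, 1]; y[1, ] <- start[, 2]
  streams <- lapply(free, function(f) new_stream(f$alpha, f$K, T - 1L))
  sep <- function(t) sqrt((x[t, 1] - x[t, 2])^2 + (y[t, 1] - y[t, 2])^2)
  bound <- sep(1) <= r_int
  release_pending <- FALSE
  if (bound) streams <- list(new_stream(alpha_d, K_d, T - 1L))
  seg_age <- 1L
  bound_t <- logical(T); bound_t[1] <- bound

  for (t in 2:T) {
    if (bound) {
      if (seg_age >= 3L && stats::runif(1) < p_unb) {
        bound <- FALSE
        release_pending <- TRUE
        streams <- lapply(free, function(f) new_stream(f$alpha, f$K, T - t + 1L))
        seg_age <- 0L
      }
    }
    if (bound) {
      dx <- streams[[1]]$dx[streams[[1]]$i]
      dy <- streams[[1]]$dy[streams[[1]]$i]
      streams[[1]]$i <- streams[[1]]$i + 1L
      x[t, ] <- x[t - 1L, ] + dx
      y[t, ] <- y[t - 1L, ] + dy
    } else {
      for (i in 1:2) {
        x[t, i] <- x[t - 1L, i] + streams[[i]]$dx[streams[[i]]$i]
        y[t, i] <- y[t - 1L, i] + streams[[i]]$dy[streams[[i]]$i]
        streams[[i]]$i <- streams[[i]]$i + 1L
      }
      near <- sep(t) <= r_int
      if (release_pending && !near) release_pending <- FALSE
      if (!release_pending && near && seg_age >= 3L) {
        bound <- TRUE
        streams <- list(new_stream(alpha_d, K_d, T - t + 1L))
        seg_age <- 0L
      }
    }
    seg_age <- seg_age + 1L
    bound_t[t] <- bound
  }
  lapply(1:2, function(i) {
    a <- ifelse(bound_t, alpha_d, free[[i]]$alpha)
    Kv <- ifelse(bound_t, K_d, free[[i]]$K)
    s <- state_from_alpha(a)
    enforce_min_segments(
      make_sim_track(x[, i], y[, i], a, Kv, s, model = "DIM"))
  })
}

#' Simulate one trajectory under a configuration
#'
#' Dispatches to the model-specific simulator. For DIM both particles are
#' produced; set \code{which} to select one or keep both.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{sim_track} (or list of two for DIM).
#' @export
simulate_track <- function(config) {
  switch(config$model,
         SSM = simulate_ssm(config),
         MSM = simulate_msm(config),
         QTM = simulate_qtm(config),
         TCM = simulate_tcm(config),
         DIM = simulate_dim(config))
}

#' Truncate a trajectory at the field-of-view boundary
#'
#' Frames from the first exit of the \code{fov} x \code{fov} square onwards
#' are dropped; the track is kept only if at least \code{min_T} frames
#' remain (otherwise NULL). A trailing label segment cut below 3 frames is
#' merged into its predecessor.
#'
#' @param track a \code{sim_track}.
#' @param fov field-of-view side length in pixels.
#' @param min_T minimum surviving length in frames.
#' @return truncated \code{sim_track}, or NULL if too short.
#' @export
apply_fov <- function(track, fov, min_T = 20L) {
  out <- track$x < 0 | track$x > fov | track$y < 0 | track$y > fov
  cut <- if (any(out)) which(out)[1] - 1L else length(track$x)
  if (cut < min_T) return(NULL)
  idx <- seq_len(cut)
  tr <- make_sim_track(track$x[idx], track$y[idx], track$alpha[idx],
                       track$K[idx], track$state[idx], track$model)
  enforce_min_segments(tr)
}

#' Simulate a two-segment trajectory with a midpoint changepoint
#'
#' Evaluation helper for changepoint-sensitivity sweeps: a trajectory of
#' length \code{T} with exactly one recorded changepoint at \code{floor(T/2)},
#' segment parameters given explicitly. The changepoint is recorded even if
#' the two segments share identical parameters (the fGN memory still resets
#' there), which is what makes a zero-difference sweep point meaningful.
#'
#' @param alpha1,K1 first-segment parameters.
#' @param alpha2,K2 second-segment parameters.
#' @param T trajectory length in frames.
#' @param cp changepoint frame (default the midpoint); must leave both
#'   segments at least 3 frames.
#' @return a \code{sim_track} with one changepoint at \code{cp}.
#' @export
simulate_two_segment <- function(alpha1, K1, alpha2, K2, T = 200L,
                                 cp = NULL) {
  T <- as.integer(T)
  cp <- if (is.null(cp)) T %/% 2L else as.integer(cp)
  stopifnot(cp >= 3L, T - cp >= 3L)
  seg1 <- simulate_segment(alpha1, K1, cp - 1L)
  seg2 <- simulate_segment(alpha2, K2, T - cp)
  dx <- c(seg1$dx, seg2$dx); dy <- c(seg1$dy, seg2$dy)
  alpha <- c(rep(alpha1, cp), rep(alpha2, T - cp))
  K <- c(rep(K1, cp), rep(K2, T - cp))
  make_sim_track(x = c(0, cumsum(dx)), y = c(0, cumsum(dy)),
                 alpha = alpha, K = K,
                 state = state_from_alpha(alpha), model = "MSM2",
                 changepoints = cp)
}
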