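#' Feature row names
#'
#' Fixed row order of the 10-feature matrix fed to the sequence labellers.
#' @return character vector of length 10.
#' @export
feature_names <- function() {
  c("x_norm", "y_norm", "dist_origin", "step_norm", "angle",
    "straightness", "straightness2", "F_x", "F_y", "F_step")
}

#' z-normalise a series
#'
#' Centre to zero mean and scale to unit variance using the population
#' standard deviation. A constant series (sigma = 0, an immobile particle)
#' maps to all zeros.
#'
#' @param v numeric vector (length >= 1).
#' @return numeric vector of the same length.
#' @export
znorm <- function(v) {
  stopifnot(length(v) >= 1)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) return(rep(0, length(v)))
  (v - m) / s
}

#' Compute the 10-feature matrix for one trajectory
#'
#' Derives, from raw pixel coordinates, the multivariate time series used as
#' network input (rows in the order of \code{\link{feature_names}}):
#' z-normalised coordinates; distance from the origin
#' \eqn{d(t) = \sqrt{(x(t)-x(0))^2 + (y(t)-y(0))^2}}; z-normalised step size;
#' the signed turning angle between consecutive displacement vectors;
#' two straightness measures computed on the normalised coordinates (net
#' displacement over path length, and its squared analogue), both 1 for a
#' perfectly straight path and 0 for a path returning to its start; and
#' log absolute first differences \eqn{F(k) = \log|\Delta k(t)|} of the
#' normalised coordinates and step series (differences clamped below at
#' 1e-12 before the log).
#'
#' Series shorter than T (steps: T-1, angles: T-2, differences: T-1) are
#' post-padded with zeros; the straightness measures are defined as 0 at
#' t = 0 where no path exists yet.
#'
#' @param x,y numeric coordinate vectors, length T >= 2.
#' @return 10 x T numeric matrix with rownames \code{feature_names()}.
#' @export
compute_features <- function(x, y) {
  T <- length(x)
  if (T < 2 || length(y) != T) stop("need x and y of equal length >= 2")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  xn <- znorm(x)
  yn <- znorm(y)
  d <- sqrt((x - x[1])^2 + (y - y[1])^2)

  dx <- diff(x); dy <- diff(y)
  step <- sqrt(dx^2 + dy^2)            # length T-1
  stepn <- znorm(step)

  # signed angle between consecutive displacement vectors, in (-pi, pi];
  # zero-length steps give an undefined angle, reported as 0
  ang <- numeric(max(T - 2L, 0L))
  if (T >= 3) {
    cross <- dx[-(T - 1)] * dy[-1] - dy[-(T - 1)] * dx[-1]
    dot <- dx[-(T - 1)] * dx[-1] + dy[-(T - 1)] * dy[-1]
    ang <- atan2(cross, dot)
    ang[step[-(T - 1)] == 0 | step[-1] == 0] <- 0
  }

  # straightness on the normalised coordinates
  dxn <- diff(xn); dyn <- diff(yn)
  net <- sqrt((xn - xn[1])^2 + (yn - yn[1])^2)
  path <- c(0, cumsum(sqrt(dxn^2 + dyn^2)))
  path2 <- c(0, cumsum(dxn^2 + dyn^2))
  str1 <- ifelse(path > 0, net / path, 0)
  str2 <- ifelse(path2 > 0, net^2 / path2, 0)
  str1[1] <- 0; str2[1] <- 0

  logdiff <- function(v) log(pmax(abs(diff(v)), 1e-12))

  pad <- function(v) c(v, numeric(T - length(v)))
  out <- rbind(xn, yn, d, pad(stepn), pad(ang), str1, str2,
               pad(logdiff(xn)), pad(logdiff(yn)), pad(logdiff(stepn)))
  rownames(out) <- feature_names()
  out
}

#' Training-time coordinate augmentations
#'
#' Applies, each independently with probability \code{p} and in the fixed
#' order noise, rotation, axis flips, truncation: additive Gaussian noise
#' (sd 0.1 px); rotation by a uniform angle in \[0, 2pi); x and/or y axis
#' flips; and truncation to a random window of at least \code{t_min} frames.
#' Features must be recomputed on the augmented coordinates.
#'
#' @param x,y coordinate vectors (length >= \code{t_min}).
#' @param p per-augmentation probability.
#' @param noise_sd Gaussian noise standard deviation in pixels.
#' @param t_min minimum trajectory length after truncation.
#' @return list with augmented \code{x}, \code{y} and the retained frame
#'   indices \code{keep} (for truncating labels to match).
#' @export
augment <- function(x, y, p = 0.3, noise_sd = 0.1, t_min = 20L) {
  T <- length(x)
  stopifnot(length(y) == T, T >= t_min)
  if (stats::runif(1) < p) {
    x <- x + stats::rnorm(T, 0, noise_sd)
    y <- y + stats::rnorm(T, 0, noise_sd)
  }
  if (stats::runif(1) < p) {
    th <- stats::runif(1, 0, 2 * pi)
    xr <- cos(th) * x - sin(th) * y
    y <- sin(th) * x + cos(th) * y
    x <- xr
  }
  if (stats::runif(1) < p) x <- -x
  if (stats::runif(1) < p) y <- -y
  keep <- seq_len(T)
  if (stats::runif(1) < p) {
    t1 <- sample.int(T - t_min + 1L, 1L)              # window start
    ends <- seq.int(t1 + t_min - 1L, T)               # admissible window ends
    t2 <- ends[sample.int(length(ends), 1L)]
    keep <- t1:t2
    x <- x[keep]; y <- y[keep]
  }
  list(x = x, y = y, keep = keep)
}

#' Pad feature matrices into a batch
#'
#' Stacks a list of 10 x T_j feature matrices into a (B, 10, T_max) array,
#' post-padding with zeros; true lengths are recorded for loss masking.
#'
#' @param mats list of feature matrices from \code{\link{compute_features}}.
#' @return list with \code{array} of dim (B, 10, T_max) and integer
#'   \code{lengths}.
#' @export
pad_and_batch <- function(mats) {
  stopifnot(length(mats) >= 1)
  lens <- vapply(mats, ncol, integer(1))
  Tmax <- max(lens)
  B <- length(mats)
  nf <- nrow(mats[[1]])
  arr <- array(0, dim = c(B, nf, Tmax))
  for (j in seq_len(B)) arr[j, , seq_len(lens[j])] <- mats[[j]]
  list(array = arr, lengths = lens)
}

# pad a list of per-frame target vectors into a B x Tmax matrix
pad_targets <- function(targets, Tmax = NULL, fill = 0) {
  lens <- lengths(targets)
  if (is.null(Tmax)) Tmax <- max(lens)
  out <- matrix(fill, length(targets), Tmax)
  for (j in seq_along(targets)) out[j, seq_len(lens[j])] <- targets[[j]]
  out
}
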