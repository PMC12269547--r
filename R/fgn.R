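#' Autocovariance of fractional Gaussian noise
#'
#' Closed-form autocovariance of unit-variance fractional Gaussian noise
#' (the stationary increment process of fractional Brownian motion),
#' \deqn{\gamma(k) = \tfrac12\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right)}
#' with Hurst exponent \eqn{H = \alpha/2}.
#'
#' @param k integer vector of lags (>= 0).
#' @param alpha anomalous exponent in \[0, 2\].
#' @return numeric vector of autocovariances at the requested lags.
#' @export
fgn_autocov <- function(k, alpha) {
  stopifnot(alpha >= 0, alpha <= 2, all(k >= 0))
  H2 <- alpha # 2H
  0.5 * (abs(k + 1)^H2 - 2 * abs(k)^H2 + abs(k - 1)^H2)
}

#' Sample fractional Gaussian noise
#'
#' Draws a stationary Gaussian increment sequence with the exact fGN
#' autocovariance, using Davies-Harte circulant embedding (O(n log n)).
#' When the circulant embedding is not positive semi-definite the sampler
#' falls back to Cholesky factorisation of the n x n Toeplitz covariance.
#'
#' Increments are unit scale: variance 1 at every frame. \code{alpha = 1}
#' gives white Gaussian noise (Brownian increments); \code{alpha = 2} is the
#' degenerate ballistic case where every increment equals one shared
#' standard-normal draw.
#'
#' @param alpha anomalous exponent in \[0, 2\] (Hurst exponent alpha/2).
#' @param n number of increments (>= 1).
#' @return numeric vector of length \code{n}.
#' @export
sample_fgn <- function(alpha, n) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 2)
    stop("alpha must lie in [0, 2]")
  stopifnot(n >= 1)
  if (alpha == 2) {
    # perfectly correlated increments: one draw repeated
    return(rep(stats::rnorm(1), n))
  }
  if (n == 1) return(stats::rnorm(1))
  r <- fgn_autocov(0:n, alpha)
  # circulant first row: r_0 ... r_n, r_{n-1} ... r_1  (length 2n)
  m <- 2L * n
  cr <- c(r, rev(r[2:n]))
  lam <- Re(stats::fft(cr))
  if (min(lam) < -1e-8 * max(lam)) {
    return(.fgn_cholesky(r[1:n], n))
  }
  lam[lam < 0] <- 0
  w <- complex(length.out = m)
  w[1] <- sqrt(lam[1] / m) * stats::rnorm(1)
  w[n + 1] <- sqrt(lam[n + 1] / m) * stats::rnorm(1)
  idx <- 2:n
  u <- stats::rnorm(n - 1)
  v <- stats::rnorm(n - 1)
  w[idx] <- sqrt(lam[idx] / (2 * m)) * complex(real = u, imaginary = v)
  w[m + 2 - idx] <- Conj(w[idx])
  Re(stats::fft(w))[1:n]
}

# Toeplitz-Cholesky fallback; r = autocovariances at lags 0..n-1
.fgn_cholesky <- function(r, n) {
  S <- stats::toeplitz(r)
  # jitter for numerical semi-definiteness near alpha -> 2
  L <- tryCatch(chol(S), error = function(e) chol(S + diag(1e-10, n)))
  as.numeric(crossprod(L, stats::rnorm(n)))
}

#' Simulate one homogeneous fBM segment
#'
#' Generates per-frame displacements of a 2-D fractional Brownian motion
#' segment with constant diffusion coefficient \code{K} and anomalous
#' exponent \code{alpha}. The x and y increments are independent fGN scaled
#' by \code{sqrt(2 K)}, so the per-axis MSD is \eqn{2 K t^\alpha} and the
#' 2-D ensemble MSD obeys \eqn{4 K t^\alpha}.
#'
#' @param alpha anomalous exponent in \[0, 2\].
#' @param K diffusion coefficient in pixels^2 / frame^alpha (>= 0).
#' @param n number of displacement frames (>= 1).
#' @return list with numeric vectors \code{dx}, \code{dy} of length \code{n}.
#' @export
simulate_segment <- function(alpha, K, n) {
  stopifnot(K >= 0, n >= 1)
  if (K == 0) return(list(dx = numeric(n), dy = numeric(n)))
  s <- sqrt(2 * K)
  list(dx = s * sample_fgn(alpha, n), dy = s * sample_fgn(alpha, n))
}
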