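# Exact sampling of stationary Gaussian series by circulant embedding
# (Davies-Harte / Dietrich-Newsam). Shared by the fractional-Brownian chain
# generator, the fBm trajectory generator and the Rouse-mode simulator.

#' Autocovariance of fractional Gaussian noise
#'
#' Covariance at integer lags `0:(n-1)` of the increment process of
#' fractional Brownian motion with Hurst index `H`, scaled so the variance of
#' a single increment is `sigma2`.
#'
#' @param n number of lags (series length).
#' @param H Hurst index in `(0, 1]`.
#' @param sigma2 variance of one increment.
#' @return numeric vector of length `n`.
#' @keywords internal
fgn_acov <- function(n, H, sigma2 = 1) {
  k <- 0:(n - 1)
  sigma2 / 2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

#' Sample stationary Gaussian series with a given autocovariance
#'
#' Draws `n_series` independent zero-mean Gaussian series of length
#' `length(acov)` whose autocovariance at lag `k` is `acov[k + 1]`, by
#' circulant embedding of the covariance (exact, no approximation beyond
#' floating point). Two independent real series are obtained per complex FFT.
#'
#' @param acov autocovariance at lags `0:(n-1)`.
#' @param n_series number of independent series to draw.
#' @return an `n x n_series` matrix, one series per column.
#' @details The circulant embedding can fail to be nonnegative definite for
#'   some covariances at short lengths; in that case the function stops with
#'   advice to increase the series length, as the embedding eigenvalues
#'   approach the (nonnegative) spectral density as the length grows.
#' @keywords internal
sample_stationary_gaussian <- function(acov, n_series) {
  n <- length(acov)
  if (n < 2L) stop_invalid("need at least 2 lags to sample a series")
  m <- 2L * (n - 1L)
  c_emb <- c(acov, acov[(n - 1L):2L])
  lam <- Re(fft(c_emb))
  tol <- 1e-8 * max(abs(lam))
  if (min(lam) < -tol) {
    stop(errorCondition(
      paste0("circulant embedding is not nonnegative definite ",
             "(min eigenvalue ", format(min(lam)), "); ",
             "increase the number of frames/points and retry"),
      class = c("fracdomain_embedding_failure", "error")))
  }
  lam[lam < 0] <- 0
  n_cplx <- ceiling(n_series / 2)
  eps <- matrix(complex(real = rnorm(m * n_cplx), imaginary = rnorm(m * n_cplx)),
                nrow = m, ncol = n_cplx)
  y <- stats::mvfft(eps * sqrt(lam)) / sqrt(m)
  out <- cbind(Re(y[1:n, , drop = FALSE]), Im(y[1:n, , drop = FALSE]))
  out[, seq_len(n_series), drop = FALSE]
}

# Fractional Brownian paths: `n_points` positions starting at 0, Hurst H,
# with E[(B(i) - B(j))^2] = sigma2_step * |i - j|^(2H) on the unit grid.
# Returns an n_points x n_series matrix.
fbm_paths <- function(n_points, H, sigma2_step = 1, n_series = 1) {
  if (n_points < 2L) stop_invalid("need at least 2 points for an fBm path")
  if (H >= 1 - 1e-12) {
    # H = 1 limit: perfectly correlated increments, i.e. a straight path with
    # one Gaussian slope per series.
    slope <- rnorm(n_series, sd = sqrt(sigma2_step))
    return(outer(0:(n_points - 1), slope))
  }
  inc <- sample_stationary_gaussian(fgn_acov(n_points - 1L, H, sigma2_step),
                                    n_series)
  rbind(0, apply(inc, 2, cumsum))
}
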