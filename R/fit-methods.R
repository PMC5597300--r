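# Methods for the central fitted-model object, `subdiffusion_fit`.

#' @export
print.subdiffusion_fit <- function(x, ...) {
  cat("<subdiffusion_fit> MSD(t) = D_sub * t^beta",
      if (!is.null(x$offset)) "+ offset", "\n")
  cat(sprintf("  D_sub = %.4g um^2/s^beta   beta = %.4f\n", x$d_sub, x$beta))
  if (!is.null(x$offset))
    cat(sprintf("  offset = %.4g um^2 (4*sigma^2 in 2D)\n", x$offset))
  cat(sprintf("  window %.3g-%.3g s (%d lags), R^2 = %.4f\n",
              x$fit_window[1], x$fit_window[2], x$n_lags, x$r_squared))
  if (x$not_subdiffusive)
    cat("  NOTE: beta >= 1, not subdiffusive\n")
  invisible(x)
}

#' @export
summary.subdiffusion_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  s.e.: D_sub %.3g, beta %.3g  (method: %s, %dD MSD)\n",
              object$stderr_d, object$stderr_beta, object$method,
              object$dim))
  invisible(object)
}

#' @export
coef.subdiffusion_fit <- function(object, ...) {
  out <- c(d_sub = object$d_sub, beta = object$beta)
  if (!is.null(object$offset)) out <- c(out, offset = object$offset)
  out
}

#' @export
predict.subdiffusion_fit <- function(object, lags = NULL, ...) {
  lags <- lags %||% object$lags
  object$d_sub * lags^object$beta + (object$offset %||% 0)
}

#' @export
residuals.subdiffusion_fit <- function(object, type = c("response", "log"),
                                       ...) {
  type <- match.arg(type)
  fitted <- predict(object)
  if (type == "response") object$observed - fitted
  else log(object$observed) - log(fitted)
}

#' @export
plot.subdiffusion_fit <- function(x, ...) {
  plot(x$lags, x$observed, log = "xy", xlab = "lag (s)",
       ylab = expression(MSD ~ (mu * m^2)), ...)
  lines(x$lags, predict(x), col = 2)
  legend("topleft", bty = "n", legend = sprintf(
    "D_sub = %.3g, beta = %.3f", x$d_sub, x$beta))
  invisible(x)
}

#' Simulate trajectories from a fitted subdiffusion model
#'
#' Draws fractional-Brownian trajectory ensembles with the fitted
#' `(D_sub, beta)`; a fitted offset is converted back into static
#' localization noise of s.d. `sqrt(offset/4)` per axis.
#'
#' @param object a `subdiffusion_fit`.
#' @param nsim number of ensembles to draw.
#' @param seed RNG seed for the first ensemble (incremented per ensemble).
#' @param n_tracks,n_frames,dt geometry of each simulated ensemble.
#' @param ... unused.
#' @return a [trajectory_ensemble()] if `nsim = 1`, else a list of them.
#' @export
simulate.subdiffusion_fit <- function(object, nsim = 1, seed = NULL,
                                      n_tracks = 100, n_frames = 100,
                                      dt = 0.05, ...) {
  sig <- sqrt((object$offset %||% 0) / 4)
  out <- lapply(seq_len(nsim), function(k) {
    generate_fbm_tracks(object$d_sub, object$beta, n_tracks, n_frames, dt,
                        loc_noise_sigma = sig,
                        seed = if (is.null(seed)) NULL else seed + k - 1)
  })
  if (nsim == 1) out[[1]] else out
}
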