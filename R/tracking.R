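# Single-particle-tracking analysis: trajectory containers, time-averaged
# and ensemble MSD estimation, and a synthetic fractional-Brownian track
# generator for validating the subdiffusion fit. Conventions: positions in
# µm, times in seconds, 2D microscopy projection unless stated otherwise,
# frame interval 0.05 s by default.

#' Single-particle trajectory
#'
#' @param track_id label of the track.
#' @param positions matrix of 2D or 3D coordinates in µm, one row per frame.
#' @param frames integer frame indices, strictly increasing (gaps allowed:
#'   missing frames are simply absent rows).
#' @param frame_interval frame time in seconds (default 0.05 = 50 ms).
#' @return a `trajectory`.
#' @export
trajectory <- function(track_id, positions, frames = NULL,
                       frame_interval = 0.05) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  if (nrow(positions) < 2L) stop_invalid("a trajectory needs >= 2 points")
  if (!ncol(positions) %in% c(2L, 3L))
    stop_invalid("positions must have 2 or 3 columns")
  if (!all(is.finite(positions))) stop_invalid("coordinates must be finite")
  if (is.null(frames)) frames <- seq_len(nrow(positions)) - 1L
  frames <- as.integer(frames)
  if (length(frames) != nrow(positions))
    stop_invalid("`frames` must match the number of position rows")
  if (is.unsorted(frames, strictly = TRUE))
    stop_invalid("`frames` must be strictly increasing")
  check_scalar(frame_interval, "frame_interval", lower = 0, open_lower = TRUE)
  structure(list(track_id = as.character(track_id), positions = positions,
                 frames = frames, frame_interval = frame_interval),
            class = "trajectory")
}

#' Ensemble of trajectories
#'
#' @param trajectories list of [trajectory()] objects sharing frame interval
#'   and dimensionality.
#' @param region_label free-text label (e.g. `"interior"`, `"periphery"`).
#' @return a `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(trajectories, region_label = "") {
  if (!is.list(trajectories) || length(trajectories) < 1L)
    stop_invalid("need at least one trajectory")
  ok <- vapply(trajectories, inherits, logical(1), "trajectory")
  if (!all(ok)) stop_invalid("all elements must be trajectory objects")
  dims <- vapply(trajectories, function(tr) ncol(tr$positions), integer(1))
  dts <- vapply(trajectories, function(tr) tr$frame_interval, numeric(1))
  if (length(unique(dims)) != 1L)
    stop_invalid("mixed dimensionality across tracks")
  if (diff(range(dts)) > 1e-12)
    stop_invalid("mixed frame intervals across tracks")
  structure(list(trajectories = trajectories, dimensionality = dims[1],
                 frame_interval = dts[1], region_label = region_label),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  len <- vapply(x$trajectories, function(tr) length(tr$frames), integer(1))
  cat(sprintf(
    "<trajectory_ensemble> %d tracks (%dD), dt = %g s, %d-%d frames%s\n",
    length(x$trajectories), x$dimensionality, x$frame_interval,
    min(len), max(len),
    if (nzchar(x$region_label)) paste0(", region '", x$region_label, "'") else ""))
  invisible(x)
}

new_msd_curve <- function(lags, msd, n_pairs, dim) {
  keep <- n_pairs >= 1
  structure(list(lags = lags[keep], msd = msd[keep], n_pairs = n_pairs[keep],
                 dim = dim),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags in [%.3g, %.3g] s (%dD MSD)\n",
              length(x$lags), min(x$lags), max(x$lags), x$dim))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  plot(x$lags, x$msd, log = "xy", xlab = "lag (s)",
       ylab = expression(MSD ~ (mu * m^2)), ...)
  invisible(x)
}

#' Time-averaged MSD of a single trajectory
#'
#' `MSD(n dt)` is the mean of `|r(i+n) - r(i)|^2` over all start frames `i`
#' for which both frames were observed; missing frames just reduce the pair
#' count at the affected lags.
#'
#' @param traj a [trajectory()].
#' @param max_lag_frames largest lag in frames; must be smaller than the
#'   track's frame span.
#' @return an `msd_curve` with fields `lags` (s), `msd` (µm²) and `n_pairs`.
#' @export
time_averaged_msd <- function(traj, max_lag_frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  span <- diff(range(traj$frames))
  if (is.null(max_lag_frames)) max_lag_frames <- span
  check_scalar(max_lag_frames, "max_lag_frames", lower = 1)
  if (max_lag_frames > span)
    stop_invalid("max_lag_frames exceeds the track's frame span")
  lags_f <- seq_len(max_lag_frames)
  msd <- n_pairs <- numeric(max_lag_frames)
  for (L in lags_f) {
    j <- match(traj$frames + L, traj$frames)
    i <- which(!is.na(j))
    n_pairs[L] <- length(i)
    if (length(i)) {
      d <- traj$positions[j[i], , drop = FALSE] -
        traj$positions[i, , drop = FALSE]
      msd[L] <- mean(rowSums(d * d))
    }
  }
  new_msd_curve(lags_f * traj$frame_interval, msd, n_pairs,
                ncol(traj$positions))
}

#' Ensemble MSD of a trajectory ensemble
#'
#' Pair-count-weighted average of the per-track time-averaged MSDs,
#' equivalent to pooling all displacement pairs at each lag. Tracks shorter
#' than a given lag contribute nothing there.
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param max_lag_frames largest lag in frames; at least one track must
#'   reach it.
#' @return an `msd_curve`.
#' @export
ensemble_msd <- function(ensemble, max_lag_frames = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  spans <- vapply(ensemble$trajectories, function(tr) diff(range(tr$frames)),
                  integer(1))
  if (is.null(max_lag_frames)) max_lag_frames <- max(spans)
  check_scalar(max_lag_frames, "max_lag_frames", lower = 1)
  if (max_lag_frames > max(spans))
    stop_invalid("no track is long enough for max_lag_frames")
  sums <- counts <- numeric(max_lag_frames)
  for (tr in ensemble$trajectories) {
    ml <- min(max_lag_frames, diff(range(tr$frames)))
    if (ml < 1) next
    cv <- time_averaged_msd(tr, ml)
    idx <- round(cv$lags / ensemble$frame_interval)
    sums[idx] <- sums[idx] + cv$msd * cv$n_pairs
    counts[idx] <- counts[idx] + cv$n_pairs
  }
  msd <- ifelse(counts > 0, sums / counts, NA_real_)
  new_msd_curve(seq_len(max_lag_frames) * ensemble$frame_interval,
                msd, counts, ensemble$dimensionality)
}

#' Fit the subdiffusion law to an MSD curve
#'
#' Fits `MSD(t) = D_sub t^beta` (optionally `+ offset` for static
#' localization error, reported as `4 sigma^2` in 2D). The default estimator
#' is ordinary least squares of `log MSD` on `log t` over the fit window;
#' with `offset = TRUE` a nonnegative-offset power law is fitted by
#' Levenberg-Marquardt nonlinear least squares.
#'
#' The default window is lags 2..10 frames: lag 1 is the most
#' localization-noise dominated and long lags have few displacement pairs.
#' The window used is always recorded in the returned object.
#'
#' @param msd an `msd_curve` (from [time_averaged_msd()], [ensemble_msd()]
#'   or [analytic_monomer_msd()]; any object with `lags` and `msd` works).
#' @param fit_window lag-time range `c(lo, hi)` in seconds; at least 4 lags
#'   must fall inside.
#' @param offset `FALSE` (default, pure power law on log-log scale) or
#'   `TRUE` (power law plus nonnegative constant).
#' @return a `subdiffusion_fit` with coefficients `d_sub` (µm²/s^beta),
#'   `beta`, optionally `offset` (µm²), their standard errors, the window
#'   and the goodness of fit; supports `print()`, `summary()`, `coef()`,
#'   `predict()`, `residuals()`, `plot()` and `simulate()`.
#' @examples
#' lag <- (1:20) * 0.05
#' curve <- structure(list(lags = lag, msd = 0.02 * lag^0.5,
#'                         n_pairs = rep(100, 20), dim = 2),
#'                    class = "msd_curve")
#' fit_subdiffusion(curve)
#' @export
fit_subdiffusion <- function(msd, fit_window = NULL, offset = FALSE) {
  lags <- msd$lags
  vals <- msd$msd
  if (is.null(fit_window)) {
    hi <- min(10L, length(lags))
    if (hi < 5L) hi <- length(lags)
    fit_window <- c(lags[min(2L, length(lags))], lags[hi])
  }
  sel <- which(lags >= fit_window[1] - 1e-12 & lags <= fit_window[2] + 1e-12 &
                 is.finite(vals))
  if (length(sel) < 4L)
    stop_invalid("fewer than 4 lags inside the fit window")
  x <- lags[sel]
  y <- vals[sel]
  if (!offset) {
    if (any(y <= 0))
      stop_degenerate("nonpositive MSD values in the window; ",
                      "use offset = TRUE or change the window")
    ll <- lm(log(y) ~ log(x))
    # exact power-law inputs make summary.lm warn about a perfect fit
    sm <- suppressWarnings(summary(ll))
    beta <- unname(coef(ll)[2])
    d_sub <- exp(unname(coef(ll)[1]))
    out <- list(d_sub = d_sub, beta = beta,
                stderr_d = d_sub * sm$coefficients[1, 2],
                stderr_beta = sm$coefficients[2, 2],
                offset = NULL, r_squared = sm$r.squared,
                method = "loglog_ols")
  } else {
    start <- tryCatch({
      pos <- y > 0
      ll <- lm(log(y[pos]) ~ log(x[pos]))
      list(D = exp(unname(coef(ll)[1])), beta = unname(coef(ll)[2]),
           off = 0)
    }, error = function(e) list(D = y[1] / x[1]^0.5, beta = 0.5, off = 0))
    if (start$beta <= 0 || start$beta >= 2) start$beta <- 0.5
    nfit <- tryCatch(
      minpack.lm::nlsLM(y ~ D * x^b + off,
                        start = list(D = start$D, b = start$beta,
                                     off = start$off),
                        lower = c(1e-300, 1e-6, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        stop(errorCondition(
          paste0("nonlinear subdiffusion fit did not converge: ",
                 conditionMessage(e)),
          class = c("fracdomain_fit_failure", "error")))
      })
    cf <- coef(nfit)
    se <- tryCatch(summary(nfit)$coefficients[, 2],
                   error = function(e) rep(NA_real_, 3))
    resid <- y - predict(nfit)
    out <- list(d_sub = unname(cf["D"]), beta = unname(cf["b"]),
                stderr_d = unname(se[1]), stderr_beta = unname(se[2]),
                offset = unname(cf["off"]),
                r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2),
                method = "nls_offset")
  }
  out$fit_window <- range(x)
  out$n_lags <- length(sel)
  out$lags <- x
  out$observed <- y
  out$dim <- msd$dim %||% 2L
  out$not_subdiffusive <- out$beta >= 1
  if (out$not_subdiffusive)
    warning("fitted beta >= 1: movement is not subdiffusive", call. = FALSE)
  class(out) <- "subdiffusion_fit"
  out
}

#' Synthetic subdiffusive trajectories (fractional Brownian motion)
#'
#' Generates 2D tracks whose ensemble MSD is exactly `d_sub * t^beta`: each
#' axis is an independent fractional Brownian path with Hurst index
#' `H = beta/2` (exact-covariance circulant-embedding sampling), plus
#' optional i.i.d. Gaussian static localization noise, which adds
#' `4 * loc_noise_sigma^2` to the measured 2D MSD at every lag.
#'
#' @param d_sub subdiffusion coefficient in µm²/s^beta, positive.
#' @param beta scaling exponent in `(0, 2)` (`beta = 1` is Brownian).
#' @param n_tracks,n_frames ensemble geometry.
#' @param dt frame interval in seconds.
#' @param loc_noise_sigma per-axis localization noise s.d. in µm (0 = none).
#' @param seed RNG seed.
#' @return a [trajectory_ensemble()].
#' @export
generate_fbm_tracks <- function(d_sub, beta, n_tracks = 100, n_frames = 100,
                                dt = 0.05, loc_noise_sigma = 0, seed = NULL) {
  check_scalar(d_sub, "d_sub", lower = 0, open_lower = TRUE)
  check_scalar(beta, "beta", lower = 0, upper = 2,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(n_tracks, "n_tracks", lower = 1)
  check_scalar(n_frames, "n_frames", lower = 2)
  check_scalar(dt, "dt", lower = 0, open_lower = TRUE)
  check_scalar(loc_noise_sigma, "loc_noise_sigma", lower = 0)
  H <- beta / 2
  sig2_step <- d_sub / 2 * dt^beta   # per-axis increment variance on the grid
  with_local_seed(seed, {
    paths <- fbm_paths(n_frames, H, sig2_step, n_series = 2L * n_tracks)
    if (loc_noise_sigma > 0)
      paths <- paths + rnorm(length(paths), sd = loc_noise_sigma)
    tracks <- lapply(seq_len(n_tracks), function(j) {
      trajectory(track_id = sprintf("fbm%04d", j),
                 positions = paths[, c(j, n_tracks + j), drop = FALSE],
                 frames = 0:(n_frames - 1), frame_interval = dt)
    })
    trajectory_ensemble(tracks, region_label = sprintf(
      "fbm d_sub=%g beta=%g", d_sub, beta))
  })
}
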