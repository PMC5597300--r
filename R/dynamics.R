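# Forward model: generalized Rouse chain with a fractal mode spectrum and
# fractional (viscoelastic) thermal noise. The chain is represented by its
# Rouse normal modes X_p, p = 1..N-1,
#   r_n(t) = X_0(t) + 2 * sum_p X_p(t) cos(p pi (n + 1/2)/N),
# with equilibrium mode variances chosen so internal distances scale as
# |n - m|^(2/d_f) (the fractal structure) and mode relaxation times chosen so
# the monomer MSD follows MSD(t) = D_sub t^beta with beta = 2 alpha/(2 + d_f)
# and D_sub growing as R^(2 d_f/(2 + d_f)) — the mobility-structure relation
# this package exists to exercise.

MODE_C1 <- 1 / (2 * pi^2)  # matches the Gaussian-chain (d_f = 2) Rouse form

#' Specification of a fractal chromatin-domain polymer
#'
#' Parameters of the forward model: a domain of `n_monomers` nucleosomes with
#' fractal dimension `df`, embedded in a viscoelastic medium with memory
#' exponent `alpha` (`alpha = 1` is purely viscous). `bond_scale` sets the
#' physical bond length in micrometers and `base_time` the elementary
#' relaxation time in seconds; the slowest (whole-domain) relaxation time is
#' `base_time * N^(2/(df*alpha))` (see [equilibration_time()]).
#'
#' Defaults emulate the imaging conditions under which single nucleosomes are
#' tracked in live nuclei: domains of a couple of hundred nucleosomes,
#' a gyration radius around 0.1 µm, and equilibration within a few seconds.
#'
#' @param n_monomers number of monomers N (>= 2).
#' @param df fractal dimension in `[1, 3]`.
#' @param alpha viscoelastic exponent in `(0, 1]`.
#' @param bond_scale bond length b in µm.
#' @param base_time elementary time tau0 in seconds.
#' @param include_com if `TRUE`, the domain's centre of mass diffuses freely
#'   (MSD grows without bound); by default it is held statistically fixed so
#'   the monomer MSD saturates at the domain scale.
#' @return a `polymer_spec`.
#' @export
polymer_spec <- function(n_monomers = 256, df = 2, alpha = 1,
                         bond_scale = 0.015, base_time = 0.01,
                         include_com = FALSE) {
  check_scalar(n_monomers, "n_monomers", lower = 2)
  check_scalar(df, "df", lower = 1, upper = 3)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(bond_scale, "bond_scale", lower = 0, open_lower = TRUE)
  check_scalar(base_time, "base_time", lower = 0, open_lower = TRUE)
  structure(list(n_monomers = as.integer(n_monomers), df = df, alpha = alpha,
                 bond_scale = bond_scale, base_time = base_time,
                 include_com = isTRUE(include_com)),
            class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf(
    "<polymer_spec> N = %d, d_f = %g, alpha = %g, b = %g um, tau0 = %g s\n",
    x$n_monomers, x$df, x$alpha, x$bond_scale, x$base_time))
  cat(sprintf("  predicted beta = %.4f, R_g = %.4g um, tau_eq = %.3g s\n",
              predicted_beta(x$alpha, x$df), sqrt(spec_rg2(x)),
              equilibration_time(x)))
  invisible(x)
}

#' Subdiffusion exponent implied by structure
#'
#' The monomer MSD exponent of a fractal domain in a viscoelastic medium:
#' `beta = 2 * alpha / (2 + df)`, always in `(0, 2/3]`.
#'
#' @param alpha viscoelastic exponent in `(0, 1]`.
#' @param df fractal dimension in `[1, 3]`.
#' @return the exponent beta.
#' @examples
#' predicted_beta(1, 2)    # 0.5, the classical Rouse value
#' predicted_beta(1, 3)    # 0.4, compact globule
#' @export
predicted_beta <- function(alpha, df) {
  check_scalar(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  check_scalar(df, "df", lower = 1, upper = 3)
  2 * alpha / (2 + df)
}

#' Subdiffusion-coefficient ratio implied by domain sizes
#'
#' For two domains with the same fractal dimension, the subdiffusion
#' coefficient scales with domain size as `D_sub ~ R^(2 df/(2 + df))`; only
#' ratios are defined, the proportionality constant being unknown.
#'
#' @param R_a,R_b domain sizes (any common unit), positive.
#' @param df shared fractal dimension in `[1, 3]`.
#' @return `(R_a/R_b)^(2*df/(2+df))`.
#' @export
predicted_dsub_ratio <- function(R_a, R_b, df) {
  check_scalar(R_a, "R_a", lower = 0, open_lower = TRUE)
  check_scalar(R_b, "R_b", lower = 0, open_lower = TRUE)
  check_scalar(df, "df", lower = 1, upper = 3)
  (R_a / R_b)^(2 * df / (2 + df))
}

#' Rouse-mode spectrum of a fractal domain
#'
#' Equilibrium variance and relaxation time of each normal mode
#' `p = 1..N-1`:
#' \deqn{\langle X_p^2 \rangle = c_1 b^2 N^{2/d_f} p^{-(1+2/d_f)}, \qquad
#'       \tau_p = \tau_0 (N^{2/d_f} p^{-(1+2/d_f)})^{1/\alpha},}
#' with `c1 = 1/(2 pi^2)` fixed by the Gaussian-chain closed form. The
#' variance law reproduces the fractal internal-distance scaling; tying
#' `tau_p^alpha` to the mode variance makes the intermediate-time MSD obey
#' both the exponent and the size dependence of the mobility-structure
#' relation (see the methods vignette).
#'
#' @param spec a [polymer_spec()].
#' @return a `mode_spectrum` with fields `p`, `variance` (µm², per 3D mode
#'   vector) and `tau` (s), both strictly decreasing in `p`.
#' @export
build_mode_spectrum <- function(spec) {
  stopifnot(inherits(spec, "polymer_spec"))
  N <- spec$n_monomers
  p <- seq_len(N - 1L)
  shape <- N^(2 / spec$df) * p^(-(1 + 2 / spec$df))
  structure(list(p = p,
                 variance = MODE_C1 * spec$bond_scale^2 * shape,
                 tau = spec$base_time * shape^(1 / spec$alpha),
                 spec = spec),
            class = "mode_spectrum")
}

# Equilibrium mean squared gyration radius implied by the spectrum:
# R_g^2 = 2 * sum_p <X_p^2> (monomer-averaged squared cosine weight is 1/2).
spec_rg2 <- function(spec) {
  2 * sum(build_mode_spectrum(spec)$variance)
}

#' Slowest relaxation time of the domain
#'
#' Returns `tau_1 = tau0 * N^(2/(df*alpha))`, the relaxation time of the
#' whole domain; beyond a few multiples of it the monomer MSD sits at its
#' plateau (thermal equilibrium within the domain).
#'
#' @param spec a [polymer_spec()].
#' @return time in seconds.
#' @export
equilibration_time <- function(spec) {
  stopifnot(inherits(spec, "polymer_spec"))
  spec$base_time * spec$n_monomers^(2 / (spec$df * spec$alpha))
}

# Mode relaxation function phi(t/tau): stretched exponential by default,
# Mittag-Leffler (numerically integrated) for verification.
mode_decay <- function(t_over_tau, alpha, decay = c("stretched", "mittag_leffler")) {
  decay <- match.arg(decay)
  if (decay == "stretched" || alpha >= 1 - 1e-12) {
    exp(-t_over_tau^alpha)
  } else {
    mittag_leffler_decay(t_over_tau, alpha)
  }
}

#' Analytic monomer mean-squared displacement
#'
#' Monomer-position-averaged MSD of the generalized Rouse model,
#' \deqn{MSD(t) = 4 \sum_p \langle X_p^2\rangle (1 - \phi_\alpha(t/\tau_p)),}
#' where the mode autocorrelation decay is exponential for `alpha = 1` and a
#' stretched exponential `exp(-(t/tau_p)^alpha)` for `alpha < 1` (an
#' approximation to the Mittag-Leffler decay with the same short- and
#' long-time exponents; set `decay = "mittag_leffler"` for the numerically
#' integrated exact form). With the centre of mass held fixed the MSD
#' saturates at `plateau = 2 * R_g^2`.
#'
#' @param spec a [polymer_spec()].
#' @param times increasing, positive lag times in seconds.
#' @param dim 3 for the full 3D MSD (default), 2 for the microscopy
#'   projection (scales the curve by 2/3).
#' @param monomer_index `NULL` for the monomer-averaged curve, or a single
#'   monomer index in `1..N`.
#' @param decay `"stretched"` (default) or `"mittag_leffler"`.
#' @return an `msd_prediction` with fields `times`, `msd`, `beta_predicted`
#'   and `plateau` (`NA` when the centre of mass diffuses freely).
#' @export
analytic_monomer_msd <- function(spec, times, dim = 3, monomer_index = NULL,
                                 decay = c("stretched", "mittag_leffler")) {
  stopifnot(inherits(spec, "polymer_spec"))
  decay <- match.arg(decay)
  if (length(times) < 1L || any(!is.finite(times)) || any(times <= 0) ||
      is.unsorted(times, strictly = TRUE))
    stop_invalid("`times` must be positive and strictly increasing")
  if (!dim %in% c(2, 3)) stop_invalid("`dim` must be 2 or 3")
  ms <- build_mode_spectrum(spec)
  N <- spec$n_monomers
  if (is.null(monomer_index)) {
    w <- rep(2, N - 1L)           # 4 * mean_n cos^2 = 2
  } else {
    check_scalar(monomer_index, "monomer_index", lower = 1, upper = N)
    w <- 4 * cos(ms$p * pi * (monomer_index - 1 + 0.5) / N)^2
  }
  phi <- vapply(seq_along(ms$p), function(k) {
    mode_decay(times / ms$tau[k], spec$alpha, decay)
  }, numeric(length(times)))
  phi <- matrix(phi, nrow = length(times))
  msd3 <- as.vector((1 - phi) %*% (2 * w * ms$variance))
  plateau3 <- sum(2 * w * ms$variance)      # long-time limit of the mode sum
  if (spec$include_com) {
    msd3 <- msd3 + com_msd3(spec, times)
    plateau3 <- NA_real_
  }
  scale <- dim / 3
  structure(list(times = times, msd = scale * msd3,
                 beta_predicted = predicted_beta(spec$alpha, spec$df),
                 plateau = scale * plateau3, dim = dim, spec = spec),
            class = "msd_prediction")
}

# Free centre-of-mass contribution (3D): subdiffusive with exponent alpha,
# amplitude set by the whole-domain friction (N monomers).
com_msd3 <- function(spec, times) {
  2 * spec$bond_scale^2 / spec$n_monomers * (times / spec$base_time)^spec$alpha
}

#' Convert MSD-like objects to an `msd_curve`
#'
#' Lets analytic predictions flow into [fit_subdiffusion()] and
#' [plateau_R()] exactly like measured curves.
#'
#' @param x an `msd_prediction` or `msd_curve`.
#' @return an `msd_curve`.
#' @export
as_msd_curve <- function(x) UseMethod("as_msd_curve")

#' @export
as_msd_curve.msd_curve <- function(x) x

#' @export
as_msd_curve.msd_prediction <- function(x) {
  new_msd_curve(x$times, x$msd, rep(1, length(x$times)), x$dim)
}

#' Log-log slope of an MSD curve over its intermediate regime
#'
#' Measures the subdiffusion exponent of an analytic curve by regression of
#' `log MSD` on `log t` over a window placed mid-way (in log time) between
#' the fastest mode time `tau0 * N^(-1/alpha)` and the domain relaxation
#' time `tau_1`, where the power law `t^beta` holds; window fractions 0.35
#' and 0.75 of the log-range keep clear of both crossovers.
#'
#' @param spec a [polymer_spec()].
#' @param n_times points in the regression window.
#' @param window_frac fractions of the log time-range delimiting the window.
#' @return the fitted slope.
#' @export
msd_mid_slope <- function(spec, n_times = 40, window_frac = c(0.35, 0.75)) {
  stopifnot(inherits(spec, "polymer_spec"))
  lt1 <- log(equilibration_time(spec))
  ltN <- log(spec$base_time * spec$n_monomers^(-1 / spec$alpha))
  tt <- exp(seq(ltN + window_frac[1] * (lt1 - ltN),
                ltN + window_frac[2] * (lt1 - ltN), length.out = n_times))
  pred <- analytic_monomer_msd(spec, tt)
  unname(coef(lm(log(pred$msd) ~ log(tt)))[2])
}

#' @export
print.msd_prediction <- function(x, ...) {
  cat(sprintf(
    "<msd_prediction> %d lags in [%.3g, %.3g] s (%dD), predicted beta = %.4f\n",
    length(x$times), min(x$times), max(x$times), x$dim, x$beta_predicted))
  if (is.finite(x$plateau))
    cat(sprintf("  plateau 2*Rg^2 = %.4g um^2\n", x$plateau))
  invisible(x)
}

#' @export
plot.msd_prediction <- function(x, ...) {
  plot(x$times, x$msd, log = "xy", type = "l", xlab = "lag (s)",
       ylab = expression(MSD ~ (mu * m^2)), ...)
  if (is.finite(x$plateau)) abline(h = x$plateau, lty = 3)
  invisible(x)
}

#' Simulate single-monomer trajectories of a fractal domain
#'
#' Each Rouse mode is simulated as a stationary Gaussian process with the
#' model autocovariance (exact circulant-embedding sampling on the frame
#' grid); the monomer position is the cosine-weighted mode superposition.
#' By default each track follows a fresh uniformly random monomer, mirroring
#' single-nucleosome imaging where every tracked dot is an arbitrary
#' nucleosome of its domain; the ensemble MSD then matches the
#' monomer-averaged [analytic_monomer_msd()].
#'
#' @param spec a [polymer_spec()].
#' @param monomer_index `"random"` (default) or a fixed monomer in `1..N`.
#' @param n_tracks number of tracks (>= 1).
#' @param n_frames frames per track (>= 8).
#' @param dt frame interval in seconds (default 0.05, the 50 ms frame time of
#'   single-nucleosome imaging).
#' @param seed RNG seed; same seed, bit-identical trajectories.
#' @param dim 2 (microscopy projection, default) or 3.
#' @return a [trajectory_ensemble()] with positions in µm.
#' @export
simulate_monomer_tracks <- function(spec, monomer_index = "random",
                                    n_tracks = 100, n_frames = 100,
                                    dt = 0.05, seed = NULL, dim = 2) {
  stopifnot(inherits(spec, "polymer_spec"))
  check_scalar(n_tracks, "n_tracks", lower = 1)
  check_scalar(n_frames, "n_frames", lower = 8)
  check_scalar(dt, "dt", lower = 0, open_lower = TRUE)
  if (!dim %in% c(2, 3)) stop_invalid("`dim` must be 2 or 3")
  N <- spec$n_monomers
  ms <- build_mode_spectrum(spec)
  tgrid <- (0:(n_frames - 1)) * dt
  with_local_seed(seed, {
    monomers <- if (identical(monomer_index, "random")) {
      sample.int(N, n_tracks, replace = TRUE)
    } else {
      check_scalar(monomer_index, "monomer_index", lower = 1, upper = N)
      rep(as.integer(monomer_index), n_tracks)
    }
    acc <- matrix(0, n_frames, 3L * n_tracks)
    for (k in seq_along(ms$p)) {
      acov <- (ms$variance[k] / 3) *
        mode_decay(tgrid / ms$tau[k], spec$alpha)
      xp <- sample_stationary_gaussian(acov, 3L * n_tracks)
      cnp <- 2 * cos(ms$p[k] * pi * (monomers - 1 + 0.5) / N)
      acc <- acc + xp * rep(cnp, 3)[col(acc)]
    }
    if (spec$include_com) {
      sig2 <- 2 * spec$bond_scale^2 /
        (3 * spec$n_monomers * spec$base_time^spec$alpha) * dt^spec$alpha
      com <- fbm_paths(n_frames, H = spec$alpha / 2, sigma2_step = sig2,
                       n_series = 3L * n_tracks)
      acc <- acc + com
    }
    tracks <- lapply(seq_len(n_tracks), function(j) {
      cols <- j + n_tracks * (0:(dim - 1))
      trajectory(track_id = sprintf("sim%04d", j),
                 positions = acc[, cols, drop = FALSE],
                 frames = 0:(n_frames - 1), frame_interval = dt)
    })
    trajectory_ensemble(tracks, region_label = sprintf(
      "simulated df=%g alpha=%g N=%d", spec$df, spec$alpha, N))
  })
}

#' Draw equilibrium conformations of the dynamic model
#'
#' Samples static chain conformations from the equilibrium Gaussian ensemble
#' defined by the mode spectrum (independent modes, cosine superposition).
#' Used to tie the dynamic plateau to the structural gyration radius.
#'
#' @param spec a [polymer_spec()].
#' @param n_chains number of conformations.
#' @param seed RNG seed.
#' @return a list of [chain_conformation][generate_line] objects
#'   (coordinates in µm).
#' @export
sample_equilibrium_conformations <- function(spec, n_chains = 200, seed = NULL) {
  stopifnot(inherits(spec, "polymer_spec"))
  check_scalar(n_chains, "n_chains", lower = 1)
  N <- spec$n_monomers
  ms <- build_mode_spectrum(spec)
  cmat <- 2 * cos(outer((0:(N - 1)) + 0.5, ms$p) * pi / N)  # N x (N-1)
  with_local_seed(seed, {
    lapply(seq_len(n_chains), function(j) {
      X <- matrix(rnorm(3 * (N - 1), sd = sqrt(ms$variance / 3)),
                  nrow = N - 1L, ncol = 3L)
      new_chain_conformation(cmat %*% X, "rouse_equilibrium",
                             df_target = spec$df)
    })
  })
}
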