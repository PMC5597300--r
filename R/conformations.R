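# Polymer chain conformations with prescribed fractal dimension d_f and the
# internal-distance estimator of d_f. Coordinates are in bond-length units
# (b = 1). The scaling law R ~ N^(1/d_f) is probed through the equivalent
# internal-distance form <|r_n - r_m|^2> ~ |n - m|^(2/d_f).

new_chain_conformation <- function(positions, generator, df_target = NA_real_,
                                   params = list(), seed = NA_integer_) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (nrow(positions) < 2L) stop_invalid("a chain needs at least 2 monomers")
  if (ncol(positions) != 3L) stop_invalid("positions must be N x 3")
  if (!all(is.finite(positions))) stop_invalid("coordinates must be finite")
  structure(
    list(positions = positions,
         n_monomers = nrow(positions),
         df_target = df_target,
         generator = list(label = generator, params = params, seed = seed)),
    class = "chain_conformation")
}

#' @export
print.chain_conformation <- function(x, ...) {
  cat("<chain_conformation> ", x$n_monomers, " monomers, generator '",
      x$generator$label, "'", sep = "")
  if (is.finite(x$df_target)) cat(", target d_f = ", x$df_target, sep = "")
  cat("\n  gyration radius:", format(gyration_radius(x), digits = 4), "b\n")
  invisible(x)
}

#' @export
plot.chain_conformation <- function(x, ...) {
  pos <- x$positions
  plot(pos[, 1], pos[, 2], type = "l", asp = 1,
       xlab = "x (b)", ylab = "y (b)",
       main = paste0("chain projection (", x$generator$label, ")"), ...)
  invisible(x)
}

# uniform random unit 3-vectors (isotropic)
random_unit_vectors <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Straight-line chain (d_f = 1)
#'
#' A perfectly collinear chain of unit bonds: the most extended polymer
#' conformation, with fractal dimension exactly 1. The seed only randomizes
#' the orientation of the line in space.
#'
#' @param n_monomers number of monomers, at least 2.
#' @param seed RNG seed for the orientation (`NULL` for the current RNG
#'   state).
#' @return a `chain_conformation`.
#' @examples
#' ch <- generate_line(100, seed = 1)
#' estimate_df(ch)  # exactly 1
#' @export
generate_line <- function(n_monomers, seed = NULL) {
  check_scalar(n_monomers, "n_monomers", lower = 2)
  u <- with_local_seed(seed, random_unit_vectors(1))
  pos <- outer(0:(n_monomers - 1), drop(u))
  new_chain_conformation(pos, "line", df_target = 1, seed = seed %||% NA_integer_)
}

#' Ideal-chain random walk (d_f = 2)
#'
#' Off-lattice random walk with independent, isotropically distributed unit
#' bonds: the ideal chain, fractal dimension 2.
#'
#' @inheritParams generate_line
#' @param seed RNG seed; the same seed reproduces the same chain.
#' @return a `chain_conformation`.
#' @export
generate_random_walk <- function(n_monomers, seed = NULL) {
  check_scalar(n_monomers, "n_monomers", lower = 2)
  steps <- with_local_seed(seed, random_unit_vectors(n_monomers - 1))
  pos <- rbind(0, apply(steps, 2, cumsum))
  new_chain_conformation(pos, "random_walk", df_target = 2,
                         seed = seed %||% NA_integer_)
}

#' Self-avoiding walk by pivot Monte Carlo (d_f ~ 5/3)
#'
#' Excluded-volume chain on the cubic lattice, equilibrated by the pivot
#' algorithm from a straight initial chain: random octahedral symmetries are
#' applied to the shorter arm around a random pivot monomer and accepted when
#' no two monomers collide. The swollen chain has fractal dimension close to
#' 5/3 (inverse of the Flory exponent).
#'
#' @inheritParams generate_random_walk
#' @param n_pivot_attempts number of attempted pivot moves; at least
#'   `10 * n_monomers` (equilibration heuristic).
#' @return a `chain_conformation`; the accepted-move count is stored in
#'   `$generator$params$accepted`.
#' @export
generate_saw_pivot <- function(n_monomers, n_pivot_attempts = 20L * n_monomers,
                               seed = NULL) {
  check_scalar(n_monomers, "n_monomers", lower = 3)
  check_scalar(n_pivot_attempts, "n_pivot_attempts", lower = 10 * n_monomers)
  res <- with_local_seed(seed,
    saw_pivot_cpp(as.integer(n_monomers), as.integer(n_pivot_attempts)))
  if (res$accepted == 0L)
    stop(errorCondition("pivot equilibration failed: zero accepted moves",
                        class = c("fracdomain_equilibration_failure", "error")))
  new_chain_conformation(res$coords, "saw", df_target = 5 / 3,
                         params = list(n_pivot_attempts = n_pivot_attempts,
                                       accepted = res$accepted),
                         seed = seed %||% NA_integer_)
}

#' Space-filling globule (d_f = 3)
#'
#' Deterministic chain tracing the 3D Hilbert curve of the given order: it
#' visits every site of a cube of side `2^order` exactly once with unit
#' bonds, the maximally compact conformation with fractal dimension 3.
#'
#' @param order curve order, at least 2; the chain has `8^order` monomers.
#' @return a `chain_conformation`.
#' @export
generate_space_filling <- function(order) {
  check_scalar(order, "order", lower = 2)
  pos <- hilbert_curve_3d(as.integer(order))
  new_chain_conformation(pos, "hilbert", df_target = 3,
                         params = list(order = order))
}

#' Gaussian fractal chain with arbitrary d_f in [1, 3]
#'
#' Samples a 3D fractional-Brownian path with Hurst index `H = 1/df` per
#' coordinate (exact-covariance circulant-embedding sampling), so the mean
#' squared internal distance scales as `|n - m|^(2/df)` and the path's
#' fractal dimension is `df`. Bonds are Gaussian with unit mean squared
#' length. `df = 2` is statistically a Gaussian random walk; `df = 1`
#' degenerates to a straight path with a Gaussian step length.
#'
#' @inheritParams generate_random_walk
#' @param df target fractal dimension in `[1, 3]`.
#' @return a `chain_conformation`.
#' @export
generate_fractal_chain <- function(n_monomers, df, seed = NULL) {
  check_scalar(n_monomers, "n_monomers", lower = 2)
  check_scalar(df, "df", lower = 1, upper = 3)
  pos <- with_local_seed(seed,
    fbm_paths(n_monomers, H = 1 / df, sigma2_step = 1 / 3, n_series = 3))
  new_chain_conformation(pos, "fractal", df_target = df,
                         seed = seed %||% NA_integer_)
}

#' Radius of gyration
#'
#' Root-mean-square distance of the monomers from their centroid; the
#' operational measure of the domain size R throughout the package.
#'
#' @param conformation a `chain_conformation` (or bare N x 3 matrix).
#' @return a single number in bond-length units.
#' @export
gyration_radius <- function(conformation) {
  pos <- if (inherits(conformation, "chain_conformation"))
    conformation$positions else as.matrix(conformation)
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, ctr)^2)))
}

# Pooled mean squared internal distance at each contour separation in `seps`,
# across a list of conformations (chains shorter than s + 1 are skipped).
internal_distance_msq <- function(chains, seps) {
  sums <- numeric(length(seps))
  counts <- numeric(length(seps))
  for (ch in chains) {
    pos <- ch$positions
    n <- nrow(pos)
    for (k in seq_along(seps)) {
      s <- seps[k]
      if (s >= n) next
      d <- pos[(s + 1):n, , drop = FALSE] - pos[1:(n - s), , drop = FALSE]
      sums[k] <- sums[k] + sum(d * d)
      counts[k] <- counts[k] + (n - s)
    }
  }
  list(msq = sums / counts, n_pairs = counts)
}

#' Estimate the fractal dimension of chain conformations
#'
#' Regresses the log mean squared internal distance on the log contour
#' separation over a window `[s_min, s_max]` and returns `df_hat = 2/slope`,
#' pooling distances over an ensemble of conformations. For a straight chain
#' the slope is exactly 2 and `df_hat` exactly 1.
#'
#' @param chains a `chain_conformation` or a list of them.
#' @param fit_window integer separation range `c(s_min, s_max)`; defaults to
#'   `c(4, N/8)` (bond-scale and finite-size ends excluded). Must lie within
#'   `[2, N/4]`.
#' @return a `df_estimate` with fields `df_hat`, `stderr`, `fit_window`,
#'   `n_conformations`, `slope` and an out-of-range `flag` (set when
#'   `df_hat` falls outside `[1, 3]`, the physical range in 3D).
#' @export
estimate_df <- function(chains, fit_window = NULL) {
  if (inherits(chains, "chain_conformation")) chains <- list(chains)
  if (!is.list(chains) || length(chains) < 1L)
    stop_invalid("`chains` must be one conformation or a non-empty list")
  ok <- vapply(chains, inherits, logical(1), "chain_conformation")
  if (!all(ok)) stop_invalid("all elements must be chain_conformation objects")
  n_min <- min(vapply(chains, function(ch) ch$n_monomers, numeric(1)))
  if (is.null(fit_window)) fit_window <- c(4, max(5, floor(n_min / 8)))
  fit_window <- as.integer(round(fit_window))
  if (fit_window[1] < 2 || fit_window[2] > n_min / 4 ||
      fit_window[2] <= fit_window[1])
    stop_invalid("fit_window must be increasing and within [2, N/4]")
  seps <- fit_window[1]:fit_window[2]
  if (length(seps) < 4L)
    stop_invalid("fit_window must contain at least 4 distinct separations")
  idm <- internal_distance_msq(chains, seps)
  if (any(idm$msq <= 0))
    stop_degenerate("zero internal distances in the fit window; ",
                    "degenerate conformations")
  fit <- lm(log(idm$msq) ~ log(seps))
  slope <- unname(coef(fit)[2])
  # exact fits (straight line) make summary.lm warn about perfection
  slope_se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  df_hat <- 2 / slope
  stderr <- 2 * slope_se / slope^2
  structure(
    list(df_hat = df_hat, stderr = stderr, fit_window = fit_window,
         n_conformations = length(chains), slope = slope,
         flag = df_hat < 1 || df_hat > 3),
    class = "df_estimate")
}

#' @export
print.df_estimate <- function(x, ...) {
  cat("<df_estimate> d_f =", format(x$df_hat, digits = 4),
      "+/-", format(x$stderr, digits = 3),
      sprintf("(window s = %d..%d, %d conformation%s)",
              x$fit_window[1], x$fit_window[2], x$n_conformations,
              if (x$n_conformations == 1) "" else "s"), "\n")
  if (x$flag)
    cat("  warning: estimate outside the physical range [1, 3]\n")
  invisible(x)
}
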