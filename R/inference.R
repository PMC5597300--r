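# Inversion of the mobility-structure relations: from a fitted (D_sub, beta)
# back to the fractal dimension and relative size of the chromatin domain,
# the region-comparison logic, and the Stokes-Einstein utility.

#' Infer the fractal dimension from the subdiffusion exponent
#'
#' Inverts `beta = 2*alpha/(2 + df)` to `df = 2*alpha/beta - 2` under an
#' assumed viscoelastic exponent `alpha`. The physical range in 3D is
#' `df` in `[1, 3]`; estimates outside it raise the `flag` (and correspond
#' to `beta` outside `(2*alpha/5, 2*alpha/3)`).
#'
#' @param beta fitted subdiffusion exponent, positive. May also be a
#'   `subdiffusion_fit`, in which case its stderr is used automatically.
#' @param alpha assumed viscoelastic exponent in `(0, 1]` (default 1,
#'   purely viscous); it is an assumption, never jointly estimated.
#' @param beta_stderr optional standard error of `beta`; propagated to
#'   `df_stderr` by the delta method.
#' @return a `domain_inference` with `df_hat`, `df_stderr`, `alpha_assumed`
#'   and `flag`.
#' @examples
#' infer_df(0.5, alpha = 1)  # the ideal chain, d_f = 2
#' infer_df(0.4, alpha = 1)  # compact globule, d_f = 3
#' @export
infer_df <- function(beta, alpha = 1, beta_stderr = NULL) {
  fit <- NULL
  if (inherits(beta, "subdiffusion_fit")) {
    fit <- beta
    beta_stderr <- beta_stderr %||% fit$stderr_beta
    beta <- fit$beta
  }
  check_scalar(beta, "beta", lower = 0, open_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  df_hat <- 2 * alpha / beta - 2
  df_stderr <- if (!is.null(beta_stderr)) 2 * alpha / beta^2 * beta_stderr
               else NA_real_
  structure(list(df_hat = df_hat, df_stderr = df_stderr,
                 alpha_assumed = alpha, source_fit = fit,
                 flag = df_hat < 1 || df_hat > 3),
            class = "domain_inference")
}

#' @export
print.domain_inference <- function(x, ...) {
  cat(sprintf("<domain_inference> d_f = %.4g", x$df_hat))
  if (is.finite(x$df_stderr)) cat(sprintf(" +/- %.3g", x$df_stderr))
  cat(sprintf("  (alpha assumed %g)\n", x$alpha_assumed))
  if (x$flag)
    cat("  warning: d_f outside the physical range [1, 3]\n")
  invisible(x)
}

#' Relative domain size from a subdiffusion-coefficient ratio
#'
#' Inverts `D_sub ~ R^(2*df/(2+df))`: for two domains sharing the fractal
#' dimension `df`, `R_a/R_b = (D_a/D_b)^((2+df)/(2*df))`. Because the
#' proportionality constant depends on `df`, the conversion is refused
#' (returns `NA` with a warning) when the caller supplies two differing
#' `df` estimates: cross-`df` prefactors are unknown.
#'
#' @param d_sub_ratio ratio `D_a/D_b`, positive.
#' @param df shared fractal dimension in `[1, 3]`.
#' @param df_a,df_b optional per-region df estimates; if they differ by more
#'   than `df_tol` the size ratio is undetermined.
#' @param df_tol tolerance for "equal df" (default 0.2).
#' @return the implied size ratio `R_a/R_b`, or `NA` when undetermined.
#' @export
infer_relative_R <- function(d_sub_ratio, df, df_a = NULL, df_b = NULL,
                             df_tol = 0.2) {
  check_scalar(d_sub_ratio, "d_sub_ratio", lower = 0, open_lower = TRUE)
  check_scalar(df, "df", lower = 1, upper = 3)
  if (!is.null(df_a) && !is.null(df_b) && abs(df_a - df_b) > df_tol) {
    warning("regions' df estimates differ by more than df_tol: ",
            "size ratio undetermined (cross-df prefactors unknown)",
            call. = FALSE)
    return(NA_real_)
  }
  d_sub_ratio^((2 + df) / (2 * df))
}

order_symbol <- function(a, b, tol) {
  if (a - b > tol) ">" else if (b - a > tol) "<" else "~"
}

#' Compare two nuclear regions through their subdiffusion fits
#'
#' Maps the mobility ordering of two regions onto the structural ordering of
#' their chromatin domains: a larger `D_sub` implies a larger domain size R,
#' and a larger `beta` implies a smaller fractal dimension (beta decreases
#' in `d_f` at fixed `alpha`). Orderings within the tolerance band are
#' reported as `"~"` and their structural images as `"undetermined"`.
#'
#' @param fit_a,fit_b `subdiffusion_fit` objects for the two regions.
#' @param alpha shared assumed viscoelastic exponent.
#' @param tol `"auto"` (default: two pooled standard errors, separately for
#'   `D_sub` and `beta`) or a numeric vector `c(d, beta)` of absolute
#'   tolerances defining the `"~"` band.
#' @param labels labels of the two regions.
#' @return a `region_comparison` with `d_order`, `beta_order` and their
#'   structural images `r_order`, `df_order`.
#' @export
compare_regions <- function(fit_a, fit_b, alpha = 1, tol = "auto",
                            labels = c("a", "b")) {
  stopifnot(inherits(fit_a, "subdiffusion_fit"),
            inherits(fit_b, "subdiffusion_fit"))
  check_scalar(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  if (identical(tol, "auto")) {
    pool <- function(a, b) {
      if (is.finite(a) && is.finite(b)) 2 * sqrt(a^2 + b^2) else 0
    }
    tol <- c(pool(fit_a$stderr_d, fit_b$stderr_d),
             pool(fit_a$stderr_beta, fit_b$stderr_beta))
  }
  if (any(tol < 0)) stop_invalid("`tol` must be nonnegative")
  d_order <- order_symbol(fit_a$d_sub, fit_b$d_sub, tol[1])
  beta_order <- order_symbol(fit_a$beta, fit_b$beta, tol[2])
  flip <- c(">" = "<", "<" = ">", "~" = "undetermined")
  keep <- c(">" = ">", "<" = "<", "~" = "undetermined")
  structure(list(region_a = labels[1], region_b = labels[2],
                 d_order = d_order, beta_order = beta_order,
                 r_order = unname(keep[d_order]),
                 df_order = unname(flip[beta_order]),
                 alpha_assumed = alpha, tol = tol),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("<region_comparison> %s vs %s (alpha = %g)\n",
              x$region_a, x$region_b, x$alpha_assumed))
  cat(sprintf("  mobility:  D_sub %s   beta %s\n", x$d_order, x$beta_order))
  cat(sprintf("  structure: R %s   d_f %s\n", x$r_order, x$df_order))
  invisible(x)
}

#' Domain size from a saturating MSD curve
#'
#' Detects saturation of an MSD curve (relative change below
#' `saturation_tol` over the final third of lags) and converts the plateau
#' into a gyration radius through the dynamic-model convention
#' `plateau = 2 * R_g^2` (3D convention; scale 2D curves by 3/2 first).
#'
#' @param msd an `msd_curve` or `msd_prediction`.
#' @param saturation_tol relative-change threshold (default 0.05).
#' @return `R_g` in µm, or `NA` when the curve does not saturate.
#' @export
plateau_R <- function(msd, saturation_tol = 0.05) {
  vals <- msd$msd
  n <- length(vals)
  if (n < 6L) stop_invalid("need at least 6 lags to detect saturation")
  tail_idx <- seq.int(ceiling(2 * n / 3), n)
  rel_change <- (vals[n] - vals[tail_idx[1]]) / vals[n]
  if (!is.finite(rel_change) || rel_change >= saturation_tol)
    return(NA_real_)
  sqrt(mean(vals[tail_idx]) / 2)
}

#' Stokes-Einstein relation solver
#'
#' Solves `D = kB * T / (6 * pi * eta * r)` for whichever one of the four
#' quantities is left `NULL` (`kB = 1.380649e-23` J/K).
#'
#' @param temperature T in K.
#' @param viscosity eta in Pa s.
#' @param radius hydrodynamic radius r in m.
#' @param diffusion D in m²/s.
#' @return the solved quantity (named).
#' @examples
#' stokes_einstein(temperature = 300, viscosity = 1e-3, radius = 1e-9)
#' @export
stokes_einstein <- function(temperature = NULL, viscosity = NULL,
                            radius = NULL, diffusion = NULL) {
  kB <- 1.380649e-23
  args <- list(temperature = temperature, viscosity = viscosity,
               radius = radius, diffusion = diffusion)
  unknown <- names(args)[vapply(args, is.null, logical(1))]
  if (length(unknown) != 1L)
    stop_invalid("exactly one of temperature, viscosity, radius, diffusion ",
                 "must be NULL (got ", length(unknown), " unknowns)")
  for (nm in setdiff(names(args), unknown))
    check_scalar(args[[nm]], nm, lower = 0, open_lower = TRUE)
  out <- switch(unknown,
    diffusion   = kB * temperature / (6 * pi * viscosity * radius),
    temperature = diffusion * 6 * pi * viscosity * radius / kB,
    viscosity   = kB * temperature / (6 * pi * diffusion * radius),
    radius      = kB * temperature / (6 * pi * viscosity * diffusion))
  stats::setNames(out, unknown)
}
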