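# Config-driven pipeline: simulate tracks -> MSD -> subdiffusion fit ->
# structural inference, persisting intermediates and a provenance report.

#' Pipeline run configuration
#'
#' @param dt_s frame interval in seconds.
#' @param alpha assumed viscoelastic exponent.
#' @param fit_window lag range in seconds, or `NULL` for the default
#'   (lags 2..10 frames).
#' @param seeds named list of per-stage seeds (`sim`).
#' @param output_dir directory for intermediates and the report.
#' @param msd_convention `"2D"` or `"3D"`.
#' @param polymer named list of [polymer_spec()] arguments.
#' @param tracks named list with `n_tracks`, `n_frames` and optionally
#'   `monomer_index`.
#' @param input optional trajectory CSV to start from (skips simulation).
#' @return a `run_config`.
#' @export
run_config <- function(dt_s = 0.05, alpha = 1, fit_window = NULL,
                       seeds = list(sim = 1L), output_dir = tempfile("fracrun"),
                       msd_convention = c("2D", "3D"),
                       polymer = list(), tracks = list(), input = NULL) {
  msd_convention <- match.arg(msd_convention)
  check_scalar(dt_s, "dt_s", lower = 0, open_lower = TRUE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  structure(list(dt_s = dt_s, alpha = alpha, fit_window = fit_window,
                 seeds = seeds, output_dir = output_dir,
                 msd_convention = msd_convention, polymer = polymer,
                 tracks = tracks, input = input),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [run_config()].
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

#' Write a pipeline configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

PIPELINE_STAGES <- c("sim-tracks", "msd", "fit", "infer")

#' Run the synthetic analysis pipeline
#'
#' Executes an ordered subset of `sim-tracks -> msd -> fit -> infer`,
#' persisting every intermediate in `config$output_dir` and returning (and
#' writing) a JSON provenance report with parameters, seeds, file hashes and
#' package version. Identical config and seeds give byte-identical
#' intermediates.
#'
#' @param config a [run_config()].
#' @param stages character vector, a contiguous ordered subset of the
#'   canonical chain; if it does not start at `"sim-tracks"`, `config$input`
#'   must point to a trajectory CSV.
#' @return the report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "run_config"))
  idx <- match(stages, PIPELINE_STAGES)
  if (any(is.na(idx)))
    stop_invalid("unknown stages: ",
                 paste(stages[is.na(idx)], collapse = ", "))
  if (length(idx) < 1L || any(diff(idx) != 1L))
    stop_invalid("stages must be a contiguous ordered subset of: ",
                 paste(PIPELINE_STAGES, collapse = " -> "))
  if (stages[1] != "sim-tracks" && is.null(config$input))
    stop_invalid("pipeline starting at '", stages[1],
                 "' needs config$input (a trajectory CSV)")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  files <- character()
  report <- list(tool = paste0("fracdomain ",
                               as.character(packageVersion("fracdomain"))),
                 stages = stages, config = unclass(config),
                 timestamp = format(Sys.time(), usetz = TRUE))
  dim <- if (config$msd_convention == "2D") 2L else 3L

  ens <- NULL
  if ("sim-tracks" %in% stages) {
    spec <- do.call(polymer_spec, config$polymer)
    tr <- modifyList(list(n_tracks = 100, n_frames = 100,
                          monomer_index = "random"), config$tracks)
    message("[sim-tracks] simulating ", tr$n_tracks, " tracks")
    ens <- simulate_monomer_tracks(spec, monomer_index = tr$monomer_index,
                                   n_tracks = tr$n_tracks,
                                   n_frames = tr$n_frames,
                                   dt = config$dt_s,
                                   seed = config$seeds$sim %||% 1L,
                                   dim = dim)
    write_trajectories(ens, out("tracks.csv"))
    files <- c(files, out("tracks.csv"))
    report$sim <- list(spec = unclass(spec), n_tracks = tr$n_tracks,
                       n_frames = tr$n_frames, seed = config$seeds$sim %||% 1L)
  } else if (!is.null(config$input)) {
    ens <- read_trajectories(config$input, config$dt_s)
    files <- c(files, config$input)
  }

  curve <- NULL
  if ("msd" %in% stages) {
    message("[msd] ensemble MSD")
    curve <- ensemble_msd(ens)
    write_msd(curve, out("msd.csv"))
    files <- c(files, out("msd.csv"))
  }

  fit <- NULL
  if ("fit" %in% stages) {
    message("[fit] subdiffusion fit")
    fit <- fit_subdiffusion(curve, fit_window = config$fit_window)
    write_fit_json(fit, out("fit.json"), input = out("msd.csv"))
    files <- c(files, out("fit.json"))
    report$fit <- list(d_sub = fit$d_sub, beta = fit$beta,
                       fit_window = fit$fit_window)
  }

  if ("infer" %in% stages) {
    message("[infer] structural inference")
    inf <- infer_df(fit, alpha = config$alpha)
    report$inference <- list(df_hat = inf$df_hat, df_stderr = inf$df_stderr,
                             alpha_assumed = inf$alpha_assumed,
                             flag = inf$flag)
    jsonlite::write_json(report$inference, out("inference.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, out("inference.json"))
  }

  report$files <- lapply(files, function(f)
    list(path = f, md5 = unname(tools::md5sum(f))))
  write_config(config, out("config.yaml"))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(report)
}
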