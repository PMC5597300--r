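# File formats. All writers emit "#"-prefixed header comments carrying tool
# version and parameter provenance; all readers skip comment lines.
# Trajectory CSV: track_id,frame,x_um,y_um[,z_um], frames 0-based.
# MSD CSV: lag_s,msd_um2,n_pairs. Conformation text: index x y z (tabs).

io_header <- function(kind, extra = character()) {
  c(sprintf("# fracdomain %s %s", as.character(packageVersion("fracdomain")),
            kind),
    paste0("# ", extra))
}

#' Read a trajectory CSV file
#'
#' Expects columns `track_id,frame,x_um,y_um` and optionally `z_um`;
#' comment lines starting with `#` are ignored. Malformed content is
#' reported with the offending line numbers / tracks.
#'
#' @param path file path.
#' @param dt_s frame interval in seconds; required (no silent default) since
#'   the file format carries no time metadata.
#' @return a [trajectory_ensemble()].
#' @export
read_trajectories <- function(path, dt_s) {
  if (missing(dt_s) || is.null(dt_s))
    stop_invalid("`dt_s` must be supplied: trajectory files carry no ",
                 "time metadata")
  check_scalar(dt_s, "dt_s", lower = 0, open_lower = TRUE)
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(raw)))
    stop_invalid("missing columns: ",
                 paste(setdiff(need, names(raw)), collapse = ", "))
  has_z <- "z_um" %in% names(raw)
  poscols <- c("x_um", "y_um", if (has_z) "z_um")
  bad <- which(!stats::complete.cases(raw[poscols]) | !is.finite(raw$frame))
  if (length(bad))
    stop_invalid("malformed rows (missing/non-finite values) at data lines: ",
                 paste(head(bad, 10), collapse = ", "))
  dup <- duplicated(raw[c("track_id", "frame")])
  if (any(dup)) {
    d1 <- raw[which(dup)[1], ]
    stop_invalid("duplicated (track_id, frame) pair: (",
                 d1$track_id, ", ", d1$frame, ")")
  }
  tracks <- lapply(split(raw, raw$track_id), function(df) {
    df <- df[order(df$frame), , drop = FALSE]
    trajectory(df$track_id[1], as.matrix(df[poscols]), df$frame, dt_s)
  })
  trajectory_ensemble(unname(tracks))
}

#' Write a trajectory ensemble to CSV
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  rows <- do.call(rbind, lapply(ensemble$trajectories, function(tr) {
    pos <- tr$positions
    df <- data.frame(track_id = tr$track_id, frame = tr$frames,
                     x_um = pos[, 1], y_um = pos[, 2])
    if (ncol(pos) == 3L) df$z_um <- pos[, 3]
    df
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header("trajectories", sprintf(
    "dt_s: %g | dim: %d | tracks: %d | 2D MSD convention unless z_um present",
    ensemble$frame_interval, ensemble$dimensionality,
    length(ensemble$trajectories))), con)
  write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an MSD curve to CSV
#' @param msd an `msd_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msd <- function(msd, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header("msd", sprintf("%dD MSD convention", msd$dim)), con)
  write.csv(data.frame(lag_s = msd$lags, msd_um2 = msd$msd,
                       n_pairs = msd$n_pairs),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an MSD curve from CSV
#' @param path file path with columns `lag_s,msd_um2,n_pairs`.
#' @param dim MSD dimensionality convention recorded in the curve.
#' @return an `msd_curve`.
#' @export
read_msd <- function(path, dim = 2) {
  raw <- read.csv(path, comment.char = "#")
  need <- c("lag_s", "msd_um2", "n_pairs")
  if (!all(need %in% names(raw)))
    stop_invalid("missing columns: ",
                 paste(setdiff(need, names(raw)), collapse = ", "))
  new_msd_curve(raw$lag_s, raw$msd_um2, raw$n_pairs, dim)
}

#' Write a chain conformation to a plain-text file
#'
#' One line per monomer (`index x y z`, tab-separated) preceded by `#`
#' header comments carrying the generator metadata;
#' [read_conformation()] round-trips exactly.
#'
#' @param conformation a chain conformation.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conformation <- function(conformation, path) {
  stopifnot(inherits(conformation, "chain_conformation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header("conformation", c(
    sprintf("generator: %s", conformation$generator$label),
    sprintf("df_target: %s", format(conformation$df_target, digits = 17)),
    sprintf("seed: %s", conformation$generator$seed))), con)
  pos <- conformation$positions
  writeLines(sprintf("%d\t%s\t%s\t%s", seq_len(nrow(pos)),
                     format(pos[, 1], digits = 17),
                     format(pos[, 2], digits = 17),
                     format(pos[, 3], digits = 17)), con)
  invisible(path)
}

#' Read a chain conformation written by [write_conformation()]
#' @param path file path.
#' @return a chain conformation.
#' @export
read_conformation <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  grab <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^# ", key, ": "), "", ln[1]) else NA_character_
  }
  fields <- do.call(rbind, strsplit(body, "\t"))
  pos <- matrix(as.numeric(fields[, 2:4]), ncol = 3)
  new_chain_conformation(
    pos, grab("generator") %||% "file",
    df_target = suppressWarnings(as.numeric(grab("df_target"))),
    seed = suppressWarnings(as.integer(grab("seed"))))
}

#' Write a subdiffusion fit as JSON
#' @param fit a `subdiffusion_fit`.
#' @param path output path.
#' @param input optional path of the MSD file the fit came from (hashed into
#'   the provenance block).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, input = NULL) {
  stopifnot(inherits(fit, "subdiffusion_fit"))
  obj <- list(d_sub = fit$d_sub, beta = fit$beta,
              stderr_d = fit$stderr_d, stderr_beta = fit$stderr_beta,
              offset = fit$offset, r_squared = fit$r_squared,
              fit_window = fit$fit_window, n_lags = fit$n_lags,
              method = fit$method, dim = fit$dim,
              not_subdiffusive = fit$not_subdiffusive,
              provenance = list(
                tool = paste0("fracdomain ",
                              as.character(packageVersion("fracdomain"))),
                input = input,
                input_md5 = if (!is.null(input))
                  unname(tools::md5sum(input)) else NULL))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a subdiffusion fit written by [write_fit_json()]
#' @param path file path.
#' @return a `subdiffusion_fit` (without the raw data points).
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(d_sub = obj$d_sub, beta = obj$beta,
                 stderr_d = obj$stderr_d %||% NA_real_,
                 stderr_beta = obj$stderr_beta %||% NA_real_,
                 offset = obj$offset, r_squared = obj$r_squared,
                 fit_window = obj$fit_window, n_lags = obj$n_lags,
                 lags = NULL, observed = NULL,
                 method = obj$method, dim = obj$dim %||% 2L,
                 not_subdiffusive = isTRUE(obj$not_subdiffusive)),
            class = "subdiffusion_fit")
}
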