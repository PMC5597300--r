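# Shared fixtures, all built in code.

crossprod_vec3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# A chain whose internal distances are all zero (every monomer at the origin).
new_degenerate_chain <- function() {
  ch <- generate_line(32, seed = 1)
  ch$positions <- matrix(0, 32, 3)
  ch
}

# An msd_curve following an exact law msd = D * t^beta + off.
power_law_curve <- function(D, beta, off = 0, lags = (1:20) * 0.05,
                            n_pairs = rep(100L, length(lags)), dim = 2L) {
  structure(list(lags = lags, msd = D * lags^beta + off,
                 n_pairs = n_pairs, dim = dim),
            class = "msd_curve")
}

# Deterministic ballistic track: x = v * frame (um), y = 0.
ballistic_track <- function(n_frames = 20, v = 0.1, dt = 0.05,
                            id = "ball") {
  trajectory(id, cbind(v * (0:(n_frames - 1)), 0), 0:(n_frames - 1), dt)
}

# Small ensemble of pure Brownian 2D tracks with per-axis step variance s2.
brownian_ensemble <- function(n_tracks, n_frames, s2, dt = 0.05, seed = 1) {
  fracdomain:::with_local_seed(seed, {
    trajectory_ensemble(lapply(seq_len(n_tracks), function(j) {
      steps <- matrix(rnorm(2 * (n_frames - 1), sd = sqrt(s2)), ncol = 2)
      trajectory(sprintf("bm%03d", j), rbind(0, apply(steps, 2, cumsum)),
                 0:(n_frames - 1), dt)
    }))
  })
}

tmp_file <- function(name) {
  tempfile(pattern = sub("\\..*$", "", name),
           fileext = sub("^[^.]*", "", name))
}

tmp_dir <- function() {
  d <- tempfile("fracdir")
  dir.create(d)
  d
}
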