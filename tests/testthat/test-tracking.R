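# SPT analysis: MSD estimators, subdiffusion fit, fBm generator.

test_that("time-averaged MSD matches closed forms and handles edge cases", {
  tr <- ballistic_track(n_frames = 20, v = 0.1, dt = 0.05)
  cv <- time_averaged_msd(tr, 10)
  n <- round(cv$lags / 0.05)
  expect_equal(cv$msd, (0.1 * n)^2, tolerance = 1e-12)
  expect_equal(cv$n_pairs, 20 - n)
  # stationary track
  still <- trajectory("still", matrix(0.3, 10, 2), 0:9, 0.05)
  expect_equal(time_averaged_msd(still, 5)$msd, rep(0, 5))
  # 2-frame track
  two <- trajectory("two", rbind(c(0, 0), c(1, 0)), 0:1, 0.05)
  cv2 <- time_averaged_msd(two, 1)
  expect_equal(cv2$n_pairs, 1)
  expect_equal(cv2$msd, 1)
  expect_error(time_averaged_msd(two, 2),
               class = "fracdomain_invalid_argument")
  # missing frames skip invalid pairs
  gap <- trajectory("gap", cbind(c(0, 1, 3), 0), frames = c(0L, 1L, 3L))
  cvg <- time_averaged_msd(gap, 3)
  expect_equal(cvg$n_pairs, c(1, 1, 1))  # lags 1 (0->1), 2 (1->3), 3 (0->3)
  expect_equal(cvg$msd, c(1, 4, 9))
})

test_that("ensemble MSD pools displacement pairs and is invariant to rigid motion", {
  tr <- ballistic_track()
  ens1 <- trajectory_ensemble(list(tr))
  ens3 <- trajectory_ensemble(list(tr, tr, tr))
  c1 <- ensemble_msd(ens1, 8)
  c3 <- ensemble_msd(ens3, 8)
  expect_equal(c3$msd, c1$msd)
  expect_equal(c3$n_pairs, 3 * c1$n_pairs)
  # translation + rotation invariance
  th <- 0.7
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- trajectory("m", sweep(tr$positions %*% t(Rm), 2, c(5, -2), "+"),
                      tr$frames, tr$frame_interval)
  expect_equal(ensemble_msd(trajectory_ensemble(list(moved)), 8)$msd, c1$msd)
  # Brownian ground truth: slope of MSD vs lag = 4D = 2 * s2/dt * 2 axes... = 2*s2/dt
  s2 <- 0.002
  bens <- brownian_ensemble(1000, 40, s2, dt = 0.05, seed = 4)
  cb <- ensemble_msd(bens, 10)
  slope <- unname(coef(lm(cb$msd ~ 0 + cb$lags)))
  expect_equal(slope, 2 * s2 / 0.05, tolerance = 0.05)
})

test_that("the subdiffusion fit recovers exact power laws to machine precision", {
  cv <- power_law_curve(0.02, 0.5)
  fit <- fit_subdiffusion(cv)
  expect_equal(fit$d_sub, 0.02, tolerance = 1e-12)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(coef(fit)), c(0.02, 0.5), tolerance = 1e-10)
  expect_equal(predict(fit, 2), 0.02 * 2^0.5, tolerance = 1e-10)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-14)
  # window is recorded and honoured
  expect_equal(fit$fit_window, c(2, 10) * 0.05)
  # offset mode recovers a localization floor
  cvo <- power_law_curve(0.02, 0.5, off = 0.004)
  fo <- fit_subdiffusion(cvo, offset = TRUE)
  expect_equal(fo$offset, 0.004, tolerance = 0.02)
  expect_equal(fo$beta, 0.5, tolerance = 0.02)
  # degenerate input
  bad <- power_law_curve(0.02, 0.5)
  bad$msd[3] <- 0
  expect_error(fit_subdiffusion(bad), class = "fracdomain_degenerate_input")
  expect_warning(fit_subdiffusion(power_law_curve(0.02, 1.3)),
                 "not subdiffusive")
})

test_that("fBm tracks have the designed MSD and the Brownian limit decorrelates", {
  ens <- generate_fbm_tracks(0.015, 0.44, 1000, 50, 0.05, seed = 9)
  cv <- ensemble_msd(ens, 5)
  expect_equal(cv$msd[1], 0.015 * 0.05^0.44, tolerance = 0.05)
  expect_identical(
    generate_fbm_tracks(0.015, 0.44, 5, 20, 0.05, seed = 3)$trajectories[[2]],
    generate_fbm_tracks(0.015, 0.44, 5, 20, 0.05, seed = 3)$trajectories[[2]])
  # beta = 1: increments uncorrelated
  bens <- generate_fbm_tracks(0.02, 1, 500, 100, 0.05, seed = 2)
  ac <- mean(vapply(bens$trajectories, function(tr) {
    dx <- diff(tr$positions[, 1])
    stats::cor(dx[-1], dx[-length(dx)])
  }, numeric(1)))
  expect_lt(abs(ac), 0.02)
})

test_that("round-trip parameter recovery holds over the operating beta range", {
  for (b in c(0.3, 0.44, 0.5, 0.6)) {
    ens <- generate_fbm_tracks(0.015, b, 500, 100, 0.05,
                               seed = round(1000 * b))
    fit <- fit_subdiffusion(ensemble_msd(ens, 15))
    expect_equal(fit$d_sub, 0.015, tolerance = 0.10,
                 label = sprintf("d_sub at beta=%.2f", b))
    expect_lt(abs(fit$beta - b), 0.03)
  }
})

test_that("localization noise adds a constant 4 sigma^2 to the 2D MSD", {
  sig <- 0.03
  base <- ensemble_msd(generate_fbm_tracks(0.015, 0.44, 800, 50, 0.05,
                                           seed = 9), 10)
  noisy <- ensemble_msd(generate_fbm_tracks(0.015, 0.44, 800, 50, 0.05,
                                            loc_noise_sigma = sig, seed = 9), 10)
  offs <- noisy$msd - base$msd
  expect_equal(mean(offs), 4 * sig^2, tolerance = 0.10)
  expect_lt(sd(offs) / mean(offs), 0.2)  # roughly constant across lags
})

test_that("tracks simulated from the polymer model fit back to the predicted exponent", {
  sp <- polymer_spec(128, 2.5, 0.75, base_time = 0.5)
  ens <- simulate_monomer_tracks(sp, n_tracks = 400, n_frames = 80,
                                 dt = 0.05, seed = 13)
  fit <- fit_subdiffusion(ensemble_msd(ens, 12))
  expect_lt(abs(fit$beta - predicted_beta(0.75, 2.5)), 0.05)
})

test_that("simulate() on a fitted model regenerates matching ensembles", {
  fit <- fit_subdiffusion(power_law_curve(0.02, 0.5))
  ens <- simulate(fit, seed = 5, n_tracks = 300, n_frames = 60)
  refit <- fit_subdiffusion(ensemble_msd(ens, 10))
  expect_equal(refit$d_sub, 0.02, tolerance = 0.1)
  expect_equal(refit$beta, 0.5, tolerance = 0.1)
})
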