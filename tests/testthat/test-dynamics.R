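# Generalized Rouse forward model: mode spectrum, analytic MSD, simulation.

test_that("predicted exponent and coefficient ratios follow the structural relations", {
  expect_equal(predicted_beta(1, 2), 0.5)
  expect_equal(predicted_beta(1, 3), 0.4)
  expect_equal(predicted_beta(0.5, 2), 0.25)
  # always within (0, 2/3]
  grid <- expand.grid(a = c(0.1, 0.5, 1), df = c(1, 2, 3))
  b <- mapply(predicted_beta, grid$a, grid$df)
  expect_true(all(b > 0 & b <= 2 / 3))
  expect_error(predicted_beta(1.5, 2), class = "fracdomain_invalid_argument")

  expect_equal(predicted_dsub_ratio(0.37, 0.37, 2.2), 1)
  expect_equal(predicted_dsub_ratio(2, 1, 2), 2)
  expect_equal(predicted_dsub_ratio(2, 1, 3), 2^(6 / 5))
  expect_error(predicted_dsub_ratio(-1, 1, 2),
               class = "fracdomain_invalid_argument")
})

test_that("the mode spectrum has the fractal variance law and Rouse limit", {
  sp2 <- polymer_spec(64, df = 2, alpha = 1)
  ms2 <- build_mode_spectrum(sp2)
  # variance exponent -(1 + 2/df) = -2 at df = 2: mode1/mode2 = 4
  expect_equal(ms2$variance[1] / ms2$variance[2], 4)
  # classical Rouse relaxation: tau_p ~ p^-2
  expect_equal(ms2$tau[1] / ms2$tau[4], 16)
  # df = 3: exponent -(5/3)
  ms3 <- build_mode_spectrum(polymer_spec(64, df = 3, alpha = 1))
  expect_equal(ms3$variance[1] / ms3$variance[2], 2^(5 / 3))
  # monotone spectra
  expect_true(all(diff(ms2$variance) < 0) && all(diff(ms2$tau) < 0))
  # Gaussian-chain calibration: R_g^2 = 2 * sum <X_p^2> ~ N b^2 / 6
  rg2 <- 2 * sum(ms2$variance)
  expect_equal(rg2, 64 * sp2$bond_scale^2 / 6, tolerance = 0.05)
})

test_that("equilibration time is the slowest mode time and grows with N", {
  taus <- vapply(c(64, 128, 256), function(N)
    equilibration_time(polymer_spec(N, 2, 1)), numeric(1))
  expect_true(all(diff(taus) > 0))
  # df = 2, alpha = 1: tau_1/tau0 = N^(2/(df*alpha)) = N
  sp <- polymer_spec(128, 2, 1)
  expect_equal(equilibration_time(sp) / sp$base_time, 128)
  expect_equal(equilibration_time(sp), build_mode_spectrum(sp)$tau[1])
})

test_that("the analytic MSD is monotone, saturates at 2 Rg^2 and obeys the exponent law", {
  specs <- list(polymer_spec(128, 1.5, 1), polymer_spec(128, 2, 0.7),
                polymer_spec(128, 3, 0.5))
  for (sp in specs) {
    tau1 <- equilibration_time(sp)
    tt <- exp(seq(log(sp$base_time / 100), log(25 * tau1), length.out = 60))
    pred <- analytic_monomer_msd(sp, tt)
    expect_true(all(diff(pred$msd) >= -1e-15))
    expect_gte(pred$plateau + 1e-15, pred$msd[length(pred$msd)])
    expect_equal(pred$msd[length(pred$msd)], pred$plateau, tolerance = 0.05)
  }
  # exponent law on a grid: mid-range slope = 2 alpha / (2 + df) within 0.03
  for (df in c(1.5, 2.5)) for (al in c(0.5, 1)) {
    sp <- polymer_spec(512, df, al)
    expect_lt(abs(msd_mid_slope(sp) - predicted_beta(al, df)), 0.03,
              label = sprintf("|slope - beta| at df=%g alpha=%g", df, al))
  }
  expect_error(analytic_monomer_msd(specs[[1]], numeric(0)),
               class = "fracdomain_invalid_argument")
})

test_that("stretched-exponential decay tracks the exact Mittag-Leffler curve", {
  # alpha = 1/2 closed form: E_{1/2}(-sqrt(x)) = exp(x) erfc(sqrt(x))
  x <- c(0.05, 0.3, 1, 4, 12)
  expect_equal(mittag_leffler_decay(x, 0.5),
               exp(x) * 2 * pnorm(-sqrt(2 * x)), tolerance = 1e-9)
  expect_equal(mittag_leffler_decay(x, 1), exp(-x))
  # the two mode-decay options give the same MSD power law (same exponents)
  sp <- polymer_spec(48, 2, 0.6)
  tt <- sp$base_time * c(0.05, 0.1, 0.2)
  m_st <- analytic_monomer_msd(sp, tt)$msd
  m_ml <- analytic_monomer_msd(sp, tt, decay = "mittag_leffler")$msd
  s_st <- coef(lm(log(m_st) ~ log(tt)))[2]
  s_ml <- coef(lm(log(m_ml) ~ log(tt)))[2]
  expect_equal(unname(s_st), unname(s_ml), tolerance = 0.05)
})

test_that("simulated monomer tracks reproduce the analytic MSD and are reproducible", {
  sp <- polymer_spec(128, 2, 1, base_time = 0.5)
  ens <- simulate_monomer_tracks(sp, n_tracks = 400, n_frames = 80,
                                 dt = 0.05, seed = 7, dim = 2)
  expect_identical(
    simulate_monomer_tracks(sp, n_tracks = 400, n_frames = 80,
                            dt = 0.05, seed = 7, dim = 2)$trajectories[[5]],
    ens$trajectories[[5]])
  cv <- ensemble_msd(ens, 20)
  pred <- analytic_monomer_msd(sp, cv$lags, dim = 2)
  expect_lt(max(abs(cv$msd / pred$msd - 1)), 0.10)
  # a fixed single monomer is also supported
  ens1 <- simulate_monomer_tracks(sp, monomer_index = 32, n_tracks = 50,
                                  n_frames = 16, dt = 0.05, seed = 1)
  expect_equal(length(ens1$trajectories), 50)
})

test_that("a larger domain at fixed d_f is pointwise more mobile", {
  tt <- exp(seq(log(0.01), log(10), length.out = 30))
  small <- analytic_monomer_msd(polymer_spec(128, 2, 1, bond_scale = 0.010), tt)
  large <- analytic_monomer_msd(polymer_spec(128, 2, 1, bond_scale = 0.020), tt)
  expect_true(all(large$msd >= small$msd))
  # growing N at fixed d_f also grows mobility pointwise
  larger_n <- analytic_monomer_msd(polymer_spec(512, 2, 1, bond_scale = 0.010), tt)
  expect_true(all(larger_n$msd >= small$msd - 1e-18))
})

test_that("equilibrium conformations sampled from the spectrum match its R_g", {
  sp <- polymer_spec(128, 2.5, 0.8)
  chains <- sample_equilibrium_conformations(sp, 800, seed = 3)
  rg2 <- mean(vapply(chains, gyration_radius, numeric(1))^2)
  expect_equal(2 * rg2, analytic_monomer_msd(sp, 1)$plateau, tolerance = 0.05)
})
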