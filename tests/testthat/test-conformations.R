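# Chain generators and the internal-distance fractal-dimension estimator.

test_that("straight-line chains are collinear with unit bonds and d_f exactly 1", {
  ch <- generate_line(100, seed = 1)
  pos <- ch$positions
  bonds <- pos[-1, ] - pos[-nrow(pos), ]
  expect_equal(unname(sqrt(rowSums(bonds^2))), rep(1, 99), tolerance = 1e-12)
  # collinear: all bonds parallel to the first
  cross_norm <- apply(bonds, 1, function(b)
    sqrt(sum(crossprod_vec3(b, bonds[1, ])^2)))
  expect_lt(max(cross_norm), 1e-10)
  expect_equal(sqrt(sum((pos[100, ] - pos[1, ])^2)), 99, tolerance = 1e-10)
  est <- suppressWarnings(estimate_df(ch, c(4, 12)))
  expect_equal(est$df_hat, 1, tolerance = 1e-10)
  expect_false(est$flag)
  # N = 2 edge case
  ch2 <- generate_line(2, seed = 0)
  expect_equal(sqrt(sum(diff(ch2$positions)^2)), 1, tolerance = 1e-12)
  expect_error(generate_line(1), class = "fracdomain_invalid_argument")
})

test_that("random walks have unit bonds, the ideal-chain statistics and d_f near 2", {
  ch <- generate_random_walk(64, seed = 3)
  bonds <- ch$positions[-1, ] - ch$positions[-64, ]
  expect_equal(unname(sqrt(rowSums(bonds^2))), rep(1, 63), tolerance = 1e-12)
  expect_identical(generate_random_walk(64, seed = 3)$positions, ch$positions)

  chains <- lapply(1:2000, function(i) generate_random_walk(512, seed = i))
  msq_e2e <- vapply(chains, function(c.)
    sum((c.$positions[512, ] - c.$positions[1, ])^2), numeric(1))
  expect_equal(mean(msq_e2e), 511, tolerance = 0.05)

  est <- estimate_df(chains[1:200])
  expect_equal(est$df_hat, 2, tolerance = 0.05)
  # a single short chain: noisy estimate, larger stderr than the ensemble's
  est1 <- estimate_df(chains[[1]])
  expect_gt(est1$stderr, est$stderr)
})

test_that("pivot-sampled SAWs are self-avoiding, swollen and reproducible", {
  saw <- generate_saw_pivot(200, 4000, seed = 5)
  expect_equal(nrow(unique(saw$positions)), 200)
  bonds <- saw$positions[-1, ] - saw$positions[-200, ]
  expect_equal(unname(sqrt(rowSums(bonds^2))), rep(1, 199))
  expect_gt(saw$generator$params$accepted, 0)
  expect_identical(generate_saw_pivot(200, 4000, seed = 5)$positions,
                   saw$positions)
  # swelling: excluded volume stretches the chain beyond the ideal value
  saws <- lapply(1:40, function(i) generate_saw_pivot(200, 4000, seed = i))
  msq <- mean(vapply(saws, function(c.)
    sum((c.$positions[200, ] - c.$positions[1, ])^2), numeric(1)))
  expect_gt(msq, 199)
  expect_error(generate_saw_pivot(200, 100),
               class = "fracdomain_invalid_argument")
})

test_that("the space-filling curve visits every cube site once with unit bonds", {
  ch <- generate_space_filling(3)
  pos <- ch$positions
  expect_equal(nrow(pos), 512)
  expect_equal(nrow(unique(pos)), 512)
  expect_equal(range(pos), c(0, 7))
  bonds <- pos[-1, ] - pos[-512, ]
  expect_equal(unname(sqrt(rowSums(bonds^2))), rep(1, 511))
  est <- estimate_df(ch, c(4, 64))
  expect_gt(est$df_hat, 2.6)
  expect_lt(est$df_hat, 3.4)
  expect_error(generate_space_filling(1),
               class = "fracdomain_invalid_argument")
})

test_that("fractional-Brownian chains round-trip their target fractal dimension", {
  for (df in c(1.5, 2, 2.5, 3)) {
    chains <- lapply(1:200, function(i)
      generate_fractal_chain(512, df, seed = 1000 * df + i))
    est <- estimate_df(chains)
    expect_equal(est$df_hat, df, tolerance = 0.15 / df,
                 label = sprintf("df_hat at target %.1f", df))
  }
  expect_identical(generate_fractal_chain(128, 2.4, seed = 9)$positions,
                   generate_fractal_chain(128, 2.4, seed = 9)$positions)
  expect_error(generate_fractal_chain(128, 3.5),
               class = "fracdomain_invalid_argument")
  # df = 1 degenerates to a collinear chain
  ch1 <- generate_fractal_chain(64, 1, seed = 2)
  bonds <- ch1$positions[-1, ] - ch1$positions[-64, ]
  expect_lt(max(abs(sweep(bonds, 2, bonds[1, ]))), 1e-9)
})

test_that("estimate_df is scale-invariant and validates its window", {
  chains <- lapply(1:20, function(i) generate_random_walk(256, seed = i))
  est <- estimate_df(chains)
  scaled <- lapply(chains, function(ch) {
    ch$positions <- ch$positions * 7.3
    ch
  })
  expect_equal(estimate_df(scaled)$df_hat, est$df_hat, tolerance = 1e-12)
  expect_error(estimate_df(chains, c(4, 5)),
               class = "fracdomain_invalid_argument")  # < 4 separations
  expect_error(estimate_df(chains, c(4, 200)),
               class = "fracdomain_invalid_argument")  # beyond N/4
  # degenerate input: all points identical beyond the first two
  degen <- new_degenerate_chain()
  expect_error(suppressWarnings(estimate_df(degen, c(2, 6))),
               class = "fracdomain_degenerate_input")
})

test_that("gyration radius matches closed-form cases and orders by compactness", {
  two <- generate_line(2, seed = 1)
  expect_equal(gyration_radius(two), 0.5, tolerance = 1e-12)
  same <- generate_line(8, seed = 1)
  same$positions <- matrix(1.5, 8, 3)
  expect_equal(gyration_radius(same), 0)
  # Debye: ideal-chain mean squared R_g ~ N b^2 / 6
  rg2 <- mean(vapply(1:300, function(i)
    gyration_radius(generate_random_walk(512, seed = i))^2, numeric(1)))
  expect_equal(rg2, 512 / 6, tolerance = 0.1)
  # compactness ordering follows d_f: line (1) > SAW (5/3) > ideal (2) > globule (3)
  n <- 512
  rg_line <- gyration_radius(generate_line(n, seed = 1))
  rg_saw <- mean(vapply(1:20, function(i)
    gyration_radius(generate_saw_pivot(n, 10240, seed = i)), numeric(1)))
  rg_rw <- mean(vapply(1:20, function(i)
    gyration_radius(generate_random_walk(n, seed = i)), numeric(1)))
  rg_sf <- gyration_radius(generate_space_filling(3))
  expect_true(rg_line > rg_saw && rg_saw > rg_rw && rg_rw > rg_sf)
})
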