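test_that("simulate_decay evaluates the multi-exponential model", {
  # single component, single echo: 250 * exp(-30/80)
  expect_equal(simulate_decay(cbind(250, 80), 30), 250 * exp(-30 / 80))
  expect_equal(round(simulate_decay(cbind(250, 80), 30), 2), 171.82)

  # t = 0 returns the amplitude for any component
  expect_equal(simulate_decay(cbind(123.4, 55), 0), 123.4)
  expect_equal(simulate_decay(list(c(10, 5), c(20, 50)), 0), 30)

  # three-component mixture matches term-by-term summation at every echo
  comps <- list(c(250, 80), c(250, 200), c(250, 600))
  te <- mese_te_grid(61)
  expect_equal(simulate_decay(comps, te), oracle_decay(comps, te))

  # strictly decreasing when any amplitude is positive
  y <- simulate_decay(comps, te)
  expect_true(all(diff(y) < 0))

  expect_error(simulate_decay(cbind(250, -5), te), "T2")
  expect_error(simulate_decay(cbind(-1, 80), te), "amplitude")
})

test_that("acquisition parameters enforce the MESE protocol invariants", {
  p <- acquisition_params()
  expect_equal(p$etl, 61)
  expect_equal(p$te_grid[1], 30)
  expect_equal(p$te_grid[61], 1830)
  expect_equal(diff(p$te_grid), rep(30, 60))
  expect_error(acquisition_params(te_grid = c(30, 30, 60)), "increasing")
  expect_error(acquisition_params(tr = 1000), "exceed")

  # long-TR regime: T1 recovery factor at TR 4000 is >= 0.98 for T1 <= 1000
  for (t1 in c(100, 500, 1000))
    expect_gte(long_tr_factor(4000, t1), 0.98)
})

test_that("generate_phantom rasterizes regions deterministically", {
  ph <- make_small_phantom(c(48, 48), n_echo = 12)
  expect_s3_class(ph$stack, "mese_stack")
  expect_equal(dim(ph$stack$data), c(48, 48, 12))
  expect_setequal(unique(as.vector(ph$labels)), 0:3)

  # every ring voxel carries the ring's decay; the ring mean equals it too
  te <- ph$stack$te_grid
  for (lb in 1:3) {
    expected <- simulate_decay(cbind(250, c(80, 200, 600)[lb]), te)
    m <- ph$labels == lb
    for (k in seq_along(te))
      expect_equal(mean(ph$stack$data[, , k][m]), expected[k])
  }
  # background is zero everywhere
  bg <- ph$labels == 0
  expect_true(all(ph$stack$data[, , 1][bg] == 0))

  # noiseless stacks decay monotonically at every voxel
  d <- ph$stack$data
  expect_true(all(d[, , -1] <= d[, , -dim(d)[3]]))

  # zero regions give an all-zero stack
  empty <- phantom_spec(c(8, 8), list())
  z <- generate_phantom(empty, acquisition_params(te_grid = mese_te_grid(5)))
  expect_true(all(z$stack$data == 0))

  # overlapping geometries are rejected
  disk <- function(rows, cols) {
    rr <- sqrt(outer(seq_len(rows) - rows / 2, rep(1, cols))^2 +
               outer(rep(1, rows), seq_len(cols) - cols / 2)^2)
    rr < 10
  }
  bad <- phantom_spec(c(32, 32), list(
    list(label = 1, geometry = disk, components = cbind(1, 100)),
    list(label = 2, geometry = disk, components = cbind(1, 100))
  ))
  expect_error(
    generate_phantom(bad, acquisition_params(te_grid = mese_te_grid(3))),
    "overlap"
  )
})

test_that("the acquisition-scale phantom has the expected geometry", {
  ph <- generate_phantom(phantom_rings(),
                         acquisition_params(te_grid = mese_te_grid(45)))
  expect_equal(dim(ph$stack$data), c(256, 256, 45))
  expect_setequal(unique(as.vector(ph$labels)), 0:3)
})

test_that("Rician noise injection matches the magnitude-reconstruction model", {
  ph <- make_small_phantom(c(32, 32), n_echo = 4)

  # sigma = 0 is the identity on nonnegative input
  same <- add_rician_noise(ph$stack, 0)
  expect_identical(same$data, ph$stack$data)

  # seeded determinism: bit-identical outputs
  a <- add_rician_noise(ph$stack, 5, seed = 7)
  b <- add_rician_noise(ph$stack, 5, seed = 7)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, add_rician_noise(ph$stack, 5, seed = 8)$data))

  # shape and TE grid preserved, sigma recorded, output nonnegative
  expect_equal(dim(a$data), dim(ph$stack$data))
  expect_equal(a$te_grid, ph$stack$te_grid)
  expect_equal(a$sigma, 5)
  expect_true(all(a$data >= 0))

  expect_error(add_rician_noise(ph$stack, -1), "nonnegative")

  # background magnitudes are Rayleigh: mean = sigma * sqrt(pi/2)
  zeros <- mese_stack(array(0, c(320, 320, 1)), 30)
  sg <- 4
  noisy <- add_rician_noise(zeros, sg, seed = 3)
  expect_equal(mean(noisy$data), sg * sqrt(pi / 2), tolerance = 0.02)

  # high-SNR regime: expected magnitude within 2% of the signal (S = 6 sigma)
  flat <- mese_stack(array(24, c(320, 320, 1)), 30)
  noisy <- add_rician_noise(flat, 4, seed = 5)
  expect_equal(mean(noisy$data) / 24, 1, tolerance = 0.02)
})

test_that("per-echo SNR estimation recovers the injected noise level", {
  ph <- make_small_phantom(c(48, 48), n_echo = 10)
  sig_mask <- ph$labels > 0
  bg_mask <- ph$labels == 0

  # noiseless: noise power reported as 0
  tab <- estimate_layer_snr(ph$stack, sig_mask, bg_mask)
  expect_true(all(tab$noise_power == 0))
  expect_equal(nrow(tab), 10)

  # pure-noise stack: sigma_hat within 3% of injected sigma at 256 x 256
  zeros <- mese_stack(array(0, c(256, 256, 2)), c(30, 60))
  noisy <- add_rician_noise(zeros, 7, seed = 9)
  half <- matrix(FALSE, 256, 256); half[1:10, 1:10] <- TRUE
  tab <- estimate_layer_snr(noisy, half, !half)
  expect_equal(tab$sigma_hat / 7, rep(1, 2), tolerance = 0.03)

  expect_error(estimate_layer_snr(ph$stack, sig_mask, sig_mask), "disjoint")
  expect_error(
    estimate_layer_snr(ph$stack, matrix(FALSE, 48, 48), bg_mask),
    "nonempty"
  )
})
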