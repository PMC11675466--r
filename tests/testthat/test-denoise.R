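test_that("patch_distance matches a brute-force kernel-weighted norm", {
  st <- make_random_stack(5, 5, 3)
  cfg <- nlm_config(patch_radius_space = 1, patch_radius_echo = 1,
                    a1 = 1, a2 = 2)

  # identical patches and symmetry
  expect_equal(patch_distance(st, c(3, 3), c(3, 3), 2, cfg), 0)
  d_ab <- patch_distance(st, c(2, 2), c(4, 3), 2, cfg)
  d_ba <- patch_distance(st, c(4, 3), c(2, 2), 2, cfg)
  expect_equal(d_ab, d_ba)
  expect_gte(d_ab, 0)

  # brute-force oracle over all center pairs including border-clipped ones
  for (pair in list(list(c(1, 1), c(5, 5)), list(c(2, 4), c(3, 2)),
                    list(c(1, 3), c(3, 3)))) {
    for (te in 1:3) {
      expect_equal(
        patch_distance(st, pair[[1]], pair[[2]], te, cfg),
        oracle_patch_distance(st$data, pair[[1]], pair[[2]], te,
                              prs = 1, pre = 1, a1 = 1, a2 = 2)
      )
    }
  }
  expect_error(patch_distance(st, c(0, 1), c(2, 2), 1, cfg), "inside")
  expect_error(patch_distance(st, c(1, 1), c(2, 2), 9, cfg), "range")
})

test_that("non-local-means weights are normalized", {
  st <- make_random_stack(7, 7, 3, seed = 4)
  cfg <- nlm_config(patch_radius_space = 1, patch_radius_echo = 1,
                    search_radius_space = 2, h_schedule = 20,
                    noise_power_schedule = 50)
  for (pos in list(c(1, 1), c(4, 4), c(7, 2))) {
    for (te in 1:3) {
      w <- nlm_weights(st, pos, te, cfg)
      expect_equal(sum(w$weight), 1, tolerance = 1e-9)
      expect_true(all(w$weight >= 0))
    }
  }
})

test_that("nlmeans2d has the constant fixed point and window-mean limit", {
  cfg <- nlm_config(search_radius_space = 2)
  flat <- matrix(42, 12, 12)
  expect_equal(nlmeans2d(flat, cfg, h = 1, noise_power = 0), flat,
               tolerance = 1e-12)

  # enormous bandwidth: every voxel approaches its search-window mean
  set.seed(8)
  img <- matrix(runif(64, 0, 10), 8, 8)
  out <- nlmeans2d(img, cfg, h = 1e8, noise_power = 0)
  # interior voxel: full 5x5 window
  expect_equal(out[4, 4], mean(img[2:6, 2:6]), tolerance = 1e-4)
})

test_that("nlmeans2d reduces variance on a homogeneous noisy region", {
  set.seed(21)
  img <- matrix(100 + rnorm(48 * 48, 0, 10), 48, 48)
  den <- nlmeans2d(img, nlm_config(), h = 10, noise_power = 100)
  inner <- 10:39
  expect_lt(stats::var(as.vector(den[inner, inner])),
            stats::var(as.vector(img[inner, inner])))
  # mean preserved within 1% on the homogeneous interior
  expect_equal(mean(den[inner, inner]) / mean(img[inner, inner]), 1,
               tolerance = 0.01)
})

test_that("nlmeans3d matches the weight-field reference implementation", {
  st <- make_random_stack(6, 6, 3, seed = 12)
  cfg <- nlm_config(patch_radius_space = 1, patch_radius_echo = 1,
                    search_radius_space = 2, h_schedule = c(30, 30, 35),
                    noise_power_schedule = 60)
  out <- nlmeans3d(st, cfg)
  ref <- oracle_nlmeans3d(st, cfg)
  expect_equal(out$data, ref, tolerance = 1e-10)
})

test_that("nlmeans3d degenerate configurations behave as documented", {
  st <- make_random_stack(6, 6, 3, seed = 13)

  # constant stack is a fixed point
  flat <- mese_stack(array(7, c(6, 6, 3)), st$te_grid)
  cfg <- nlm_config(h_schedule = 1, noise_power_schedule = 0)
  expect_equal(nlmeans3d(flat, cfg)$data, flat$data, tolerance = 1e-12)

  # echo patch radius 0 with shared schedules equals per-layer 2D filtering
  cfg0 <- nlm_config(patch_radius_echo = 0, search_radius_space = 2,
                     h_schedule = c(25, 25, 25), noise_power_schedule = 40)
  out3 <- nlmeans3d(st, cfg0)
  for (k in 1:3) {
    out2 <- nlmeans2d(st$data[, , k], cfg0, h = 25, noise_power = 40)
    expect_equal(out3$data[, , k], out2, tolerance = 1e-12)
  }

  # search radius 0: only the self weight contributes -> identity
  cfg_id <- nlm_config(search_radius_space = 0, h_schedule = 10,
                       noise_power_schedule = 0)
  expect_equal(nlmeans3d(st, cfg_id)$data, st$data, tolerance = 1e-12)

  # schedule length mismatch is a configuration error
  bad <- nlm_config(h_schedule = c(1, 2))
  expect_error(nlmeans3d(st, bad), "length")
  # too few echoes for the echo patch radius
  thin <- mese_stack(st$data[, , 1, drop = FALSE], 30)
  expect_error(nlmeans3d(thin, nlm_config(patch_radius_echo = 2)), "echoes")
})

test_that("h_schedule_from_noise maps noise power to a monotone bandwidth", {
  # constant power: constant h = scale * sqrt(p)
  expect_equal(h_schedule_from_noise(rep(25, 5), scale = 2), rep(10, 5))
  # zero noise: positive floor
  expect_equal(h_schedule_from_noise(rep(0, 3)), rep(1e-6, 3))
  # increasing powers: strictly increasing h
  h <- h_schedule_from_noise(c(1, 4, 9, 16))
  expect_true(all(diff(h) > 0))
  # a dip is flattened by the running maximum, never decreasing
  h <- h_schedule_from_noise(c(4, 1, 9))
  expect_true(all(diff(h) >= 0))
  expect_error(h_schedule_from_noise(c(1, -2)), "nonnegative")
})

test_that("denoising metrics match hand-computed definitions", {
  truth <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16),
                  4, 4) / 16
  noisy <- truth + 0.1
  den <- truth + 0.05

  m <- evaluate_denoising(noisy, den, truth)
  rng <- max(truth) - min(truth)
  expect_equal(m$aggregate$rmse, 0.05)
  expect_equal(m$aggregate$psnr, 10 * log10(rng^2 / 0.05^2))

  # perfect reconstruction: zero RMSE, infinite PSNR
  m0 <- evaluate_denoising(noisy, truth, truth)
  expect_equal(m0$aggregate$rmse, 0)
  expect_equal(m0$aggregate$psnr, Inf)

  # denoised == noisy reproduces the noisy baseline
  mn <- evaluate_denoising(noisy, noisy, truth)
  expect_equal(mn$aggregate$psnr, mn$per_echo$psnr_noisy[1])

  expect_error(evaluate_denoising(noisy, den, truth[1:2, ]), "match")
})
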