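test_that("the chaos map follows the logistic recurrence and stays bounded", {
  expect_equal(chaos_step(0.25), 0.75)
  expect_equal(chaos_step(0.5), 1)   # absorbing; reseeded on the next call
  expect_equal(chaos_step(0.1), 4 * 0.1 * 0.9)

  # long iteration stays in [0, 1] with nondegenerate variance
  set.seed(3)
  r <- 0.3
  seq <- numeric(1e4)
  for (k in seq_along(seq)) {
    r <- chaos_step(r)
    seq[k] <- r
  }
  expect_true(all(seq >= 0 & seq <= 1))
  expect_gt(stats::var(seq), 0.01)
})

test_that("the particle update follows the velocity equation and clips", {
  b <- component_bounds(c(0, 0), c(10, 10))
  p <- list(x = c(2, 3), v = c(1, -1), pbest = c(4, 4))

  # degenerate coefficients: pure inertia
  up <- pso_update(p, gbest = c(9, 9), w = 1, c1 = 0, c2 = 0,
                   r1 = 0.5, r2 = 0.5, bounds = b)
  expect_equal(up$x, p$x + p$v)
  expect_equal(up$v, p$v)

  # at the attractors the velocity only decays
  p2 <- list(x = c(5, 5), v = c(2, 2), pbest = c(5, 5))
  up <- pso_update(p2, gbest = c(5, 5), w = 0.7, c1 = 2, c2 = 2,
                   r1 = 0.3, r2 = 0.9, bounds = b)
  expect_equal(up$v, 0.7 * c(2, 2))

  # general coefficients match the formula
  up <- pso_update(p, gbest = c(9, 9), w = 0.5, c1 = 1.5, c2 = 2,
                   r1 = 0.2, r2 = 0.4, bounds = b)
  v_exp <- 0.5 * p$v + 1.5 * 0.2 * (p$pbest - p$x) + 2 * 0.4 * (c(9, 9) - p$x)
  expect_equal(up$x, pmin(pmax(p$x + v_exp, 0), 10))

  # 1000 random updates on a 1-D quadratic stay inside the bounds
  set.seed(14)
  b1 <- component_bounds(c(0, -3), c(1, 7))
  part <- list(x = c(0.5, 2), v = c(0, 0), pbest = c(0.5, 1))
  fit1 <- function(x) (x[2] - 1)^2
  part$pbest_fit <- fit1(part$pbest)
  for (k in 1:1000) {
    part <- pso_update(part, gbest = part$pbest, w = runif(1, 0.4, 0.9),
                       c1 = 2, c2 = 2, r1 = runif(1), r2 = runif(1),
                       bounds = b1, fitness_fn = fit1)
    expect_true(all(part$x >= b1$lo & part$x <= b1$hi))
  }
})

test_that("immune operators preserve size and never worsen the best", {
  set.seed(6)
  b <- component_bounds(c(0, 1), c(100, 500))
  sphere <- function(X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    rowSums((X - rep(c(40, 200), each = nrow(X)))^2)
  }
  n <- 12
  X <- cbind(runif(n, 0, 100), runif(n, 1, 500))
  swarm <- list(X = X, V = matrix(0, n, 2), P = X,
                fit = sphere(X), pfit = sphere(X))

  # inert configuration: swarm unchanged
  cfg0 <- optimizer_config(clone_count = 0, p_mutation = 0, p_crossover = 0)
  out <- immune_operators(swarm, b, cfg0, sphere)
  expect_equal(out$X, swarm$X)

  # active operators: elitist selection keeps or improves the minimum
  cfg <- optimizer_config(n_particles = n)
  for (g in 1:20) {
    out <- immune_operators(swarm, b, cfg, sphere, r_chaos = runif(1))
    expect_equal(nrow(out$X), n)
    expect_lte(min(out$fit), min(swarm$fit))
    expect_true(all(out$X >= rep(b$lo, each = n)))
    expect_true(all(out$X <= rep(b$hi, each = n)))
    swarm <- out[c("X", "V", "P", "fit", "pfit")]
  }
})

test_that("adaptive interval update compresses toward the incumbent", {
  b <- component_bounds(c(0, 0), c(100, 1000), s = 0.6, gamma = 5)

  # centered incumbent: m1 = m2 = 0.5 < s, no update
  out <- adapt_bounds(b, c(50, 500))
  expect_equal(out$lo, b$lo)
  expect_equal(out$hi, b$hi)

  # incumbent near the lower bound: the upper bound compresses (s < m1 < 1)
  out <- adapt_bounds(b, c(10, 100))
  expect_lt(out$hi[1], b$hi[1])
  expect_lt(out$hi[2], b$hi[2])
  expect_equal(out$lo, b$lo)  # m2 = 0.1 below s: lower bound unchanged
  # the move is |ln m1| / gamma of the width
  m1 <- (100 - 10) / 100
  expect_equal(out$hi[1], 100 - abs(log(m1)) / 5 * 100)

  # incumbent on a bound: that dimension left unchanged
  out <- adapt_bounds(b, c(0, 500))
  expect_equal(out$lo[1], 0)
  expect_equal(out$hi[1], 100)

  # repeated adaptation: width non-increasing, incumbent always inside
  g <- c(30, 700)
  cur <- b
  widths <- matrix(NA_real_, 50, 2)
  for (k in 1:50) {
    nxt <- adapt_bounds(cur, g)
    expect_true(all(nxt$lo < g & g < nxt$hi))
    expect_true(all(nxt$hi - nxt$lo <= cur$hi - cur$lo + 1e-12))
    widths[k, ] <- nxt$hi - nxt$lo
    cur <- nxt
  }
  expect_true(all(diff(widths[, 1]) <= 1e-12))

  # multi-component T2 intervals stay disjoint under adaptation
  b3 <- default_bounds(3, 600)
  g3 <- c(200, 80, 200, 200, 200, 600)
  for (k in 1:20) {
    b3 <- adapt_bounds(b3, g3)
    t2 <- 2 * 1:3
    expect_lte(b3$hi[t2[1]], b3$lo[t2[2]])
    expect_lte(b3$hi[t2[2]], b3$lo[t2[3]])
  }
})

test_that("bounds constructors validate their invariants", {
  expect_error(component_bounds(c(0, 10), c(5, 5)), "lo < hi")
  expect_error(component_bounds(c(0, 1, 0, 1), c(10, 500, 10, 400)),
               "non-overlapping")
  expect_error(component_bounds(c(0, 1), c(10, 100), s = 1.5), "s must")
  expect_error(component_bounds(c(0, 1), c(10, 100), gamma = 0), "gamma")
  b <- default_bounds(3, 250)
  expect_equal(b$e, 3)
  expect_true(all(b$lo < b$hi))
})

test_that("swarm inversion recovers noiseless decays to high precision", {
  te <- mese_te_grid(61)
  curve <- decay_curve(te, simulate_decay(cbind(250, 80), te))
  fit <- invert_decay(curve, e = 1, config = optimizer_config(seed = 7))
  expect_equal(unname(fit$theta$components[1, "A"]), 250, tolerance = 1e-3)
  expect_equal(unname(fit$theta$components[1, "T2"]), 80, tolerance = 1e-3)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  # same curve + same seed: identical result
  fit2 <- invert_decay(curve, e = 1, config = optimizer_config(seed = 7))
  expect_identical(fit$theta$components, fit2$theta$components)
  expect_identical(fit$cls, fit2$cls)

  # log-linear oracle equivalence on random mono-exponential curves
  set.seed(17)
  for (k in 1:8) {
    A <- runif(1, 50, 500); T2 <- runif(1, 40, 1000)
    y <- simulate_decay(cbind(A, T2), te)
    o <- oracle_loglinear(te, y)
    f <- invert_decay(decay_curve(te, y), e = 1,
                      config = optimizer_config(seed = k))
    expect_equal(unname(f$theta$components[1, "T2"]) / o[["T2"]], 1,
                 tolerance = 1e-3)
  }
})

test_that("tri-exponential inversion matches the least-squares oracle", {
  skip_if_not_installed("minpack.lm")
  te <- mese_te_grid(61)
  comps <- list(c(250, 80), c(250, 200), c(250, 600))
  curve <- decay_curve(te, simulate_decay(comps, te))
  fit <- invert_decay(curve, e = 3, config = optimizer_config(seed = 11))

  o <- minpack.lm::nlsLM(
    y ~ a1 * exp(-te / t1) + a2 * exp(-te / t2) + a3 * exp(-te / t3),
    data.frame(te = te, y = curve$y),
    start = list(a1 = 250, t1 = 80, a2 = 250, t2 = 200, a3 = 250, t3 = 600)
  )
  t2_oracle <- sort(stats::coef(o)[c("t1", "t2", "t3")])
  expect_equal(unname(fit$theta$components[, "T2"] / t2_oracle), rep(1, 3),
               tolerance = 0.05)
})

test_that("the optimizer trace shows monotone best fitness inside bounds", {
  te <- mese_te_grid(45)
  curve <- decay_curve(te, simulate_decay(cbind(180, 350), te))
  fit <- invert_decay(curve, e = 1,
                      config = optimizer_config(seed = 19, trace = TRUE))
  h <- fit$history
  expect_true(all(diff(h$gfit) <= 0))
  expect_true(all(h$in_bounds))
  # interval widths never grow
  w1 <- vapply(seq_along(h$lo), function(k) h$hi[[k]][2] - h$lo[[k]][2],
               numeric(1))
  expect_true(all(diff(w1) <= 1e-9))
})

test_that("invert_decay validates inputs", {
  te <- mese_te_grid(10)
  curve <- decay_curve(te, simulate_decay(cbind(10, 100), te))
  expect_error(invert_decay(curve, e = 5), "e must")
  expect_error(
    invert_decay(curve, e = 1, bounds = default_bounds(2, 10)),
    "different number"
  )
  short <- decay_curve(te[1:3], curve$y[1:3])
  expect_error(invert_decay(short, e = 2), "echoes")
})
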