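# Chaotic immune particle-swarm inversion with adaptive component-interval
# bounds: the engine that minimizes the weighted least-squares criterion of
# the multi-exponential decay model.

#' Per-component search-interval bounds
#'
#' Lower and upper bounds for every model parameter in the optimizer's
#' vector layout `(A_1, T2_1, A_2, T2_2, ...)`, with components ordered by
#' ascending T2 interval. The e relaxation-time intervals must be pairwise
#' non-overlapping and ascending: this component segmentation is what makes
#' the multi-exponential fit identifiable and keeps the water-state labels
#' stable during optimization. `s` and `gamma` parameterize the adaptive
#' interval update (see [adapt_bounds()]).
#'
#' @param lo,hi Numeric vectors of length `2e`, elementwise `lo < hi`.
#' @param s Interval-update threshold in (0, 1); a bound is only moved when
#'   the incumbent best lies in the outer `1 - s` fraction... see
#'   [adapt_bounds()]. Default 0.6.
#' @param gamma Compression factor > 0 scaling the bound movement; larger
#'   values move bounds more cautiously. Default 5.
#' @return An object of class `component_bounds`.
#' @export
component_bounds <- function(lo, hi, s = 0.6, gamma = 5) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != length(hi) || length(lo) %% 2 != 0)
    stop("lo and hi must have equal even length (A, T2 per component)")
  if (any(lo >= hi)) stop("need lo < hi elementwise")
  e <- length(lo) / 2
  t2_idx <- 2 * seq_len(e)
  if (e > 1) {
    for (j in seq_len(e - 1)) {
      if (hi[t2_idx[j]] > lo[t2_idx[j + 1]])
        stop("T2 intervals must be non-overlapping and ascending")
    }
  }
  if (s <= 0 || s >= 1) stop("s must be in (0, 1)")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(lo = lo, hi = hi, s = s, gamma = gamma, e = e),
            class = "component_bounds")
}

#' Default search bounds for an e-component fit
#'
#' Amplitude intervals are `[0, 2 * y1 * f_j]` per component, where `y1` is
#' the first-echo signal and `f_j = min(exp(te1 / t2lo_j), exp(2))` undoes
#' the decay a component at the slow end of its T2 interval has already
#' suffered by the first echo time `te1` (capped at `exp(2)`: components
#' decaying much faster than the first echo are not identifiable anyway).
#' Relaxation-time intervals segment the physically meaningful T2 range:
#' for e = 3 they are (1, 100], (100, 400], (400, 2000] ms, bracketing
#' bound, semi-bound and free water in fruit tissue at low field.
#'
#' @param e Number of components (1-4).
#' @param y1 First-echo signal amplitude used to scale the amplitude bounds.
#' @param te1 First echo time (ms), used to back-extrapolate the amplitude
#'   cap. Default 30.
#' @param s,gamma Passed to [component_bounds()].
#' @return A `component_bounds`.
#' @export
default_bounds <- function(e, y1, te1 = 30, s = 0.6, gamma = 5) {
  if (!e %in% 1:4) stop("e must be 1, 2, 3 or 4")
  if (y1 <= 0) stop("y1 must be positive")
  t2_int <- switch(e,
    `1` = list(c(1, 2000)),
    `2` = list(c(1, 200), c(200, 2000)),
    `3` = list(c(1, 100), c(100, 400), c(400, 2000)),
    `4` = list(c(1, 60), c(60, 200), c(200, 600), c(600, 2000))
  )
  lo <- hi <- numeric(2 * e)
  for (j in seq_len(e)) {
    f <- min(exp(te1 / t2_int[[j]][1]), exp(2))
    lo[2 * j - 1] <- 0;            hi[2 * j - 1] <- 2 * y1 * f
    lo[2 * j]     <- t2_int[[j]][1]; hi[2 * j]   <- t2_int[[j]][2]
  }
  component_bounds(lo, hi, s = s, gamma = gamma)
}

#' Optimizer configuration
#'
#' Hyperparameters of the chaotic immune particle swarm. The defaults favour
#' accuracy (region-level fits); the `"fast"` preset trades some accuracy
#' for speed and suits voxel-wise mapping and provisional fits.
#'
#' @param n_particles Swarm size (>= 2).
#' @param max_iter Maximum iterations; `NULL` (the default) resolves at fit
#'   time to a per-component budget (500 iterations per exponential
#'   component, 150 for the `"fast"` preset), since the search space grows
#'   with the model order.
#' @param tol Absolute criterion value below which iteration stops.
#' @param stall_iter,stall_tol Stop when the best criterion improves by less
#'   than `stall_tol` (relative) over `stall_iter` iterations; `stall_iter
#'   = NULL` likewise resolves per component at fit time.
#' @param w_max,w_min Inertia weight, decayed linearly from `w_max` to
#'   `w_min` over `max_iter` iterations.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param elite_frac Fraction of the swarm cloned by the immune operator.
#' @param clone_count Clones per elite particle.
#' @param p_mutation Per-dimension chaotic mutation probability of a clone.
#' @param p_crossover Probability that a random clone pair undergoes
#'   arithmetic crossover.
#' @param adapt_every Apply the adaptive interval update every this many
#'   iterations (0 disables it).
#' @param seed Integer seed; the run is reproducible given the seed. `NULL`
#'   uses (and advances) the caller's RNG stream.
#' @param trace Record the best criterion value and the interval bounds at
#'   every iteration (in the fit's `history`).
#' @param preset `"default"` or `"fast"`; a preset supplies base values which
#'   explicit arguments then override.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(n_particles = NULL, max_iter = NULL, tol = 0,
                             stall_iter = NULL, stall_tol = 1e-10,
                             w_max = 0.9, w_min = 0.4, c1 = 2, c2 = 2,
                             elite_frac = 0.1, clone_count = 3,
                             p_mutation = 0.1, p_crossover = 0.5,
                             adapt_every = 10, seed = NULL, trace = FALSE,
                             preset = c("default", "fast")) {
  preset <- match.arg(preset)
  if (is.null(n_particles))
    n_particles <- switch(preset, default = 60, fast = 30)
  if (n_particles < 2) stop("n_particles must be >= 2")
  for (p in c(elite_frac, p_mutation, p_crossover))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  structure(list(
    n_particles = n_particles, max_iter = max_iter, tol = tol,
    stall_iter = stall_iter, stall_tol = stall_tol,
    w_max = w_max, w_min = w_min, c1 = c1, c2 = c2,
    elite_frac = elite_frac, clone_count = clone_count,
    p_mutation = p_mutation, p_crossover = p_crossover,
    adapt_every = adapt_every, seed = seed, trace = trace, preset = preset
  ), class = "optimizer_config")
}

#' Logistic chaos map step
#'
#' One step of the logistic map at full chaos, `r' = 4 r (1 - r)`, used to
#' evolve the stochastic coefficients r1, r2 of the velocity update and to
#' drive chaotic mutation. Inputs outside the open interval (0, 1), and the
#' fixed point 0.75 (where the map would stall), are replaced by a fresh
#' uniform draw before stepping; note the map sends 0.5 to 1, so a returned
#' 1 triggers a reseed on the following call.
#'
#' @param r Current value.
#' @return Next value in `[0, 1]`.
#' @examples
#' chaos_step(0.25)  # 0.75
#' chaos_step(0.5)   # 1; the next call reseeds
#' @export
chaos_step <- function(r) {
  if (!is.finite(r) || r <= 0 || r >= 1 || r == 0.75)
    r <- runif(1)
  4 * r * (1 - r)
}

#' One particle-swarm velocity/position update
#'
#' The canonical update
#' `v' = w v + c1 r1 (pBest - x) + c2 r2 (gBest - x)`, `x' = x + v'`, with
#' positions clipped to the bounds; a clipped dimension gets zero velocity
#' so particles do not press against the walls. If a fitness function is
#' supplied, the particle's personal best is updated when the new position
#' improves on it.
#'
#' @param particle List with numeric vectors `x`, `v`, `pbest`, and
#'   optionally `pbest_fit`.
#' @param gbest Global best position.
#' @param w,c1,c2 Inertia and acceleration coefficients.
#' @param r1,r2 Stochastic coefficients in (0, 1) (chaotically evolved in
#'   the full algorithm).
#' @param bounds A [component_bounds] (or any list with `lo`, `hi`).
#' @param fitness_fn Optional scalar fitness function of a position vector.
#' @return The updated particle list.
#' @export
pso_update <- function(particle, gbest, w, c1, c2, r1, r2, bounds,
                       fitness_fn = NULL) {
  v <- w * particle$v +
    c1 * r1 * (particle$pbest - particle$x) +
    c2 * r2 * (gbest - particle$x)
  x <- particle$x + v
  lo <- bounds$lo; hi <- bounds$hi
  clipped <- x < lo | x > hi
  x <- pmin(pmax(x, lo), hi)
  v[clipped] <- 0
  particle$x <- x
  particle$v <- v
  if (!is.null(fitness_fn)) {
    f <- fitness_fn(x)
    particle$fit <- f
    if (is.null(particle$pbest_fit) || f < particle$pbest_fit) {
      particle$pbest <- x
      particle$pbest_fit <- f
    }
  }
  particle
}

#' Immune clone / crossover / mutation operator
#'
#' The artificial-immune-system step of the optimizer: the highest-affinity
#' particles (affinity = `1 / (1 + fitness)`) are cloned; clones undergo
#' chaotic mutation (a mutated dimension is replaced by
#' `lo + r * (hi - lo)` with `r` drawn from the logistic chaos stream) and
#' arithmetic crossover between random clone pairs; clones are evaluated and
#' the best `n` individuals among parents and clones survive. Selection is
#' elitist, so the best criterion value never worsens and the swarm size is
#' preserved.
#'
#' @param swarm List with matrices `X` (positions, one row per particle),
#'   `V` (velocities), `P` (personal bests), and vectors `fit`, `pfit`.
#' @param bounds A [component_bounds].
#' @param config An [optimizer_config].
#' @param fitness_fn Vectorized fitness: `function(X) -> numeric(nrow(X))`.
#' @param r_chaos Current value of the mutation chaos stream.
#' @return The updated swarm list, with element `r_chaos` carrying the
#'   advanced chaos stream value.
#' @export
immune_operators <- function(swarm, bounds, config, fitness_fn, r_chaos = 0.31) {
  n <- nrow(swarm$X)
  n_elite <- max(1L, floor(config$elite_frac * n))
  if (config$clone_count < 1 || config$elite_frac == 0) {
    swarm$r_chaos <- r_chaos
    return(swarm)
  }
  elite <- order(swarm$fit)[seq_len(n_elite)]
  clones <- swarm$X[rep(elite, each = config$clone_count), , drop = FALSE]
  d <- ncol(clones)
  lo <- bounds$lo; hi <- bounds$hi
  # hypermutation: Gaussian jitter at the scale of the swarm's current
  # per-dimension spread, so clones refine locally as the swarm contracts
  spread <- pmax(apply(swarm$X, 2, stats::sd), 1e-12 * (hi - lo))
  clones <- clones + matrix(rnorm(length(clones)), nrow(clones), d) *
    rep(spread, each = nrow(clones))
  # chaotic mutation
  if (config$p_mutation > 0 && nrow(clones) > 0) {
    mask <- matrix(runif(length(clones)) < config$p_mutation,
                   nrow(clones), d)
    idx <- which(mask)
    if (length(idx) > 0) {
      rs <- numeric(length(idx))
      for (k in seq_along(rs)) {
        r_chaos <- chaos_step(r_chaos)
        rs[k] <- r_chaos
      }
      dims <- ((idx - 1) %/% nrow(clones)) + 1L
      clones[idx] <- lo[dims] + rs * (hi[dims] - lo[dims])
    }
  }
  # arithmetic crossover between random clone pairs
  nc <- nrow(clones)
  if (config$p_crossover > 0 && nc >= 2) {
    idx_perm <- sample.int(nc)
    m <- floor(nc / 2)
    pairs <- cbind(idx_perm[seq_len(m)], idx_perm[m + seq_len(m)])
    for (p in seq_len(nrow(pairs))) {
      if (runif(1) < config$p_crossover) {
        a <- pairs[p, 1]; b <- pairs[p, 2]
        alpha <- runif(1)
        xa <- clones[a, ]; xb <- clones[b, ]
        clones[a, ] <- alpha * xa + (1 - alpha) * xb
        clones[b, ] <- (1 - alpha) * xa + alpha * xb
      }
    }
  }
  # receptor correction: amplitudes snapped to their conditional
  # least-squares optimum given each clone's relaxation times
  rc <- attr(fitness_fn, "receptor_correct")
  if (!is.null(rc)) clones <- rc(clones)
  # keep clones inside the current bounds
  clones <- pmin(pmax(clones, rep(lo, each = nrow(clones))),
                 rep(hi, each = nrow(clones)))
  cfit <- fitness_fn(clones)
  # elitist selection among parents + clones
  all_X <- rbind(swarm$X, clones)
  all_V <- rbind(swarm$V, matrix(0, nc, d))
  all_fit <- c(swarm$fit, cfit)
  all_P <- rbind(swarm$P, clones)
  all_pfit <- c(swarm$pfit, cfit)
  keep <- order(all_fit)[seq_len(n)]
  swarm$X <- all_X[keep, , drop = FALSE]
  swarm$V <- all_V[keep, , drop = FALSE]
  swarm$fit <- all_fit[keep]
  swarm$P <- all_P[keep, , drop = FALSE]
  swarm$pfit <- all_pfit[keep]
  swarm$r_chaos <- r_chaos
  swarm
}

#' Adaptive component-interval update (peak correction)
#'
#' Compresses the per-parameter search interval around the incumbent best
#' position. For each dimension with interval `[lo, hi]` of width `W` and
#' incumbent `g` strictly inside, let `m1 = (hi - g) / W` and
#' `m2 = (g - lo) / W`. When `s < m1 < 1` the upper bound moves toward `g`
#' by `|log(m1)| / gamma` of the width; symmetrically for the lower bound
#' when `s < m2 < 1`. The incumbent always stays strictly inside the updated
#' interval, and adjacent relaxation-time intervals are kept non-overlapping
#' by clipping at the midpoint of any would-be overlap. Dimensions whose
#' incumbent lies on or outside a bound are left unchanged.
#'
#' @param bounds A [component_bounds].
#' @param gbest Incumbent best position (optimizer vector layout).
#' @param s,gamma Override the bounds' own `s` and `gamma` if given.
#' @return The updated `component_bounds`.
#' @export
adapt_bounds <- function(bounds, gbest, s = NULL, gamma = NULL) {
  stopifnot(inherits(bounds, "component_bounds"))
  if (is.null(s)) s <- bounds$s
  if (is.null(gamma)) gamma <- bounds$gamma
  lo <- bounds$lo; hi <- bounds$hi
  d <- length(lo)
  if (length(gbest) != d) stop("gbest length must match bounds")
  for (k in seq_len(d)) {
    g <- gbest[k]
    if (g <= lo[k] || g >= hi[k]) next  # incumbent on/outside: leave alone
    W <- hi[k] - lo[k]
    m1 <- (hi[k] - g) / W
    m2 <- (g - lo[k]) / W
    if (m1 > s && m1 < 1) {
      new_hi <- hi[k] - abs(log(m1)) / gamma * W
      hi[k] <- max(new_hi, g + 1e-12 * max(1, abs(g)))
    }
    if (m2 > s && m2 < 1) {
      new_lo <- lo[k] + abs(log(m2)) / gamma * W
      lo[k] <- min(new_lo, g - 1e-12 * max(1, abs(g)))
    }
  }
  # keep adjacent T2 intervals disjoint
  e <- bounds$e
  if (e > 1) {
    t2 <- 2 * seq_len(e)
    for (j in seq_len(e - 1)) {
      a <- t2[j]; b <- t2[j + 1]
      if (hi[a] > lo[b]) {
        mid <- (hi[a] + lo[b]) / 2
        hi[a] <- min(hi[a], mid)
        lo[b] <- max(lo[b], mid)
      }
    }
  }
  component_bounds(lo, hi, s = bounds$s, gamma = bounds$gamma)
}

# Vectorized weighted least-squares criterion over a swarm position matrix.
# The returned closure carries a "receptor_correct" attribute: the immune
# receptor-correction operator, which refines a particle's amplitudes to
# their exact conditional least-squares values given its relaxation times
# (the criterion is linear in the amplitudes), clipped to the bounds.
make_swarm_objective <- function(curve, e, bounds = NULL) {
  te <- curve$te; y <- curve$y
  nt <- length(te)
  inv2s2 <- rep(1 / (2 * curve$sigma^2), length.out = nt)
  f <- function(X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    S <- matrix(0, nt, nrow(X))
    for (j in seq_len(e)) {
      A <- X[, 2 * j - 1]
      T2 <- X[, 2 * j]
      S <- S + exp(outer(te, -1 / T2)) * rep(A, each = nt)
    }
    colSums((y - S)^2 * inv2s2)
  }
  a_idx <- 2 * seq_len(e) - 1
  t_idx <- 2 * seq_len(e)
  # weighted design for the conditional amplitude solve
  sw <- sqrt(2 * inv2s2)
  yw <- y * sw
  attr(f, "receptor_correct") <- function(X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    for (r in seq_len(nrow(X))) {
      E <- exp(outer(te, -1 / X[r, t_idx])) * sw
      A <- tryCatch(qr.solve(E, yw), error = function(err) NULL)
      if (is.null(A) || any(!is.finite(A))) next
      X[r, a_idx] <- pmax(A, 0)
    }
    X
  }
  f
}

#' Invert a decay curve by the chaotic immune particle swarm
#'
#' Fits an e-component exponential decay to a measured curve by minimizing
#' the weighted least-squares criterion ([objective_cls()]) with particle
#' swarm optimization refined by chaotic coefficient updates, immune
#' clone/crossover/mutation, and periodic adaptive compression of the
#' per-component search intervals around the incumbent best
#' ([adapt_bounds()]). Components of the returned fit are sorted ascending
#' by T2.
#'
#' @param curve A [decay_curve].
#' @param e Number of exponential components (1-4).
#' @param bounds A [component_bounds] for `2e` parameters; default
#'   [default_bounds()] scaled by the curve's first-echo signal.
#' @param config An [optimizer_config].
#' @return An object of class `fit_result`: list with `theta`
#'   ([exp_params]), `cls` (final criterion value), `r2`, `rmse` (via
#'   [fit_metrics()]), `excluded` (empty here; filled by
#'   [invert_structures()]), `n_iter`, and `converged`.
#' @examples
#' te <- mese_te_grid(61)
#' curve <- decay_curve(te, simulate_decay(cbind(250, 80), te))
#' fit <- invert_decay(curve, e = 1, config = optimizer_config(seed = 7))
#' fit$theta$components
#' @export
invert_decay <- function(curve, e = 1, bounds = NULL,
                         config = optimizer_config()) {
  stopifnot(inherits(curve, "decay_curve"))
  if (!e %in% 1:4) stop("e must be 1, 2, 3 or 4")
  if (length(curve$te) < 2 * e) stop("need at least 2e echoes")
  if (is.null(bounds))
    bounds <- default_bounds(e, max(curve$y[1], 1e-12), te1 = curve$te[1])
  stopifnot(inherits(bounds, "component_bounds"))
  if (bounds$e != e) stop("bounds are for a different number of components")
  config <- resolve_budget(config, e)
  fitness <- make_swarm_objective(curve, e, bounds)
  res <- with_seed(config$seed, run_acs_cipso(fitness, bounds, config))
  theta <- vec_to_theta(res$gbest)
  m <- fit_metrics(curve, theta)
  structure(list(
    theta = theta, cls = res$gfit, r2 = m$r2, rmse = m$rmse,
    excluded = integer(0), n_iter = res$n_iter, converged = res$converged,
    history = res$history
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> e = %d, criterion = %.4g, R2 = %.4f, RMSE = %.4g, %d iterations%s\n",
              x$theta$e, x$cls, x$r2, x$rmse, x$n_iter,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  print(round(x$theta$components, 4))
  invisible(x)
}

# Resolve the NULL (auto) iteration budget to the per-component default.
resolve_budget <- function(config, e) {
  if (is.null(config$max_iter))
    config$max_iter <- switch(config$preset, default = 500L, fast = 150L) * e
  if (is.null(config$stall_iter))
    config$stall_iter <- switch(config$preset,
                                default = 50L + 50L * e, fast = 30L + 10L * e)
  config
}

# Core loop, runs under the caller-managed RNG state.
run_acs_cipso <- function(fitness, bounds, config) {
  d <- length(bounds$lo)
  n <- config$n_particles
  lo <- bounds$lo; hi <- bounds$hi
  X <- matrix(runif(n * d), n, d) * rep(hi - lo, each = n) + rep(lo, each = n)
  V <- matrix(0, n, d)
  fit <- fitness(X)
  P <- X; pfit <- fit
  gi <- which.min(pfit)
  gbest <- P[gi, ]; gfit <- pfit[gi]
  r1 <- runif(1); r2 <- runif(1); r_chaos <- runif(1)
  stall_ref <- gfit; stall_count <- 0L
  converged <- FALSE
  iter <- 0L
  swarm <- list(X = X, V = V, P = P, fit = fit, pfit = pfit)
  hist_gfit <- if (isTRUE(config$trace)) numeric(config$max_iter) else NULL
  hist_lo <- if (isTRUE(config$trace)) vector("list", config$max_iter) else NULL
  hist_hi <- hist_lo
  hist_in_bounds <- if (isTRUE(config$trace)) logical(config$max_iter) else NULL
  while (iter < config$max_iter) {
    iter <- iter + 1L
    w <- config$w_max - (config$w_max - config$w_min) * iter / config$max_iter
    # velocity/position update (vectorized across the swarm)
    swarm$V <- w * swarm$V +
      config$c1 * r1 * (swarm$P - swarm$X) +
      config$c2 * r2 * (rep(gbest, each = n) - swarm$X)
    Xn <- swarm$X + swarm$V
    lo_m <- rep(bounds$lo, each = n); hi_m <- rep(bounds$hi, each = n)
    clipped <- Xn < lo_m | Xn > hi_m
    Xn[Xn < lo_m] <- lo_m[Xn < lo_m]
    Xn[Xn > hi_m] <- hi_m[Xn > hi_m]
    swarm$V[clipped] <- 0
    swarm$X <- Xn
    swarm$fit <- fitness(swarm$X)
    improved <- swarm$fit < swarm$pfit
    swarm$P[improved, ] <- swarm$X[improved, , drop = FALSE]
    swarm$pfit[improved] <- swarm$fit[improved]
    # immune clone / crossover / mutation with elitist selection
    swarm <- immune_operators(swarm, bounds, config, fitness, r_chaos)
    r_chaos <- swarm$r_chaos
    gi <- which.min(swarm$pfit)
    if (swarm$pfit[gi] < gfit) {
      gfit <- swarm$pfit[gi]
      gbest <- swarm$P[gi, ]
    }
    # chaotic evolution of the stochastic coefficients
    r1 <- chaos_step(r1); r2 <- chaos_step(r2)
    # adaptive component-interval compression around the incumbent
    if (config$adapt_every > 0 && iter %% config$adapt_every == 0) {
      bounds <- adapt_bounds(bounds, gbest)
      lo_m <- rep(bounds$lo, each = n); hi_m <- rep(bounds$hi, each = n)
      resc <- swarm$X < lo_m | swarm$X > hi_m
      if (any(resc)) {
        swarm$X[swarm$X < lo_m] <- lo_m[swarm$X < lo_m]
        swarm$X[swarm$X > hi_m] <- hi_m[swarm$X > hi_m]
        swarm$V[resc] <- 0
        swarm$fit <- fitness(swarm$X)
      }
      pr <- swarm$P < lo_m | swarm$P > hi_m
      if (any(pr)) {
        swarm$P[swarm$P < lo_m] <- lo_m[swarm$P < lo_m]
        swarm$P[swarm$P > hi_m] <- hi_m[swarm$P > hi_m]
        swarm$pfit <- fitness(swarm$P)
      }
    }
    if (isTRUE(config$trace)) {
      hist_gfit[iter] <- gfit
      hist_lo[[iter]] <- bounds$lo
      hist_hi[[iter]] <- bounds$hi
      hist_in_bounds[iter] <-
        all(swarm$X >= rep(bounds$lo, each = n) - 1e-12) &&
        all(swarm$X <= rep(bounds$hi, each = n) + 1e-12)
    }
    if (gfit <= config$tol) { converged <- TRUE; break }
    if (gfit < stall_ref * (1 - config$stall_tol)) {
      stall_ref <- gfit; stall_count <- 0L
    } else {
      stall_count <- stall_count + 1L
      if (stall_count >= config$stall_iter) { converged <- TRUE; break }
    }
  }
  history <- if (isTRUE(config$trace)) {
    list(gfit = hist_gfit[seq_len(iter)],
         lo = hist_lo[seq_len(iter)], hi = hist_hi[seq_len(iter)],
         in_bounds = hist_in_bounds[seq_len(iter)])
  } else NULL
  list(gbest = gbest, gfit = gfit, n_iter = iter, converged = converged,
       history = history)
}
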