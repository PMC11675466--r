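# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: plain loops, closed forms, or
# third-party fitters.

# Term-by-term multi-exponential decay, one scalar at a time.
oracle_decay <- function(components, te) {
  out <- numeric(length(te))
  for (k in seq_along(te)) {
    s <- 0
    for (comp in components) s <- s + comp[1] * exp(-te[k] / comp[2])
    out[k] <- s
  }
  out
}

# Mono-exponential recovery by linear regression on log-signal.
oracle_loglinear <- function(te, y) {
  fit <- stats::lm(log(y) ~ te)
  t2 <- -1 / stats::coef(fit)[[2]]
  a <- exp(stats::coef(fit)[[1]])
  c(A = a, T2 = t2)
}

# Kernel-weighted patch distance by naive triple loop (1-based indexing,
# borders clipped for both patches, kernel renormalized).
oracle_patch_distance <- function(arr, i, j, te, prs, pre, a1, a2) {
  d <- dim(arr)
  num <- 0; den <- 0
  for (dz in -pre:pre) {
    tz <- te + dz
    if (tz < 1 || tz > d[3]) next
    for (dy in -prs:prs) {
      for (dx in -prs:prs) {
        x1 <- i[1] + dx; y1 <- i[2] + dy
        x2 <- j[1] + dx; y2 <- j[2] + dy
        if (x1 < 1 || x1 > d[1] || x2 < 1 || x2 > d[1]) next
        if (y1 < 1 || y1 > d[2] || y2 < 1 || y2 > d[2]) next
        k <- exp(-dz^2 / (2 * a1^2)) * exp(-(dx^2 + dy^2) / (2 * a2^2))
        num <- num + k * (arr[x1, y1, tz] - arr[x2, y2, tz])^2
        den <- den + k
      }
    }
  }
  if (den > 0) num / den else 0
}

# Full non-local-means reference built from per-voxel weight fields.
oracle_nlmeans3d <- function(stack, config) {
  d <- dim(stack$data)
  out <- array(0, d)
  for (te in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        w <- nlm_weights(stack, c(i, j), te, config)
        vals <- mapply(function(r, c) stack$data[r, c, te], w$row, w$col)
        out[i, j, te] <- sum(w$weight * vals)
      }
    }
  }
  out
}

# Small deterministic random stack for denoiser tests.
make_random_stack <- function(rows = 5, cols = 5, ne = 3, seed = 99) {
  set.seed(seed)
  mese_stack(array(runif(rows * cols * ne, 0, 100), c(rows, cols, ne)),
             te_grid = 30 * seq_len(ne))
}

# Noiseless ring phantom fixture at reduced size.
make_small_phantom <- function(shape = c(48, 48), n_echo = 45, ...) {
  generate_phantom(phantom_rings(shape, ...),
                   acquisition_params(te_grid = mese_te_grid(n_echo)))
}
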