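# Forward simulation of MESE acquisitions: decay model, ring phantom,
# Rician noise injection, per-echo SNR estimation.

#' MESE acquisition parameters
#'
#' Bundle of the pulse-sequence timing parameters that define a multi-echo
#' spin-echo acquisition: repetition time, the echo-time grid, and the
#' echo-train length.
#'
#' With a long repetition time (TR much larger than T1) the longitudinal
#' magnetization recovers almost fully between excitations, so the signal at
#' each echo is proportional to proton density times `exp(-TE/T2)`; the
#' T1-recovery factor `1 - exp(-TR/T1)` is within 2% of unity for
#' T1 <= 1000 ms at TR = 4000 ms (see [long_tr_factor()]).
#'
#' @param tr Repetition time in ms. Default 4000 (long-TR regime).
#' @param te_grid Strictly increasing echo times in ms. Default
#'   `mese_te_grid(61)`: 30, 60, ..., 1830 ms.
#' @param t1 Optional longitudinal relaxation time in ms, only used to check
#'   the long-TR approximation.
#' @return An object of class `acquisition_params`.
#' @examples
#' acquisition_params()                    # tomato protocol: 61 echoes
#' acquisition_params(te_grid = mese_te_grid(45))  # phantom protocol
#' @export
acquisition_params <- function(tr = 4000, te_grid = mese_te_grid(61), t1 = NULL) {
  te_grid <- as.numeric(te_grid)
  if (length(te_grid) == 0 || any(te_grid <= 0))
    stop("te_grid must be nonempty and positive")
  if (any(diff(te_grid) <= 0))
    stop("te_grid must be strictly increasing")
  if (tr <= max(te_grid))
    stop("tr must exceed the last echo time")
  structure(
    list(tr = tr, te_grid = te_grid, etl = length(te_grid), t1 = t1),
    class = "acquisition_params"
  )
}

#' Regular echo-time grid
#'
#' Echo times `30, 60, ..., n_echo * 30` ms, the uniform 30 ms echo spacing
#' of the MESE protocol.
#'
#' @param n_echo Number of echoes (echo-train length).
#' @param delta_te Echo spacing in ms (default 30).
#' @return Numeric vector of echo times in ms.
#' @export
mese_te_grid <- function(n_echo = 61, delta_te = 30) {
  if (n_echo < 1) stop("n_echo must be >= 1")
  delta_te * seq_len(n_echo)
}

#' T1-recovery factor for the long-TR approximation
#'
#' Computes `1 - exp(-TR/T1)`, the factor by which incomplete longitudinal
#' recovery attenuates the signal. When it is close to 1 the acquisition is
#' effectively proton-density times T2-decay weighted.
#'
#' @param tr Repetition time (ms).
#' @param t1 Longitudinal relaxation time (ms).
#' @return The recovery factor in (0, 1).
#' @export
long_tr_factor <- function(tr, t1) {
  if (tr <= 0 || t1 <= 0) stop("tr and t1 must be positive")
  1 - exp(-tr / t1)
}

#' Multi-exponential T2 decay signal
#'
#' Evaluates `S(t) = sum_e A_e * exp(-t / T2_e)` at each echo time: the
#' noiseless multi-exponential transverse-relaxation decay of a voxel whose
#' water populations have amplitudes `A_e` and relaxation times `T2_e`.
#'
#' @param components Components as a 2-column matrix `cbind(A, T2)`, a list of
#'   `c(A, T2)` pairs, or an [exp_params] object. Amplitudes are in signal
#'   units, T2 in ms.
#' @param te_grid Echo times (ms) at which to evaluate the decay.
#' @return Numeric vector of signal values, one per echo.
#' @examples
#' simulate_decay(cbind(250, 80), 30)  # 250 * exp(-30/80)
#' simulate_decay(list(c(250, 80), c(250, 200), c(250, 600)), mese_te_grid(61))
#' @export
simulate_decay <- function(components, te_grid) {
  comp <- as_component_matrix(components)
  te_grid <- as.numeric(te_grid)
  if (length(te_grid) == 0) stop("te_grid must be nonempty")
  if (any(comp[, 2L] <= 0)) stop("all T2 values must be positive")
  if (any(comp[, 1L] < 0)) stop("amplitudes must be nonnegative")
  # n_echo x e matrix of per-component decays, summed across components
  as.vector(exp(-outer(te_grid, 1 / comp[, 2L])) %*% comp[, 1L])
}

# Coerce the accepted component representations to a 2-column (A, T2) matrix.
as_component_matrix <- function(components) {
  if (inherits(components, "exp_params")) {
    comp <- components$components
  } else if (is.list(components)) {
    comp <- do.call(rbind, lapply(components, function(p) {
      if (length(p) != 2) stop("each component must be a pair (A, T2)")
      as.numeric(p)
    }))
  } else if (is.matrix(components)) {
    comp <- components
  } else if (is.numeric(components) && length(components) == 2) {
    comp <- matrix(components, 1L, 2L)
  } else {
    stop("components must be a matrix, list of pairs, or exp_params")
  }
  if (ncol(comp) != 2) stop("components must have two columns (A, T2)")
  storage.mode(comp) <- "double"
  colnames(comp) <- c("A", "T2")
  comp
}

#' Phantom specification
#'
#' Describes a simulated object as labelled regions, each carrying the
#' multi-exponential decay components of its tissue. Geometry descriptors are
#' functions mapping a (rows x cols) grid to a logical membership mask, so
#' arbitrary disjoint layouts are possible; [phantom_rings()] and
#' [phantom_tomato()] build the stock layouts.
#'
#' @param shape Integer `(rows, cols)`.
#' @param regions List of regions, each a list with elements `label` (positive
#'   integer, unique), `geometry` (`function(rows, cols) -> logical matrix`),
#'   and `components` (see [simulate_decay()]).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, regions) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 1)) stop("shape must be (rows, cols)")
  labels <- vapply(regions, function(r) as.integer(r$label), integer(1))
  if (any(labels <= 0)) stop("region labels must be positive")
  if (anyDuplicated(labels)) stop("region labels must be unique")
  for (r in regions) {
    comp <- as_component_matrix(r$components)
    if (any(comp[, 2L] <= 0) || any(comp[, 1L] < 0))
      stop("region components must have A >= 0 and T2 > 0")
  }
  structure(list(shape = shape, regions = regions), class = "phantom_spec")
}

# Membership masks for n concentric annuli spanning outer_frac of the
# half-width, centred in the grid. Equal radial thickness by default;
# equal_area = TRUE instead places radii at r_max * sqrt(k/n) so all rings
# cover the same number of voxels (making the foreground mean an
# equal-amplitude mixture).
ring_masks <- function(rows, cols, n_rings = 3, outer_frac = 0.8,
                       equal_area = FALSE) {
  r_max <- outer_frac * min(rows, cols) / 2
  cy <- (rows + 1) / 2
  cx <- (cols + 1) / 2
  rr <- sqrt(outer(seq_len(rows) - cy, rep(1, cols))^2 +
             outer(rep(1, rows), seq_len(cols) - cx)^2)
  radius <- function(k) {
    if (equal_area) r_max * sqrt(k / n_rings) else k * r_max / n_rings
  }
  lapply(seq_len(n_rings), function(k) {
    rr > radius(k - 1) & rr <= radius(k)
  })
}

#' Three-ring simulation phantom
#'
#' The stock simulation phantom: three concentric rings (inner disk, middle
#' and outer annulus) on a 256 x 256 grid, all with amplitude 250 and
#' mono-exponential T2 of 80, 200 and 600 ms from inner to outer, zero
#' background.
#'
#' @param shape Grid shape, default `c(256, 256)`.
#' @param amplitudes Per-ring amplitude, inner to outer.
#' @param t2 Per-ring T2 (ms), inner to outer.
#' @param outer_frac Fraction of the half-width spanned by the rings.
#' @param equal_area Use equal-area rings (radii at `r_max * sqrt(k/n)`)
#'   instead of equal radial thickness, so the foreground mean is an
#'   equal-amplitude mixture of the ring decays.
#' @return A `phantom_spec` with ring labels 1 (inner) to 3 (outer).
#' @export
phantom_rings <- function(shape = c(256, 256), amplitudes = c(250, 250, 250),
                          t2 = c(80, 200, 600), outer_frac = 0.8,
                          equal_area = FALSE) {
  n <- length(t2)
  if (length(amplitudes) != n) stop("amplitudes and t2 must have equal length")
  regions <- lapply(seq_len(n), function(k) {
    list(
      label = k,
      geometry = local({
        kk <- k
        function(rows, cols)
          ring_masks(rows, cols, n, outer_frac, equal_area)[[kk]]
      }),
      components = cbind(amplitudes[k], t2[k])
    )
  })
  phantom_spec(shape, regions)
}

#' Six-structure tomato-like template phantom
#'
#' A geometric stand-in for the transverse section of a cherry tomato with
#' six labelled structures: 1 exocarp (outer skin annulus), 2 endocarp
#' (pericarp annulus), 3 partition (radial septa), 4 ovary tissue (locule
#' regions), 5 seeds (small disks inside the locules), 6 placenta (central
#' core). Each structure carries a tri-exponential component mix with bound,
#' semi-bound and free water T2s in physiologically plausible ranges. The
#' geometry is synthetic; it emulates the topology of a segmented fruit
#' section, not any particular scan.
#'
#' @param shape Grid shape, default `c(256, 256)`.
#' @return A `phantom_spec` with labels 1-6 and a `names` attribute mapping
#'   labels to structure names.
#' @export
phantom_tomato <- function(shape = c(256, 256)) {
  geom <- function(fun) fun  # readability
  base_masks <- function(rows, cols) {
    r_out <- 0.45 * min(rows, cols)
    cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
    y <- outer(seq_len(rows) - cy, rep(1, cols))
    x <- outer(rep(1, rows), seq_len(cols) - cx)
    rr <- sqrt(y^2 + x^2)
    th <- atan2(y, x)
    septa <- (abs(sin(1.5 * th))^0.2 < 0.55)  # three radial septa
    seeds <- matrix(FALSE, rows, cols)
    for (ang in c(0.6, 2.7, 4.8)) {
      sy <- cy + 0.55 * r_out * sin(ang)
      sx <- cx + 0.55 * r_out * cos(ang)
      seeds <- seeds |
        (sqrt(outer(seq_len(rows) - sy, rep(1, cols))^2 +
              outer(rep(1, rows), seq_len(cols) - sx)^2) < 0.06 * min(rows, cols))
    }
    list(
      exocarp   = rr <= r_out & rr > 0.93 * r_out,
      endocarp  = rr <= 0.93 * r_out & rr > 0.72 * r_out,
      partition = rr <= 0.72 * r_out & rr > 0.22 * r_out & septa & !seeds,
      ovary     = rr <= 0.72 * r_out & rr > 0.22 * r_out & !septa & !seeds,
      seeds     = seeds & rr <= 0.72 * r_out,
      placenta  = rr <= 0.22 * r_out
    )
  }
  mk <- function(name) {
    force(name)
    function(rows, cols) base_masks(rows, cols)[[name]]
  }
  comps <- list(
    exocarp   = rbind(c(40, 30),  c(90, 150),  c(120, 450)),
    endocarp  = rbind(c(35, 40),  c(95, 180),  c(140, 550)),
    partition = rbind(c(30, 35),  c(80, 160),  c(130, 500)),
    ovary     = rbind(c(25, 45),  c(70, 200),  c(160, 650)),
    seeds     = rbind(c(60, 25),  c(90, 120),  c(80, 350)),
    placenta  = rbind(c(35, 40),  c(85, 170),  c(130, 520))
  )
  nm <- names(comps)
  regions <- lapply(seq_along(nm), function(k) {
    list(label = k, geometry = geom(mk(nm[k])), components = comps[[nm[k]]])
  })
  sp <- phantom_spec(shape, regions)
  attr(sp, "names_table") <- stats::setNames(seq_along(nm), nm)
  sp
}

#' Multi-echo stack container
#'
#' Wraps a `rows x cols x n_echo` array of nonnegative magnitude images with
#' its echo-time grid and (optionally) the channel-noise standard deviation.
#'
#' @param data 3D numeric array, `rows x cols x n_echo`, nonnegative.
#' @param te_grid Echo times (ms), one per slice of the third dimension.
#' @param sigma Optional channel-noise standard deviation in signal units
#'   (the Gaussian sigma of each quadrature channel, not of the magnitude).
#' @return An object of class `mese_stack`.
#' @export
mese_stack <- function(data, te_grid, sigma = NULL) {
  if (length(dim(data)) != 3) stop("data must be a rows x cols x n_echo array")
  if (dim(data)[3] != length(te_grid))
    stop("third dimension must match length(te_grid)")
  if (any(data < 0)) stop("magnitude data must be nonnegative")
  if (any(diff(te_grid) <= 0)) stop("te_grid must be strictly increasing")
  structure(list(data = data, te_grid = as.numeric(te_grid), sigma = sigma),
            class = "mese_stack")
}

#' @export
print.mese_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mese_stack> %d x %d x %d echoes, TE %g..%g ms%s\n",
              d[1], d[2], d[3], min(x$te_grid), max(x$te_grid),
              if (!is.null(x$sigma)) sprintf(", sigma = %g", x$sigma) else ""))
  invisible(x)
}

#' Generate a noiseless multi-echo phantom stack
#'
#' Rasterizes a [phantom_spec] onto the acquisition grid: every voxel of a
#' region carries that region's noiseless multi-exponential decay evaluated
#' at the echo times; background voxels are zero at all echoes. Deterministic.
#'
#' @param spec A `phantom_spec`.
#' @param params An [acquisition_params] supplying the echo grid.
#' @return A list with elements `stack` (a [mese_stack]) and `labels` (an
#'   integer label matrix, 0 = background).
#' @examples
#' ph <- generate_phantom(phantom_rings(c(64, 64)),
#'                        acquisition_params(te_grid = mese_te_grid(45)))
#' dim(ph$stack$data)
#' @export
generate_phantom <- function(spec, params = acquisition_params()) {
  stopifnot(inherits(spec, "phantom_spec"))
  rows <- spec$shape[1]; cols <- spec$shape[2]
  te <- params$te_grid
  labels <- matrix(0L, rows, cols)
  stack <- array(0, dim = c(rows, cols, length(te)))
  for (r in spec$regions) {
    mask <- r$geometry(rows, cols)
    if (!is.matrix(mask) || !identical(dim(mask), c(rows, cols)))
      stop("geometry must return a rows x cols logical matrix")
    if (any(labels[mask] != 0L))
      stop("phantom regions overlap: geometries must be pairwise disjoint")
    labels[mask] <- as.integer(r$label)
    sig <- simulate_decay(r$components, te)
    idx <- which(mask)
    for (k in seq_along(te)) {
      slice <- stack[, , k]
      slice[idx] <- sig[k]
      stack[, , k] <- slice
    }
  }
  nt <- attr(spec, "names_table")
  lab <- labels
  if (!is.null(nt)) attr(lab, "names_table") <- nt
  list(stack = mese_stack(stack, te), labels = lab)
}

#' Inject Rician noise into a magnitude stack
#'
#' Treats each input magnitude value S as the real-channel signal, adds
#' independent zero-mean Gaussian noise of standard deviation `sigma` to the
#' real and imaginary channels, and reconstructs the magnitude:
#' `sqrt((S + n1)^2 + n2^2)`. In signal-free background this yields
#' Rayleigh-distributed intensities with mean `sigma * sqrt(pi/2)`; at high
#' SNR the magnitude is approximately Gaussian around S. Noise is white
#' across voxels and echoes.
#'
#' @param stack A [mese_stack].
#' @param sigma Channel-noise standard deviation, >= 0.
#' @param seed Integer seed for reproducibility.
#' @return A new [mese_stack] with noisy data and `sigma` recorded.
#' @export
add_rician_noise <- function(stack, sigma, seed = 1L) {
  stopifnot(inherits(stack, "mese_stack"))
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(mese_stack(stack$data, stack$te_grid, sigma = 0))
  n <- length(stack$data)
  noisy <- with_seed(seed, {
    n1 <- rnorm(n, 0, sigma)
    n2 <- rnorm(n, 0, sigma)
    sqrt((as.vector(stack$data) + n1)^2 + n2^2)
  })
  out <- array(noisy, dim = dim(stack$data))
  mese_stack(out, stack$te_grid, sigma = sigma)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Per-echo signal and noise power estimation
#'
#' For each echo layer, estimates the signal power as the mean squared
#' intensity over the signal mask, and the channel-noise variance from the
#' background magnitude statistics with the Rayleigh correction
#' `sigma_hat^2 = mean(background^2) / 2` (in signal-free background the
#' squared magnitude has expectation `2 sigma^2`). SNR is the ratio of signal
#' power to the noise power `sigma_hat^2`.
#'
#' @param stack A [mese_stack].
#' @param signal_mask,background_mask Disjoint, nonempty logical matrices of
#'   the stack's spatial shape.
#' @return A data.frame with one row per echo: `te`, `signal_power`,
#'   `noise_power`, `sigma_hat`, `snr`.
#' @export
estimate_layer_snr <- function(stack, signal_mask, background_mask) {
  stopifnot(inherits(stack, "mese_stack"))
  d <- dim(stack$data)
  for (m in list(signal_mask, background_mask)) {
    if (!identical(dim(m), d[1:2])) stop("mask shape must match the stack")
  }
  if (!any(signal_mask) || !any(background_mask)) stop("masks must be nonempty")
  if (any(signal_mask & background_mask)) stop("masks must be disjoint")
  sig_p <- noise_p <- numeric(d[3])
  for (k in seq_len(d[3])) {
    layer <- stack$data[, , k]
    sig_p[k] <- mean(layer[signal_mask]^2)
    noise_p[k] <- mean(layer[background_mask]^2) / 2  # sigma^2 under Rayleigh
  }
  data.frame(
    te = stack$te_grid,
    signal_power = sig_p,
    noise_power = noise_p,
    sigma_hat = sqrt(noise_p),
    snr = ifelse(noise_p > 0, sig_p / noise_p, Inf)
  )
}
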