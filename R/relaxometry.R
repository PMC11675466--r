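# Decay-curve containers, the least-squares criterion, echo exclusion,
# goodness-of-fit metrics, and water-state component classification.

#' Decay curve
#'
#' One (TE, signal) series, the unit of inversion: the measured magnitude of
#' a voxel (or a region mean) at each echo time, with an optional noise scale
#' sigma used to weight the least-squares criterion.
#'
#' @param te Echo times (ms), strictly increasing.
#' @param y Measured signal per echo, same length as `te`.
#' @param sigma Noise scale in signal units: either one value per curve or
#'   one per echo (a heteroscedastic weight vector). Default 1, reducing
#'   the weighted criterion to ordinary least squares.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(te, y, sigma = 1) {
  te <- as.numeric(te); y <- as.numeric(y)
  if (length(te) != length(y)) stop("te and y must have equal length")
  if (length(te) == 0) stop("curve must be nonempty")
  if (any(diff(te) <= 0)) stop("te must be strictly increasing")
  if (!is.numeric(sigma) || !length(sigma) %in% c(1L, length(te)) ||
      any(sigma <= 0))
    stop("sigma must be positive, of length 1 or one per echo")
  structure(list(te = te, y = y, sigma = sigma), class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %d echoes, TE %g..%g ms, y[1] = %g, sigma = %s\n",
              length(x$te), min(x$te), max(x$te), x$y[1],
              if (length(x$sigma) == 1) format(x$sigma)
              else sprintf("per-echo (%.3g..%.3g)", min(x$sigma), max(x$sigma))))
  invisible(x)
}

#' Exponential-model parameters
#'
#' An ordered set of exponential components `(A_e, T2_e)`. Components are
#' stored sorted ascending by T2 so that for the tri-exponential model the
#' conventional water-state labels apply: T21 (bound) <= T22 (semi-bound)
#' <= T23 (free), with amplitudes A01, A02, A03.
#'
#' @param components See [simulate_decay()] for accepted forms; between 1 and
#'   4 components.
#' @return An object of class `exp_params` with a `components` matrix sorted
#'   ascending by T2.
#' @export
exp_params <- function(components) {
  comp <- as_component_matrix(components)
  e <- nrow(comp)
  if (e < 1 || e > 4) stop("between 1 and 4 components are supported")
  if (any(comp[, "A"] < 0)) stop("amplitudes must be nonnegative")
  if (any(comp[, "T2"] <= 0)) stop("T2 values must be positive")
  comp <- comp[order(comp[, "T2"]), , drop = FALSE]
  structure(list(components = comp, e = e), class = "exp_params")
}

#' @export
print.exp_params <- function(x, ...) {
  cat(sprintf("<exp_params> e = %d\n", x$e))
  print(round(x$components, 4))
  invisible(x)
}

# Flatten exp_params to the optimizer's vector layout (A1, T21, A2, T22, ...)
# and back.
theta_to_vec <- function(theta) as.vector(t(theta$components))
vec_to_theta <- function(v) {
  exp_params(matrix(v, ncol = 2, byrow = TRUE))
}

#' Weighted least-squares criterion
#'
#' The quadratic inversion criterion
#' `C = 1/(2 sigma^2) * sum_t (y_t - S(theta, t))^2`, where `S` is the
#' multi-exponential decay model evaluated at the curve's echo times. With
#' sigma = 1 this is half the residual sum of squares; a per-echo sigma
#' vector turns it into heteroscedasticity-weighted least squares,
#' `C = sum_t (y_t - S_t)^2 / (2 sigma_t^2)`.
#'
#' @param theta An [exp_params] (or anything [simulate_decay()] accepts).
#' @param curve A [decay_curve].
#' @return Nonnegative scalar criterion value.
#' @export
objective_cls <- function(theta, curve) {
  stopifnot(inherits(curve, "decay_curve"))
  s <- simulate_decay(theta, curve$te)
  sum((curve$y - s)^2 / (2 * curve$sigma^2))
}

#' Goodness-of-fit metrics on first-echo-normalized signals
#'
#' Computes the coefficient of determination R^2 and the root-mean-square
#' error of a fitted decay model against a measured curve. Both the measured
#' and fitted signals are normalized by the measured first-echo value before
#' metric computation, so RMSE is on a ~0-1 scale comparable across regions
#' of different absolute intensity; R^2 is invariant to this scaling.
#'
#' @param curve A [decay_curve].
#' @param theta Fitted [exp_params].
#' @return List with `r2` and `rmse`. For a constant measured signal
#'   (zero total sum of squares) `r2` is `NA` (undefined).
#' @export
fit_metrics <- function(curve, theta) {
  stopifnot(inherits(curve, "decay_curve"))
  scale <- curve$y[1]
  if (scale == 0) scale <- 1
  y <- curve$y / scale
  s <- simulate_decay(theta, curve$te) / scale
  ss_res <- sum((y - s)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    rmse = sqrt(mean((y - s)^2))
  )
}

#' Echo-exclusion preprocessing
#'
#' Removes anomalous echoes (spikes from interference, motion or
#' reconstruction artefacts) before the final fit. A provisional model is
#' fitted, residuals are standardized by a robust scale (the median absolute
#' deviation), and echoes whose standardized residual magnitude exceeds
#' `threshold_k` are dropped — never more than 20% of the echoes, and never
#' so many that fewer than `2e + 2` echoes remain. The model is then refit
#' on the reduced curve by the caller.
#'
#' @param curve A [decay_curve].
#' @param e Number of exponential components of the provisional model.
#' @param threshold_k Outlier threshold in robust standard deviations
#'   (default 3).
#' @param fit_fn Function `(curve, e) -> exp_params` producing the
#'   provisional fit; default is a reduced-budget swarm inversion.
#' @param max_frac Maximum fraction of echoes that may be removed (0.2).
#' @return List with `curve` (reduced [decay_curve]), `excluded` (integer
#'   indices into the original curve, possibly empty), and `refused` (TRUE
#'   when exclusion would leave too few echoes and the curve is returned
#'   unchanged).
#' @export
exclude_echoes <- function(curve, e = 1, threshold_k = 3,
                           fit_fn = NULL, max_frac = 0.2) {
  stopifnot(inherits(curve, "decay_curve"))
  n <- length(curve$te)
  if (n < 2 * e + 2) stop("curve too short for the requested model order")
  if (is.null(fit_fn)) {
    fit_fn <- function(curve, e) {
      invert_decay(curve, e = e,
                   config = optimizer_config(preset = "fast", seed = 1L))$theta
    }
  }
  theta0 <- fit_fn(curve, e)
  # residuals standardized by the per-echo noise scale (no-op when scalar 1)
  sig <- rep(curve$sigma, length.out = n)
  res <- (curve$y - simulate_decay(theta0, curve$te)) / sig
  z0 <- abs(res - median(res)) / max(mad(res, center = median(res)), 1e-300)
  if (max(z0) > threshold_k && n - 1 >= 2 * e + 2) {
    # one-step robustification: a gross outlier skews the provisional fit
    # and can push clean echoes over the threshold, so refit the
    # provisional model without the single worst echo before flagging
    drop1 <- which.max(z0)
    keep1 <- setdiff(seq_len(n), drop1)
    sig1 <- if (length(curve$sigma) > 1) curve$sigma[keep1] else curve$sigma
    theta0 <- fit_fn(decay_curve(curve$te[keep1], curve$y[keep1], sig1), e)
    res <- (curve$y - simulate_decay(theta0, curve$te)) / sig
  }
  scale <- mad(res, center = median(res))
  if (scale <= 0) scale <- sd(res)
  if (!is.finite(scale) || scale <= 0)
    return(list(curve = curve, excluded = integer(0), refused = FALSE))
  z <- abs(res - median(res)) / scale
  bad <- which(z > threshold_k)
  if (length(bad) == 0)
    return(list(curve = curve, excluded = integer(0), refused = FALSE))
  # keep at most 20% of echoes removable, worst offenders first
  cap <- floor(max_frac * n)
  if (length(bad) > cap) bad <- bad[order(z[bad], decreasing = TRUE)][seq_len(cap)]
  bad <- sort(bad)
  if (n - length(bad) < 2 * e + 2) {
    warning("echo exclusion would leave too few echoes; curve unchanged")
    return(list(curve = curve, excluded = integer(0), refused = TRUE))
  }
  keep <- setdiff(seq_len(n), bad)
  sig <- if (length(curve$sigma) > 1) curve$sigma[keep] else curve$sigma
  list(
    curve = decay_curve(curve$te[keep], curve$y[keep], sig),
    excluded = bad,
    refused = FALSE
  )
}

#' Rician bias correction of a magnitude decay curve
#'
#' Approximately removes the magnitude (Rician) noise floor from a single
#' voxel curve by the moment relation `E[v^2] ~ S^2 + 2 sigma^2`:
#' `y_corrected = sqrt(max(y^2 - 2 sigma^2, 0))`. For region-mean curves
#' prefer the exact second-moment correction built into
#' [extract_region_curves()].
#'
#' @param curve A [decay_curve].
#' @param sigma Channel-noise standard deviation.
#' @return The corrected [decay_curve].
#' @export
correct_rician_bias <- function(curve, sigma) {
  stopifnot(inherits(curve, "decay_curve"))
  if (sigma < 0) stop("sigma must be nonnegative")
  decay_curve(curve$te, sqrt(pmax(curve$y^2 - 2 * sigma^2, 0)),
              sigma = curve$sigma)
}

#' Water-state classification of fitted components
#'
#' Sorts fitted components ascending by T2 and labels them with the standard
#' water-state names: for a tri-exponential fit, T21/A01 = bound water
#' (shortest T2), T22/A02 = semi-bound water, T23/A03 = free water (longest
#' T2). Proportions are amplitudes normalized to sum to 1, i.e. the relative
#' content of each water state.
#'
#' @param theta An [exp_params].
#' @return A data.frame with columns `label` (`"T21"`, ...), `t2`, `A`,
#'   `proportion`.
#' @export
classify_components <- function(theta) {
  if (!inherits(theta, "exp_params")) theta <- exp_params(theta)
  comp <- theta$components  # already ascending by T2
  total <- sum(comp[, "A"])
  if (total == 0) stop("all amplitudes are zero; proportions undefined")
  data.frame(
    label = paste0("T2", seq_len(theta$e)),
    t2 = comp[, "T2"],
    A = comp[, "A"],
    proportion = comp[, "A"] / total,
    row.names = NULL
  )
}
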