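# Non-local-means denoising: layer-wise 2D baseline and the 3D variant that
# compares patches across the echo dimension with an echo-dependent
# bandwidth.

#' Non-local-means configuration
#'
#' Patch and search geometry plus the kernel and bandwidth parameters of the
#' non-local-means denoisers. Patch distances are Gaussian-kernel-weighted
#' mean squared differences between patches; `a2` is the kernel standard
#' deviation over the two spatial offsets and `a1` over the echo offset, so
#' nearby voxels within a patch count more than distant ones. `h_schedule`
#' is the per-echo smoothing bandwidth; because noise power grows relative
#' to signal along the echo train, it must be non-decreasing (see
#' [h_schedule_from_noise()]).
#'
#' @param patch_radius_space Spatial patch radius in voxels (patch side
#'   `2r + 1`). Default 2.
#' @param patch_radius_echo Patch radius along the echo axis. Default 1.
#' @param search_radius_space Spatial search-window radius. Default 5.
#' @param a1 Gaussian kernel sd on the echo offset (echo units). Default 1.
#' @param a2 Gaussian kernel sd on spatial offsets (voxels). Default 2.
#' @param h_schedule Per-echo bandwidth vector, positive and non-decreasing;
#'   or a single value recycled to every echo.
#' @param noise_power_schedule Per-echo noise variance `sigma^2(te)` (or one
#'   value recycled). Twice this value — the expected patch distance between
#'   two noise realizations of identical structure — is subtracted from
#'   every patch distance before the exponential weighting, so
#'   same-structure candidates get weight ~1 and `h` purely controls edge
#'   tolerance. `NULL` derives it from the stack's recorded noise level.
#' @return An object of class `nlm_config`.
#' @export
nlm_config <- function(patch_radius_space = 2, patch_radius_echo = 1,
                       search_radius_space = 5, a1 = 1, a2 = 2,
                       h_schedule = NULL, noise_power_schedule = NULL) {
  if (patch_radius_space < 0 || patch_radius_echo < 0 || search_radius_space < 0)
    stop("radii must be nonnegative")
  if (a1 <= 0 || a2 <= 0) stop("a1 and a2 must be positive")
  if (!is.null(h_schedule)) {
    if (any(h_schedule <= 0)) stop("h_schedule must be positive")
    if (length(h_schedule) > 1 && any(diff(h_schedule) < 0))
      stop("h_schedule must be non-decreasing across echoes")
  }
  if (!is.null(noise_power_schedule) && any(noise_power_schedule < 0))
    stop("noise_power_schedule must be nonnegative")
  structure(list(
    patch_radius_space = as.integer(patch_radius_space),
    patch_radius_echo = as.integer(patch_radius_echo),
    search_radius_space = as.integer(search_radius_space),
    a1 = a1, a2 = a2, h_schedule = h_schedule,
    noise_power_schedule = noise_power_schedule
  ), class = "nlm_config")
}

# Fallback noise scale for a stack without a recorded sigma.
stack_sigma_guess <- function(stack) {
  sg <- stack$sigma
  if (is.null(sg) || sg <= 0)
    sg <- max(stats::mad(as.vector(stack$data)), 1e-6)
  sg
}

# Resolve the per-echo bandwidth vector for a stack.
resolve_h <- function(config, stack) {
  ne <- dim(stack$data)[3]
  h <- config$h_schedule
  if (is.null(h)) {
    h <- rep(stack_sigma_guess(stack), ne)
  } else if (length(h) == 1) {
    h <- rep(h, ne)
  } else if (length(h) != ne) {
    stop("h_schedule length must match the number of echoes")
  }
  h
}

# Resolve the per-echo noise-power (variance) vector used as the patch
# distance offset.
resolve_noise_power <- function(config, stack) {
  ne <- dim(stack$data)[3]
  np <- config$noise_power_schedule
  if (is.null(np)) {
    np <- rep(stack_sigma_guess(stack)^2, ne)
  } else if (length(np) == 1) {
    np <- rep(np, ne)
  } else if (length(np) != ne) {
    stop("noise_power_schedule length must match the number of echoes")
  }
  np
}

#' Gaussian-kernel-weighted patch distance
#'
#' The structural dissimilarity between the 3D patches centred at spatial
#' positions `i` and `j` of echo `te`: the kernel-weighted mean of squared
#' voxel differences over all patch offsets valid for both patches (patches
#' are clipped at image borders and the kernel renormalized). Echo offsets
#' are weighted by a Gaussian of sd `a1`, spatial offsets by sd `a2`.
#'
#' @param stack A [mese_stack].
#' @param i,j Integer `(row, col)` positions of the two patch centres.
#' @param te Echo index (1-based).
#' @param config An [nlm_config].
#' @return Nonnegative scalar; 0 for identical patches, symmetric in
#'   `i`, `j`.
#' @export
patch_distance <- function(stack, i, j, te, config = nlm_config()) {
  stopifnot(inherits(stack, "mese_stack"))
  d <- dim(stack$data)
  for (p in list(i, j)) {
    if (length(p) != 2 || any(p < 1) || p[1] > d[1] || p[2] > d[2])
      stop("patch centres must lie inside the image")
  }
  if (te < 1 || te > d[3]) stop("te out of range")
  prs <- config$patch_radius_space; pre <- config$patch_radius_echo
  num <- 0; den <- 0
  for (dz in -pre:pre) {
    tz <- te + dz
    if (tz < 1 || tz > d[3]) next
    kz <- exp(-dz^2 / (2 * config$a1^2))
    for (dy in -prs:prs) {
      y1 <- i[2] + dy; y2 <- j[2] + dy
      if (y1 < 1 || y1 > d[2] || y2 < 1 || y2 > d[2]) next
      for (dx in -prs:prs) {
        x1 <- i[1] + dx; x2 <- j[1] + dx
        if (x1 < 1 || x1 > d[1] || x2 < 1 || x2 > d[1]) next
        k <- kz * exp(-(dx^2 + dy^2) / (2 * config$a2^2))
        num <- num + k * (stack$data[x1, y1, tz] - stack$data[x2, y2, tz])^2
        den <- den + k
      }
    }
  }
  if (den > 0) num / den else 0
}

#' Normalized non-local-means weight field of one target voxel
#'
#' The weights
#' `w(i, j, te) = exp(-max(d(i, j, te) - 2 sigma^2(te), 0) / h(te)^2) /
#' z(i, te)` that the denoiser assigns to every candidate voxel `j` in the
#' spatial search window around target `i` at echo `te`, after
#' normalization by `z(i, te) = sum_j w`. The noise-power offset
#' `2 sigma^2` is the expected distance between two noise realizations of
#' the same structure, so identical structure scores weight ~1. The self
#' weight is set to the maximum candidate weight. Weights sum to 1; exposed
#' mainly for inspection and testing.
#'
#' @inheritParams patch_distance
#' @return A data.frame with columns `row`, `col`, `weight`.
#' @export
nlm_weights <- function(stack, i, te, config = nlm_config()) {
  d <- dim(stack$data)
  srs <- config$search_radius_space
  h <- resolve_h(config, stack)[te]
  off <- 2 * resolve_noise_power(config, stack)[te]
  rows <- max(1, i[1] - srs):min(d[1], i[1] + srs)
  cols <- max(1, i[2] - srs):min(d[2], i[2] + srs)
  grid <- expand.grid(row = rows, col = cols)
  self <- grid$row == i[1] & grid$col == i[2]
  w <- numeric(nrow(grid))
  for (k in which(!self)) {
    dist <- patch_distance(stack, i, c(grid$row[k], grid$col[k]), te, config)
    w[k] <- exp(-max(dist - off, 0) / h^2)
  }
  w[self] <- if (any(!self)) max(w[!self]) else 1
  grid$weight <- w / sum(w)
  grid
}

#' Layer-wise 2D non-local means
#'
#' The baseline denoiser: each voxel of a single echo layer is replaced by
#' the weight-normalized average of the voxels in its spatial search window,
#' with weights decaying in the (spatial-only) patch distance. Equivalent to
#' [nlmeans3d()] with `patch_radius_echo = 0` applied to one layer.
#'
#' @param layer Numeric matrix (one echo image).
#' @param config An [nlm_config]; `patch_radius_echo` is ignored.
#' @param h Scalar bandwidth for this layer; default from the config's
#'   `h_schedule` (first element) or a robust scale of the layer.
#' @param noise_power Scalar noise variance for the distance offset;
#'   default from the config or `h^2`.
#' @return The denoised matrix.
#' @export
nlmeans2d <- function(layer, config = nlm_config(), h = NULL,
                      noise_power = NULL) {
  if (!is.matrix(layer)) stop("layer must be a matrix")
  if (is.null(h)) {
    h <- if (!is.null(config$h_schedule)) config$h_schedule[1]
         else max(stats::mad(as.vector(layer)), 1e-6)
  }
  if (is.null(noise_power)) {
    noise_power <- if (!is.null(config$noise_power_schedule))
      config$noise_power_schedule[1] else h^2
  }
  st <- array(layer, dim = c(dim(layer), 1))
  out <- nlm3d_cpp(as.vector(st), dim(layer)[1], dim(layer)[2], 1L,
                   config$patch_radius_space, 0L, config$search_radius_space,
                   config$a1, config$a2, h, 2 * noise_power)
  matrix(out, dim(layer)[1], dim(layer)[2])
}

#' 3D non-local means across space and echoes
#'
#' Denoises a multi-echo stack by weighted averaging over each voxel's
#' spatial search window, with weights computed from 3D patch distances
#' that extend along the echo axis ([patch_distance()]) and an echo-specific
#' bandwidth `h(te)`. Exploiting the strong between-echo correlation of the
#' decay signal, the 3D patches discriminate structure from noise better
#' than per-layer 2D patches, particularly at late echoes where SNR is low.
#'
#' @param stack A [mese_stack] with at least `2 * patch_radius_echo + 1`
#'   echoes.
#' @param config An [nlm_config]; if `h_schedule` or
#'   `noise_power_schedule` is `NULL`, constant schedules are derived from
#'   the stack's recorded noise level (`h = sigma`, noise power
#'   `= sigma^2`).
#' @return A denoised [mese_stack] (same shape, same TE grid).
#' @export
nlmeans3d <- function(stack, config = nlm_config()) {
  stopifnot(inherits(stack, "mese_stack"))
  d <- dim(stack$data)
  if (d[3] < 2 * config$patch_radius_echo + 1)
    stop("stack needs at least 2 * patch_radius_echo + 1 echoes")
  h <- resolve_h(config, stack)
  offs <- 2 * resolve_noise_power(config, stack)
  out <- nlm3d_cpp(as.vector(stack$data), d[1], d[2], d[3],
                   config$patch_radius_space, config$patch_radius_echo,
                   config$search_radius_space, config$a1, config$a2, h, offs)
  mese_stack(array(pmax(out, 0), dim = d), stack$te_grid, sigma = stack$sigma)
}

#' Per-echo bandwidth schedule from noise powers
#'
#' Maps per-layer noise-power estimates (e.g. the `noise_power` column of
#' [estimate_layer_snr()]) to the denoiser bandwidth
#' `h(te) = scale * sigma_hat(te)`, made non-decreasing by a running maximum
#' so the smoothing strength grows with the layer noise and never drops. A
#' small positive floor avoids a zero bandwidth on noiseless layers.
#'
#' @param layer_noise_powers Nonnegative per-echo noise power (variance)
#'   estimates.
#' @param scale Dimensionless multiplier; default 1 (with the
#'   noise-compensated weights, `h ~ sigma` rejects structure differing by
#'   a few sigma while averaging same-structure voxels freely).
#' @param floor Minimum bandwidth. Default 1e-6.
#' @return Positive, non-decreasing bandwidth vector.
#' @export
h_schedule_from_noise <- function(layer_noise_powers, scale = 1, floor = 1e-6) {
  if (any(layer_noise_powers < 0)) stop("noise powers must be nonnegative")
  h <- pmax(scale * sqrt(layer_noise_powers), floor)
  cummax(h)
}

#' Denoising quality metrics
#'
#' PSNR, RMSE and a global SSIM of a denoised stack against the noiseless
#' truth, per echo and aggregated. PSNR uses the truth's dynamic range; a
#' perfect reconstruction reports `Inf` PSNR and zero RMSE.
#'
#' @param noisy,denoised,truth Arrays (or [mese_stack]s) of identical shape.
#' @return List with `per_echo` (data.frame: `rmse`, `psnr`, `ssim` per
#'   echo, for both the denoised and the noisy input) and `aggregate`
#'   (overall `rmse`, `psnr`, `ssim` of the denoised stack).
#' @export
evaluate_denoising <- function(noisy, denoised, truth) {
  arr <- function(x) if (inherits(x, "mese_stack")) x$data else x
  noisy <- arr(noisy); denoised <- arr(denoised); truth <- arr(truth)
  if (!identical(dim(noisy), dim(truth)) || !identical(dim(denoised), dim(truth)))
    stop("shapes must match")
  if (length(dim(truth)) == 2) {
    noisy <- array(noisy, c(dim(noisy), 1))
    denoised <- array(denoised, c(dim(denoised), 1))
    truth <- array(truth, c(dim(truth), 1))
  }
  ne <- dim(truth)[3]
  rng <- max(truth) - min(truth)
  per <- data.frame(
    echo = seq_len(ne),
    rmse_denoised = NA_real_, psnr_denoised = NA_real_, ssim_denoised = NA_real_,
    rmse_noisy = NA_real_, psnr_noisy = NA_real_
  )
  for (k in seq_len(ne)) {
    per$rmse_denoised[k] <- rmse_of(denoised[, , k], truth[, , k])
    per$psnr_denoised[k] <- psnr_of(denoised[, , k], truth[, , k], rng)
    per$ssim_denoised[k] <- ssim_of(denoised[, , k], truth[, , k], rng)
    per$rmse_noisy[k] <- rmse_of(noisy[, , k], truth[, , k])
    per$psnr_noisy[k] <- psnr_of(noisy[, , k], truth[, , k], rng)
  }
  list(
    per_echo = per,
    aggregate = list(
      rmse = rmse_of(denoised, truth),
      psnr = psnr_of(denoised, truth, rng),
      ssim = mean(per$ssim_denoised)
    )
  )
}

rmse_of <- function(x, ref) sqrt(mean((x - ref)^2))

psnr_of <- function(x, ref, rng = max(ref) - min(ref)) {
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(rng^2 / mse)
}

# Global (single-window) structural similarity with the standard constants.
ssim_of <- function(x, ref, rng = max(ref) - min(ref)) {
  c1 <- (0.01 * rng)^2; c2 <- (0.03 * rng)^2
  mx <- mean(x); mr <- mean(ref)
  vx <- mean((x - mx)^2); vr <- mean((ref - mr)^2)
  cov <- mean((x - mx) * (ref - mr))
  ((2 * mx * mr + c1) * (2 * cov + c2)) /
    ((mx^2 + mr^2 + c1) * (vx + vr + c2))
}
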