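# Label-map templates, region-mean curve extraction, per-structure
# inversion tables, voxel-wise parameter maps, and tabular/graphical
# reporting.

#' Concentric-ring label template
#'
#' The label map matching the ring phantom's geometry: label 0 background,
#' labels 1..n from the inner disk outward.
#'
#' @param shape Integer `(rows, cols)`.
#' @param n_rings Number of rings.
#' @param outer_frac Fraction of the half-width spanned by the rings
#'   (matches [phantom_rings()]).
#' @param equal_area Equal-area rings, as in [phantom_rings()].
#' @return Integer label matrix.
#' @export
make_ring_template <- function(shape, n_rings = 3, outer_frac = 0.8,
                               equal_area = FALSE) {
  shape <- as.integer(shape)
  if (any(shape < 1)) stop("shape must be positive")
  masks <- ring_masks(shape[1], shape[2], n_rings, outer_frac, equal_area)
  labels <- matrix(0L, shape[1], shape[2])
  for (k in seq_len(n_rings)) labels[masks[[k]]] <- k
  labels
}

#' Six-structure tomato label template
#'
#' The label map of the synthetic tomato-like section built by
#' [phantom_tomato()]: 1 exocarp, 2 endocarp, 3 partition, 4 ovary tissue,
#' 5 seeds, 6 placenta, 0 background. A `names_table` attribute maps
#' structure names to labels.
#'
#' @param shape Integer `(rows, cols)`.
#' @return Integer label matrix with a `names_table` attribute.
#' @export
make_tomato_template <- function(shape = c(256, 256)) {
  generate_phantom(phantom_tomato(shape),
                   acquisition_params(te_grid = mese_te_grid(2)))$labels
}

#' Region-mean decay curves
#'
#' For each nonbackground label, averages the stack over the label's voxels
#' at every echo, producing one [decay_curve] per structure. When the stack
#' carries a noise level, each curve's sigma is the standard error of the
#' region mean, `sigma / sqrt(n_voxels)`, which is the appropriate weight
#' for the least-squares criterion of an averaged curve.
#'
#' When the stack records a positive noise level, magnitude (Rician) bias is
#' removed by default via the second-moment identity of the Rice
#' distribution, `E[v^2] = S^2 + 2 sigma^2`: the region signal is estimated
#' as the signed square root of `mean(v^2) - 2 sigma^2`, which is unbiased
#' for a homogeneous region and matters at late echoes where the magnitude
#' floor otherwise masquerades as a slow decay component (the signed root
#' keeps the estimator's fluctuation symmetric where the true signal is
#' ~0). Each corrected curve carries a per-echo noise scale from the
#' delta-method standard error of the estimator, floored near zero signal,
#' so downstream fits weight late low-SNR echoes correctly.
#'
#' @param stack A [mese_stack].
#' @param labels Integer label matrix of the stack's spatial shape.
#' @param bias_correct Apply the second-moment Rician bias correction;
#'   default on whenever the stack's `sigma` is known and positive.
#' @return Named list of [decay_curve]s, names from the label map's
#'   `names_table` attribute when present, otherwise `"region_<label>"`.
#'   Empty regions are skipped with a warning.
#' @export
extract_region_curves <- function(stack, labels,
                                  bias_correct = !is.null(stack$sigma) &&
                                    stack$sigma > 0) {
  stopifnot(inherits(stack, "mese_stack"))
  d <- dim(stack$data)
  if (!identical(dim(labels), d[1:2])) stop("label map shape must match stack")
  labs <- sort(unique(as.vector(labels)))
  labs <- labs[labs > 0]
  nt <- attr(labels, "names_table")
  curves <- list()
  flat <- matrix(stack$data, d[1] * d[2], d[3])
  for (lb in labs) {
    idx <- which(labels == lb)
    if (length(idx) == 0) { warning(sprintf("label %d empty; skipped", lb)); next }
    if (isTRUE(bias_correct)) {
      v2 <- flat[idx, , drop = FALSE]^2
      s2 <- colMeans(v2) - 2 * stack$sigma^2
      y <- sign(s2) * sqrt(abs(s2))
      # delta-method SE of the signed-root estimator, floored where the
      # estimate is within its own noise of zero
      m2sd <- apply(v2, 2, stats::sd) / sqrt(length(idx))
      sg <- pmax(m2sd / (2 * sqrt(pmax(abs(s2), m2sd))),
                 1e-9 * max(abs(y), 1))
    } else {
      y <- colMeans(flat[idx, , drop = FALSE])
      sg <- if (!is.null(stack$sigma) && stack$sigma > 0)
        stack$sigma / sqrt(length(idx)) else 1
    }
    nm <- if (!is.null(nt) && lb %in% nt) names(nt)[match(lb, nt)]
          else sprintf("region_%d", lb)
    curves[[nm]] <- decay_curve(stack$te_grid, y, sigma = sg)
  }
  curves
}

#' Per-structure mono- and tri-exponential inversion table
#'
#' Runs the full region-level analysis for each structure curve: a raw fit,
#' echo-exclusion preprocessing ([exclude_echoes()]), and a refit on the
#' reduced curve, for each requested model order. Reports R-squared and RMSE
#' before and after exclusion, and for multi-component fits the classified
#' water-state components and proportions.
#'
#' @param curves Named list of [decay_curve]s (see
#'   [extract_region_curves()]).
#' @param e Model orders to fit, default `c(1, 3)`.
#' @param bounds Optional named list of [component_bounds] per model order
#'   (names `"1"`, `"3"`, ...); default [default_bounds()] per curve.
#' @param config An [optimizer_config].
#' @param threshold_k Echo-exclusion threshold, see [exclude_echoes()].
#' @return A `structure_fit_table`: data.frame with one row per structure
#'   and model order, columns `structure`, `e`, `r2_raw`, `rmse_raw`,
#'   `r2_exp`, `rmse_exp`, `n_excluded`, then `T2<j>` and `A0<j>` and
#'   `prop<j>` per component of the post-exclusion fit. The full
#'   [invert_decay()] results are attached as attribute `fits`.
#' @export
invert_structures <- function(curves, e = c(1, 3), bounds = NULL,
                              config = optimizer_config(),
                              threshold_k = 3) {
  if (length(curves) == 0) stop("no curves to invert")
  rows <- list(); fits <- list()
  for (nm in names(curves)) {
    curve <- curves[[nm]]
    for (ee in e) {
      b <- if (!is.null(bounds)) bounds[[as.character(ee)]] else NULL
      fit_raw <- invert_decay(curve, e = ee, bounds = b, config = config)
      exc <- exclude_echoes(curve, e = ee, threshold_k = threshold_k,
                            fit_fn = function(curve, e)
                              invert_decay(curve, e = e, bounds = b,
                                           config = config)$theta)
      fit_exp <- if (length(exc$excluded) > 0) {
        f <- invert_decay(exc$curve, e = ee, bounds = b, config = config)
        f$excluded <- exc$excluded
        f
      } else fit_raw
      comp <- classify_components(fit_exp$theta)
      row <- data.frame(
        structure = nm, e = ee,
        r2_raw = fit_raw$r2, rmse_raw = fit_raw$rmse,
        r2_exp = fit_exp$r2, rmse_exp = fit_exp$rmse,
        n_excluded = length(exc$excluded),
        stringsAsFactors = FALSE
      )
      for (j in seq_len(ee)) {
        row[[sprintf("T2%d", j)]] <- comp$t2[j]
        row[[sprintf("A0%d", j)]] <- comp$A[j]
        row[[sprintf("prop%d", j)]] <- comp$proportion[j]
      }
      rows[[length(rows) + 1L]] <- row
      fits[[sprintf("%s_e%d", nm, ee)]] <-
        list(raw = fit_raw, excluded = exc$excluded, exp = fit_exp)
    }
  }
  # rbind with differing component columns
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA_real_
    r[all_cols]
  })
  tab <- do.call(rbind, rows)
  attr(tab, "fits") <- fits
  class(tab) <- c("structure_fit_table", class(tab))
  tab
}

#' Voxel-wise T2 and amplitude maps
#'
#' Inverts each masked voxel's decay curve independently and assembles
#' per-component T2 and amplitude maps. Voxels outside the mask (and voxels
#' whose fit fails) carry the sentinel `NA`. A stride subsamples the mask on
#' a regular grid for desk-scale runs; tri-exponential maps at full
#' resolution are expensive and best run strided.
#'
#' @param stack A [mese_stack].
#' @param mask Logical matrix of the stack's spatial shape.
#' @param e Model order, default 1.
#' @param bounds Optional [component_bounds].
#' @param config An [optimizer_config]; the `"fast"` preset is the sensible
#'   default at voxel scale.
#' @param stride Evaluate every `stride`-th row/column of the mask
#'   (default 1 = all masked voxels).
#' @return List with `t2` and `A`: each a `rows x cols x e` array (maps per
#'   component, ascending T2), plus `n_failed`.
#' @export
voxelwise_maps <- function(stack, mask, e = 1, bounds = NULL,
                           config = optimizer_config(preset = "fast"),
                           stride = 1) {
  stopifnot(inherits(stack, "mese_stack"))
  d <- dim(stack$data)
  if (!identical(dim(mask), d[1:2])) stop("mask shape must match stack")
  if (stride < 1) stop("stride must be >= 1")
  sel <- matrix(FALSE, d[1], d[2])
  sel[seq(1, d[1], by = stride), seq(1, d[2], by = stride)] <- TRUE
  sel <- sel & mask
  t2_map <- array(NA_real_, c(d[1], d[2], e))
  a_map <- array(NA_real_, c(d[1], d[2], e))
  idx <- which(sel, arr.ind = TRUE)
  sg <- if (!is.null(stack$sigma) && stack$sigma > 0) stack$sigma else 1
  n_failed <- 0L
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]
    y <- stack$data[i, j, ]
    if (y[1] <= 0) { n_failed <- n_failed + 1L; next }
    fit <- tryCatch(
      invert_decay(decay_curve(stack$te_grid, y, sigma = sg),
                   e = e, bounds = bounds, config = config),
      error = function(err) NULL
    )
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    comp <- fit$theta$components
    t2_map[i, j, ] <- comp[, "T2"]
    a_map[i, j, ] <- comp[, "A"]
  }
  list(t2 = t2_map, A = a_map, n_failed = n_failed)
}

#' Write a structure fit table and parameter maps to disk
#'
#' Writes the per-structure table as CSV, the full fit detail as JSON, and
#' (optionally) parameter maps as float TIFF images with PNG previews.
#'
#' @param table A `structure_fit_table` from [invert_structures()].
#' @param dir Output directory (created if missing).
#' @param maps Optional result of [voxelwise_maps()].
#' @return Invisibly, the paths written.
#' @export
report_structures <- function(table, dir, maps = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  csv <- file.path(dir, "structure_fits.csv")
  write.csv(as.data.frame(table), csv, row.names = FALSE)
  paths <- c(paths, csv)
  fits <- attr(table, "fits")
  if (!is.null(fits)) {
    js <- file.path(dir, "structure_fits.json")
    detail <- lapply(fits, function(f) list(
      raw = fit_result_to_list(f$raw),
      excluded = f$excluded,
      exp = fit_result_to_list(f$exp)
    ))
    jsonlite::write_json(detail, js, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, js)
  }
  if (!is.null(maps)) paths <- c(paths, report_maps(maps, dir))
  invisible(paths)
}

fit_result_to_list <- function(fit) {
  list(
    components = apply(fit$theta$components, 1, function(r)
      list(A = unname(r["A"]), T2 = unname(r["T2"]))),
    cls = fit$cls, r2 = fit$r2, rmse = fit$rmse,
    n_iter = fit$n_iter, converged = fit$converged
  )
}

#' Write parameter maps as float TIFFs with PNG previews
#'
#' @param maps Result of [voxelwise_maps()].
#' @param dir Output directory.
#' @return Paths written.
#' @export
report_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (what in c("t2", "A")) {
    arr <- maps[[what]]
    for (j in seq_len(dim(arr)[3])) {
      m <- arr[, , j]
      tif <- file.path(dir, sprintf("%s_map_c%d.tif", what, j))
      m_w <- m; m_w[is.na(m_w)] <- 0
      tiff::writeTIFF(m_w / max(m_w, 1), tif, bits.per.sample = 32L)
      png_path <- file.path(dir, sprintf("%s_map_c%d.png", what, j))
      grDevices::png(png_path, width = 480, height = 480)
      op <- graphics::par(mar = c(2, 2, 2, 4))
      graphics::image(t(m[nrow(m):1, ]), axes = FALSE, useRaster = TRUE,
                      main = sprintf("%s map (component %d)", toupper(what), j))
      graphics::par(op)
      grDevices::dev.off()
      paths <- c(paths, tif, png_path)
    }
  }
  paths
}
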