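# Round-tripping of stacks, label maps, decay curves and fit results
# through plain formats: multipage TIFF + JSON sidecar, CSV, JSON.

#' Write a multi-echo stack as a multipage TIFF with a JSON sidecar
#'
#' One 32-bit page per echo. TIFF pages store intensities rescaled to
#' `[0, 1]`; the scale factor, echo grid, repetition time and noise level go
#' to a `<path>.json` sidecar so reading restores the original values.
#'
#' @param stack A [mese_stack].
#' @param path Output `.tif` path.
#' @param tr Optional repetition time recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path, tr = NULL) {
  stopifnot(inherits(stack, "mese_stack"))
  scale <- max(stack$data)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(k) stack$data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(te_grid = stack$te_grid, scale = scale,
                  sigma = stack$sigma, tr = tr)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-echo stack written by [write_stack()]
#'
#' @param path The `.tif` path; the `<path>.json` sidecar must exist.
#' @return A [mese_stack].
#' @export
read_stack <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * sidecar$scale
  sigma <- sidecar$sigma
  if (is.null(sigma) || length(sigma) == 0) sigma <- NULL
  mese_stack(arr, sidecar$te_grid, sigma = sigma)
}

#' Write / read an integer label map as an 8-bit TIFF
#'
#' Labels 0-255; an optional name table travels in a JSON sidecar.
#'
#' @param labels Integer matrix.
#' @param path Output `.tif` path.
#' @return Invisibly, `path`.
#' @export
write_labelmap <- function(labels, path) {
  if (any(labels < 0) || any(labels > 255)) stop("labels must be in 0..255")
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8L)
  nt <- attr(labels, "names_table")
  if (!is.null(nt))
    jsonlite::write_json(as.list(nt), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  m <- tiff::readTIFF(path)
  labels <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    nt <- unlist(jsonlite::read_json(sidecar, simplifyVector = TRUE))
    attr(labels, "names_table") <- nt
  }
  labels
}

#' Write / read a decay curve as CSV
#'
#' Columns `te_ms`, `signal`, and `sigma` (constant per curve).
#'
#' @param curve A [decay_curve].
#' @param path CSV path.
#' @return Invisibly, `path`; the reader returns a [decay_curve].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  write.csv(data.frame(te_ms = curve$te, signal = curve$y,
                       sigma = curve$sigma),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  if (!all(c("te_ms", "signal") %in% names(df)))
    stop("curve CSV needs columns te_ms and signal")
  sigma <- if ("sigma" %in% names(df)) {
    if (length(unique(df$sigma)) == 1) df$sigma[1] else df$sigma
  } else 1
  decay_curve(df$te_ms, df$signal, sigma = sigma)
}

#' Write a fit result as JSON
#'
#' @param fit A `fit_result` from [invert_decay()].
#' @param path JSON path.
#' @return Invisibly, `path`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(fit_result_to_list(fit), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
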