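#' CEST / WASSR image series containers
#'
#' A saturation-offset image series: a 4-D array (x, y, slice, offset) of
#' signal intensities, the saturation offsets in ppm, and the index of the
#' unsaturated reference volume (acquired at a far off-resonant offset, e.g.
#' 300 ppm) used as the S0 normalizer.
#'
#' @param volumes 4-D numeric array (x, y, z, offset) or 3-D (x, y, offset)
#'   which is promoted to a single slice.
#' @param offsets ppm values, one per 4th-dimension volume.
#' @param reference_index position of the unsaturated reference volume.
#' @return object of class \code{cest_series} (or \code{wassr_series}).
#' @export
cest_series <- function(volumes, offsets, reference_index) {
  if (length(dim(volumes)) == 3L)
    dim(volumes) <- c(dim(volumes)[1:2], 1L, dim(volumes)[3])
  stopifnot(length(dim(volumes)) == 4L,
            dim(volumes)[4] == length(offsets),
            length(reference_index) == 1L,
            reference_index >= 1, reference_index <= length(offsets))
  structure(list(volumes = volumes, offsets = as.numeric(offsets),
                 reference_index = as.integer(reference_index)),
            class = "cest_series")
}

#' @rdname cest_series
#' @details \code{wassr_series} additionally requires the non-reference
#'   offsets to form a symmetric grid around 0 ppm (within 1e-6).
#' @export
wassr_series <- function(volumes, offsets, reference_index) {
  s <- cest_series(volumes, offsets, reference_index)
  off <- s$offsets[-s$reference_index]
  if (max(abs(sort(off) + rev(sort(off)))) > 1e-6)
    stop("WASSR offsets must be symmetric around 0 ppm", call. = FALSE)
  class(s) <- c("wassr_series", "cest_series")
  s
}

series_dims <- function(series) dim(series$volumes)[1:3]

# normalized z-values for one voxel; NULL if the voxel is unusable
voxel_zvalues <- function(series, i, j, k) {
  s <- series$volumes[i, j, k, ]
  s0 <- s[series$reference_index]
  if (!is.finite(s0) || s0 <= 0) return(NULL)
  z <- s[-series$reference_index] / s0
  if (any(!is.finite(z))) return(NULL)
  z
}

#' Estimate the per-voxel B0 offset map from a WASSR series
#'
#' Maximum-symmetry algorithm: for each voxel the normalized WASSR spectrum
#' is interpolated onto a dense 0.001 ppm grid with a cubic spline and the
#' water-centre frequency is taken as the candidate c minimising the
#' mirror-symmetry cost sum_w [Z(c+w) - Z(c-w)]^2, evaluated exhaustively on
#' the dense grid over the search range.
#'
#' @param wassr a \code{\link{wassr_series}}.
#' @param mask optional logical array (x, y, z); voxels outside are skipped.
#' @param search_ppm half-width of the candidate-centre range (default 0.5;
#'   must leave room for the mirror lags inside the sampled offsets).
#' @param dense_step dense interpolation grid step in ppm.
#' @return object of class \code{b0_map}: \code{offset_ppm} array (NA where
#'   invalid) and logical \code{valid} array.
#' @export
estimate_b0_map <- function(wassr, mask = NULL, search_ppm = 0.5,
                            dense_step = 0.001) {
  stopifnot(inherits(wassr, "wassr_series"))
  dims <- series_dims(wassr)
  off <- wassr$offsets[-wassr$reference_index]
  ord <- order(off); off <- off[ord]
  lo <- min(off); hi <- max(off)
  if (search_ppm >= hi)
    stop("search range must be smaller than the WASSR offset range", call. = FALSE)
  grid <- seq(lo, hi, by = dense_step)
  ci <- which(abs(grid) <= search_ppm + 1e-12)
  centres <- grid[ci]
  # mirror lags: every 10th dense point out to the guaranteed common support
  lag_max <- hi - search_ppm
  lags <- seq(10L, floor(lag_max / dense_step), by = 10L)
  offset_map <- array(NA_real_, dims)
  valid <- array(FALSE, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    if (!is.null(mask) && !mask[i, j, k]) next
    z <- voxel_zvalues(wassr, i, j, k)
    if (is.null(z)) next
    z <- z[ord]
    if (max(z) - min(z) < 1e-6) next           # flat spectrum: no water line
    zd <- spline(off, z, xout = grid, method = "fmm")$y
    cost <- rep(0, length(ci))
    for (l in lags) cost <- cost + (zd[ci + l] - zd[ci - l])^2
    b0 <- centres[which.min(cost)]
    offset_map[i, j, k] <- b0
    valid[i, j, k] <- TRUE
  }
  structure(list(offset_ppm = offset_map, valid = valid), class = "b0_map")
}

#' B0-correct a single z-spectrum
#'
#' Shifts the frequency axis by \code{-offset} (i.e. resamples the measured
#' spectrum at the nominal offsets plus the voxel's water-centre shift) with
#' cubic-spline interpolation. Points falling outside the measured support
#' are extrapolated flat and flagged.
#'
#' @param zspec a \code{\link{zspectrum}} (already normalized by S0).
#' @param offset the voxel's B0 offset in ppm; |offset| must be within the
#'   WASSR mapping range (1 ppm).
#' @return a corrected \code{zspectrum} on the nominal offset grid, with
#'   attributes \code{corrected = TRUE} and logical \code{extrapolated}.
#' @export
correct_zspectrum <- function(zspec, offset) {
  stopifnot(inherits(zspec, "zspectrum"), length(offset) == 1L, is.finite(offset))
  if (abs(offset) > 1)
    stop("B0 offset beyond the WASSR mapping range (1 ppm)", call. = FALSE)
  if (isTRUE(attr(zspec, "corrected")))
    stop("z-spectrum is already B0-corrected", call. = FALSE)
  xout <- zspec$offsets + offset
  outside <- xout < min(zspec$offsets) | xout > max(zspec$offsets)
  f <- splinefun(zspec$offsets, zspec$z, method = "fmm")
  znew <- f(pmin(pmax(xout, min(zspec$offsets)), max(zspec$offsets)))
  out <- zspectrum(zspec$offsets, znew, s0 = zspec$s0)
  attr(out, "corrected") <- TRUE
  attr(out, "extrapolated") <- outside
  out
}

#' Per-voxel gagCEST (MTR_asym) map
#'
#' For each voxel: normalize by the unsaturated reference, apply the
#' WASSR-derived B0 correction, compute the MTR_asym curve and average it
#' over the GAG-specific window (trapezoidal mean on a 0.05 ppm
#' interpolation grid). Voxels without a valid B0 estimate or signal are NaN.
#'
#' @param series a \code{\link{cest_series}}.
#' @param b0 a \code{b0_map} from \code{\link{estimate_b0_map}}, aligned
#'   with \code{series}.
#' @param window averaging window in ppm (default the GAG-specific 0.9-1.9).
#' @param mask optional logical array restricting the computation.
#' @return numeric array (x, y, z) of MTR_asym in percent.
#' @export
mtr_asym_map <- function(series, b0, window = c(0.9, 1.9), mask = NULL) {
  stopifnot(inherits(series, "cest_series"), inherits(b0, "b0_map"))
  dims <- series_dims(series)
  if (!identical(dim(b0$offset_ppm)[1:3], dims))
    stop("B0 map and CEST series are not aligned", call. = FALSE)
  off <- series$offsets[-series$reference_index]
  window <- sort(window)
  if (window[2] > max(off) || -window[1] < min(off))
    stop("window outside spectral coverage", call. = FALSE)
  out <- array(NaN, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    if (!is.null(mask) && !mask[i, j, k]) next
    if (!b0$valid[i, j, k]) next
    z <- voxel_zvalues(series, i, j, k)
    if (is.null(z)) next
    zs <- zspectrum(off, z)
    zc <- correct_zspectrum(zs, b0$offset_ppm[i, j, k])
    out[i, j, k] <- mean_mtr_asym_in_window(compute_mtr_asym(zc), window)
  }
  out
}

#' Multi-pool Lorentzian model of a z-spectrum
#'
#' Fixed-centre pools for cartilage gagCEST at 3 T: water (0 ppm), GAG-OH
#' (+1 ppm), GAG-NH (+3.2 ppm), two nuclear Overhauser components (-1 and
#' -2.8 ppm) and a magnetization-transfer pool (-2.43 ppm). The water centre
#' is fixed at 0 ppm, which is where it must lie after B0 correction.
#'
#' @param centers named numeric vector of pool centres in ppm.
#' @param amplitudes,widths starting values (fraction of Z; FWHM in ppm),
#'   recycled to the number of pools.
#' @return object of class \code{lorentzian_model}.
#' @export
lorentzian_model <- function(centers = c(water = 0, gag_oh = 1.0, gag_nh = 3.2,
                                         noe1 = -1.0, noe2 = -2.8, mt = -2.43),
                             amplitudes = c(0.8, rep(0.05, length(centers) - 1)),
                             widths = c(1.5, rep(1, length(centers) - 1))) {
  n <- length(centers)
  amplitudes <- rep_len(amplitudes, n)
  widths <- rep_len(widths, n)
  stopifnot(!is.null(names(centers)), all(amplitudes >= 0), all(amplitudes <= 1),
            all(widths > 0))
  structure(list(centers = centers, amplitudes = setNames(amplitudes, names(centers)),
                 widths = setNames(widths, names(centers))),
            class = "lorentzian_model")
}

lorentzian_sum <- function(omega, centers, amplitudes, widths) {
  z <- rep(1, length(omega))
  for (i in seq_along(centers)) {
    hw2 <- (widths[i] / 2)^2
    z <- z - amplitudes[i] * hw2 / (hw2 + (omega - centers[i])^2)
  }
  z
}

#' Evaluate a Lorentzian model
#'
#' @param model a \code{lorentzian_model}.
#' @param offsets ppm values at which to evaluate Z.
#' @return predicted Z values.
#' @export
predict_lorentzian <- function(model, offsets)
  lorentzian_sum(offsets, model$centers, model$amplitudes, model$widths)

#' Fit a multi-pool Lorentzian decomposition to a z-spectrum
#'
#' Least-squares fit of \code{Z(w) = 1 - sum_i A_i (G_i/2)^2 / ((G_i/2)^2 +
#' (w - d_i)^2)} with pool centres fixed, amplitudes bounded in [0, 1] and
#' widths (FWHM) bounded in (0.1, 10] ppm. A small multi-start (default 5
#' seeds, deterministic) guards against local minima; the best-residual
#' solution is returned.
#'
#' @param zspec a B0-corrected, normalized \code{\link{zspectrum}}.
#' @param model a \code{\link{lorentzian_model}} carrying centres and
#'   starting values.
#' @param n_starts number of random restarts (the first start uses the
#'   model's own starting values).
#' @param seed RNG seed for the restart jitter.
#' @return the fitted \code{lorentzian_model} with added fields
#'   \code{residual_norm}, \code{fitted}.
#' @export
fit_lorentzian <- function(zspec, model = lorentzian_model(), n_starts = 5,
                           seed = 1) {
  stopifnot(inherits(zspec, "zspectrum"), inherits(model, "lorentzian_model"))
  n <- length(model$centers)
  if (length(zspec$offsets) < 2 * n)
    stop("fewer data points than free parameters", call. = FALSE)
  lower <- c(rep(0, n), rep(0.1, n))
  upper <- c(rep(1, n), rep(10, n))
  resid_fn <- function(p)
    lorentzian_sum(zspec$offsets, model$centers, p[1:n], p[(n + 1):(2 * n)]) - zspec$z
  p0 <- c(model$amplitudes, model$widths)
  starts <- with_local_seed(seed, {
    c(list(p0), lapply(seq_len(max(0, n_starts - 1)), function(s) {
      p <- p0 * exp(rnorm(2 * n, sd = 0.4))
      pmin(pmax(p, lower + 1e-6), upper - 1e-6)
    }))
  })
  best <- NULL
  for (p in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("Lorentzian fit failed for all starts", call. = FALSE)
  p <- best$fit$par
  out <- model
  out$amplitudes <- setNames(p[1:n], names(model$centers))
  out$widths <- setNames(p[(n + 1):(2 * n)], names(model$centers))
  out$residual_norm <- best$rn
  out$fitted <- lorentzian_sum(zspec$offsets, model$centers, out$amplitudes, out$widths)
  out
}

#' Define a region of interest
#'
#' @param mask logical array (x, y, z) or (x, y).
#' @param label ROI label.
#' @param rater rater identifier.
#' @return object of class \code{roi_definition}.
#' @export
roi_definition <- function(mask, label = "cartilage", rater = "rater1") {
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  structure(list(mask = mask, label = label, rater = rater),
            class = "roi_definition")
}

#' Mean of a voxel map inside an ROI
#'
#' NaN/NA voxels are excluded, matching the ROI statistic used for gagCEST
#' summaries.
#'
#' @param map numeric array.
#' @param roi a \code{\link{roi_definition}} (or logical array).
#' @return scalar mean.
#' @export
roi_mean <- function(map, roi) {
  mask <- if (inherits(roi, "roi_definition")) roi$mask else roi
  v <- map[mask]
  mean(v[is.finite(v)])
}

#' ROI-averaged z-spectrum of a CEST series
#'
#' Voxel signals are averaged inside the ROI per offset, then normalized by
#' the averaged reference signal.
#'
#' @param series a \code{\link{cest_series}}.
#' @param roi a \code{\link{roi_definition}}.
#' @return a \code{\link{zspectrum}}.
#' @export
roi_zspectrum <- function(series, roi) {
  mask <- if (inherits(roi, "roi_definition")) roi$mask else roi
  nv <- dim(series$volumes)[4]
  sig <- vapply(seq_len(nv), function(v) {
    vol <- series$volumes[, , , v, drop = FALSE]
    dim(vol) <- dim(series$volumes)[1:3]
    mean(vol[mask])
  }, numeric(1))
  s0 <- sig[series$reference_index]
  zspectrum(series$offsets[-series$reference_index],
            sig[-series$reference_index] / s0, s0 = s0)
}
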