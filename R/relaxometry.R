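#' Relaxometry time series container
#'
#' @param times_ms inversion times (T1) or echo times (T2) in milliseconds,
#'   strictly increasing.
#' @param signals numeric vector (one voxel/ROI) or matrix with one row per
#'   voxel and one column per time point.
#' @param kind \code{"T1"} (inversion recovery) or \code{"T2"} (multi-echo).
#' @return object of class \code{relax_series}.
#' @export
relax_series <- function(times_ms, signals, kind = c("T1", "T2")) {
  kind <- match.arg(kind)
  times_ms <- as.numeric(times_ms)
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  stopifnot(!is.unsorted(times_ms, strictly = TRUE),
            ncol(signals) == length(times_ms))
  minpts <- if (kind == "T1") 3L else 2L
  if (length(times_ms) < minpts)
    stop("need at least ", minpts, " time points for ", kind, call. = FALSE)
  structure(list(times_ms = times_ms, signals = signals, kind = kind),
            class = "relax_series")
}

# default TI/TE grids of the 3 T ankle protocol
default_ti_ms <- function() c(25, 50, 100, 500, 1000, 2000)
default_te_ms <- function() c(13.8, 27.6, 41.4, 55.2, 69)

ir_model <- function(t, m0, mi, T1) m0 - (m0 - mi) * exp(-t / T1)

fit_t1_one <- function(t, y, magnitude) {
  m0_init <- max(abs(y))
  T1_init <- median(t)
  candidates <- if (magnitude) seq(0, length(t)) else 0
  # magnitude data lose the sign of the early inverted samples; restore the
  # polarity by trying every plausible zero-crossing position
  best <- NULL
  for (nneg in candidates) {
    ys <- y
    if (nneg > 0) ys[seq_len(nneg)] <- -abs(y[seq_len(nneg)])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(m0 = m0_init, mi = -m0_init, T1 = T1_init),
        lower = c(-Inf, -Inf, 1e-3), upper = c(Inf, Inf, 1e7),
        fn = function(p) ir_model(t, p[1], p[2], p[3]) - ys,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    pred <- ir_model(t, fit$par[1], fit$par[2], fit$par[3])
    res <- if (magnitude) abs(pred) - abs(y) else pred - y
    rms <- sqrt(mean(res^2))
    if (is.null(best) || rms < best$rms) best <- list(par = fit$par, rms = rms)
  }
  if (is.null(best) || best$par[3] <= 0 || !is.finite(best$par[3]))
    return(c(T1 = NA_real_, M0 = NA_real_, M_initial = NA_real_, rms = NA_real_))
  c(T1 = unname(best$par[3]), M0 = unname(best$par[1]),
    M_initial = unname(best$par[2]), rms = best$rms)
}

#' Fit T1 from an inversion-recovery series
#'
#' Three-parameter mono-exponential inversion recovery,
#' \code{Mz(t) = Mz0 - (Mz0 - Mz(0)) exp(-t/T1)}. With \code{magnitude =
#' TRUE} (scanner magnitude images, the default) the polarity of the early
#' samples is restored by trying each possible zero-crossing position and
#' keeping the best-residual fit.
#'
#' @param series a \code{\link{relax_series}} of kind \code{"T1"}, or a
#'   numeric vector of signals (then \code{times_ms} must be given).
#' @param times_ms inversion times if \code{series} is a plain vector.
#' @param magnitude treat signals as magnitude data.
#' @return data.frame with one row per voxel: \code{T1_ms}, \code{M0},
#'   \code{M_initial}, \code{residual_rms}. Non-convergent voxels get NA.
#' @export
fit_t1 <- function(series, times_ms = default_ti_ms(), magnitude = TRUE) {
  if (!inherits(series, "relax_series"))
    series <- relax_series(times_ms, series, "T1")
  res <- t(apply(series$signals, 1, function(y)
    fit_t1_one(series$times_ms, y, magnitude)))
  data.frame(T1_ms = res[, "T1"], M0 = res[, "M0"],
             M_initial = res[, "M_initial"], residual_rms = res[, "rms"])
}

fit_t2_one <- function(t, y, method) {
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1)) {
    # constant signal: no decay information
    return(c(T2 = Inf, M0 = y[1], rms = 0))
  }
  if (method == "loglinear" && all(y > 0)) {
    co <- stats::lm.fit(cbind(1, t), log(y))$coefficients
    if (co[2] < 0)
      return(c(T2 = unname(-1 / co[2]), M0 = unname(exp(co[1])),
               rms = sqrt(mean((exp(co[1] + co[2] * t) - y)^2))))
    # non-decaying log fit: fall through to nonlinear
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(m0 = max(y), T2 = max(t[1], t[length(t)] / 3)),
      lower = c(0, 1e-3), upper = c(Inf, 1e7),
      fn = function(p) p[1] * exp(-t / p[2]) - y,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(c(T2 = NA_real_, M0 = NA_real_, rms = NA_real_))
  c(T2 = unname(fit$par[2]), M0 = unname(fit$par[1]),
    rms = sqrt(mean(fit$fvec^2)))
}

#' Fit T2 from a multi-echo series
#'
#' Mono-exponential decay \code{Mxy(t) = Mxy(0) exp(-t/T2)}. The default is
#' nonlinear least squares; \code{method = "loglinear"} uses linear
#' regression on log signals and falls back to the nonlinear fit when any
#' signal is non-positive. A constant series carries no decay information
#' and is flagged with \code{T2 = Inf}.
#'
#' @param series a \code{\link{relax_series}} of kind \code{"T2"}, or a
#'   numeric vector of signals.
#' @param times_ms echo times if \code{series} is a plain vector.
#' @param method \code{"nonlinear"} (default) or \code{"loglinear"}.
#' @return data.frame with one row per voxel: \code{T2_ms}, \code{M0},
#'   \code{residual_rms}.
#' @export
fit_t2 <- function(series, times_ms = default_te_ms(),
                   method = c("nonlinear", "loglinear")) {
  method <- match.arg(method)
  if (!inherits(series, "relax_series"))
    series <- relax_series(times_ms, series, "T2")
  res <- t(apply(series$signals, 1, function(y)
    fit_t2_one(series$times_ms, y, method)))
  data.frame(T2_ms = res[, "T2"], M0 = res[, "M0"], residual_rms = res[, "rms"])
}

#' Voxelwise relaxation-time map from a 4-D series
#'
#' @param volumes 4-D array (x, y, z, time) or 3-D (x, y, time).
#' @param times_ms TI or TE list in ms.
#' @param kind \code{"T1"} or \code{"T2"}.
#' @param mask optional logical array; voxels outside are NA.
#' @param ... passed to \code{\link{fit_t1}} / \code{\link{fit_t2}}.
#' @return numeric array of T1 or T2 in ms.
#' @export
relaxation_map <- function(volumes, times_ms, kind = c("T1", "T2"),
                           mask = NULL, ...) {
  kind <- match.arg(kind)
  if (length(dim(volumes)) == 3L)
    dim(volumes) <- c(dim(volumes)[1:2], 1L, dim(volumes)[3])
  dims <- dim(volumes)[1:3]
  idx <- which(if (is.null(mask)) array(TRUE, dims) else mask)
  mat <- matrix(volumes, ncol = dim(volumes)[4])[idx, , drop = FALSE]
  fits <- if (kind == "T1") fit_t1(relax_series(times_ms, mat, "T1"), ...)
          else fit_t2(relax_series(times_ms, mat, "T2"), ...)
  out <- array(NA_real_, dims)
  out[idx] <- fits[[1]]
  out
}
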