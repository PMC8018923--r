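#' Define one proton pool
#'
#' A pool is characterised by its longitudinal and transverse relaxation
#' times, its proton concentration (which sets the equilibrium magnetization
#' relative to water), its chemical-exchange rate towards water, and its
#' chemical shift relative to the water resonance.
#'
#' @param name label, e.g. \code{"water"}, \code{"gag_oh"}.
#' @param T1,T2 relaxation times in seconds; \code{T2 <= T1} required.
#' @param concentration proton concentration in mol/L (water approx. 88 M).
#' @param exchange_rate exchange rate towards water in Hz; must be 0 for the
#'   water pool itself.
#' @param chemical_shift resonance offset from water in ppm.
#' @return an object of class \code{pool_parameters}.
#' @examples
#' water <- pool_parameters("water", T1 = 1.2, T2 = 0.039, concentration = 88)
#' @export
pool_parameters <- function(name, T1, T2, concentration,
                            exchange_rate = 0, chemical_shift = 0) {
  vals <- c(T1 = T1, T2 = T2, concentration = concentration,
            exchange_rate = exchange_rate, chemical_shift = chemical_shift)
  if (any(!is.finite(vals)))
    stop("pool '", name, "': all parameters must be finite", call. = FALSE)
  if (T1 <= 0 || T2 <= 0) stop("pool '", name, "': T1 and T2 must be > 0", call. = FALSE)
  if (T2 > T1) stop("pool '", name, "': T2 must not exceed T1", call. = FALSE)
  if (concentration <= 0) stop("pool '", name, "': concentration must be > 0", call. = FALSE)
  if (exchange_rate < 0) stop("pool '", name, "': exchange rate must be >= 0", call. = FALSE)
  structure(list(name = name, T1 = T1, T2 = T2, concentration = concentration,
                 exchange_rate = exchange_rate, chemical_shift = chemical_shift),
            class = "pool_parameters")
}

#' Literature pool parameters for tibiotalar cartilage gagCEST at 3 T
#'
#' Water (88 M, T1 = 1.2 s, T2 = 39 ms), GAG hydroxyl protons (+1 ppm,
#' 1000 Hz exchange, 0.3 M) and GAG amine protons (+3.2 ppm, 50 Hz, 0.1 M);
#' both solute pools have T1 = 1 s and T2 = 10 ms.
#'
#' @param gag_oh_concentration,gag_nh_concentration solute concentrations in
#'   mol/L; scaling both emulates varying tissue GAG content.
#' @return list of three \code{pool_parameters} (water first).
#' @export
cartilage_pools <- function(gag_oh_concentration = 0.3,
                            gag_nh_concentration = 0.1) {
  pools <- list(pool_parameters("water", 1.2, 0.039, 88))
  if (gag_oh_concentration > 0)
    pools <- c(pools, list(pool_parameters("gag_oh", 1, 0.01, gag_oh_concentration,
                                           exchange_rate = 1000, chemical_shift = 1)))
  if (gag_nh_concentration > 0)
    pools <- c(pools, list(pool_parameters("gag_nh", 1, 0.01, gag_nh_concentration,
                                           exchange_rate = 50, chemical_shift = 3.2)))
  pools
}

#' Define a pulsed pre-saturation train
#'
#' @param b1_uT nominal RF amplitude in microtesla. By convention
#'   (\code{b1_convention = "mean"}) this is the time-average amplitude over
#'   the pulse-on period; a Gaussian envelope is rescaled so its mean equals
#'   \code{b1_uT}. With \code{"peak"} it is the envelope maximum.
#' @param tp_ms duration of one saturation pulse in milliseconds.
#' @param np number of pulses in the train.
#' @param duty_cycle fraction of the saturation period with RF on; the
#'   interpulse delay is \code{tp_ms * (1 - duty_cycle) / duty_cycle}.
#' @param shape \code{"gaussian"} (truncated at 2.5 sigma, sigma = tp/5) or
#'   \code{"block"}.
#' @param segments number of piecewise-constant amplitude steps used to
#'   discretise a shaped pulse (block pulses always use one).
#' @param spoil if \code{TRUE}, transverse magnetization is zeroed at the
#'   start of each interpulse gap (ideal spoiling); default free evolution.
#' @param b1_convention see \code{b1_uT}.
#' @return an object of class \code{saturation_scheme}.
#' @examples
#' # in-vivo gagCEST module: 8 Gaussian pulses, 300 ms, 0.8 uT, DC 0.5
#' saturation_scheme(b1_uT = 0.8, tp_ms = 300, np = 8)
#' @export
saturation_scheme <- function(b1_uT, tp_ms, np, duty_cycle = 0.5,
                              shape = c("gaussian", "block"), segments = 64,
                              spoil = FALSE,
                              b1_convention = c("mean", "peak")) {
  shape <- match.arg(shape)
  b1_convention <- match.arg(b1_convention)
  stopifnot(is.finite(b1_uT), b1_uT >= 0,
            is.finite(tp_ms), tp_ms > 0,
            np >= 1, np == round(np),
            duty_cycle > 0, duty_cycle <= 1,
            segments >= 1)
  structure(list(b1_uT = b1_uT, tp_ms = tp_ms, np = as.integer(np),
                 duty_cycle = duty_cycle, shape = shape,
                 segments = as.integer(segments), spoil = spoil,
                 b1_convention = b1_convention),
            class = "saturation_scheme")
}

#' @export
print.saturation_scheme <- function(x, ...) {
  cat(sprintf("Pulsed saturation: %d x %s pulse(s), tp = %g ms, B1 = %g uT (%s), DC = %g\n",
              x$np, x$shape, x$tp_ms, x$b1_uT, x$b1_convention, x$duty_cycle))
  invisible(x)
}

# interpulse delay in seconds, derived (not stored)
interpulse_gap_s <- function(scheme)
  scheme$tp_ms / 1000 * (1 - scheme$duty_cycle) / scheme$duty_cycle

#' Scanner context for ppm/Hz conversion
#'
#' @param field_strength_T static field in tesla.
#' @param gamma_bar_MHz_T reduced gyromagnetic ratio in MHz/T (42.577 for 1H).
#' @return object of class \code{scanner_context}; \code{$f0_hz_per_ppm} is
#'   the offset conversion factor, \code{$gamma_hz_per_uT} converts B1.
#' @export
scanner_context <- function(field_strength_T = 3, gamma_bar_MHz_T = 42.577) {
  stopifnot(field_strength_T > 0, gamma_bar_MHz_T > 0)
  structure(list(field_strength_T = field_strength_T,
                 gamma_bar_MHz_T = gamma_bar_MHz_T,
                 f0_hz_per_ppm = field_strength_T * gamma_bar_MHz_T,
                 gamma_hz_per_uT = gamma_bar_MHz_T),
            class = "scanner_context")
}

#' Construct a z-spectrum
#'
#' @param offsets saturation offsets in ppm, strictly monotonic.
#' @param z normalized water signal Z(offset), same length as \code{offsets}.
#' @param s0 unsaturated reference signal used for normalization.
#' @return object of class \code{zspectrum}.
#' @export
zspectrum <- function(offsets, z, s0 = 1) {
  offsets <- as.numeric(offsets); z <- as.numeric(z)
  if (length(offsets) == 0L) stop("offsets must be non-empty", call. = FALSE)
  if (length(offsets) != length(z))
    stop("offsets and z must have the same length", call. = FALSE)
  d <- diff(offsets)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("offsets must be strictly monotonic", call. = FALSE)
  if (length(d) && all(d < 0)) { offsets <- rev(offsets); z <- rev(z) }
  structure(list(offsets = offsets, z = z, s0 = s0), class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("z-spectrum: %d offsets in [%g, %g] ppm, Z in [%.4f, %.4f]\n",
              length(x$offsets), min(x$offsets), max(x$offsets),
              min(x$z), max(x$z)))
  invisible(x)
}

# piecewise-constant amplitudes (uT) and durations (s) for one pulse
pulse_segments <- function(scheme) {
  tp <- scheme$tp_ms / 1000
  if (scheme$shape == "block")
    return(list(amp = scheme$b1_uT, dur = tp))
  n <- scheme$segments
  mid <- (seq_len(n) - 0.5) / n * tp          # segment midpoints in [0, tp]
  sigma <- tp / 5                              # truncation at +/- 2.5 sigma
  env <- exp(-(mid - tp / 2)^2 / (2 * sigma^2))
  scale <- if (scheme$b1_convention == "mean") scheme$b1_uT / mean(env)
           else scheme$b1_uT / max(env)
  list(amp = env * scale, dur = rep(tp / n, n))
}

pools_matrix <- function(pools) {
  if (inherits(pools, "pool_parameters")) pools <- list(pools)
  stopifnot(length(pools) >= 1)
  for (p in pools) if (!inherits(p, "pool_parameters"))
    stop("pools must be a list of pool_parameters", call. = FALSE)
  if (pools[[1]]$exchange_rate != 0)
    stop("first pool must be water (exchange rate 0)", call. = FALSE)
  m <- t(vapply(pools, function(p)
    c(1 / p$T1, 1 / p$T2, p$concentration / pools[[1]]$concentration,
      p$exchange_rate, p$chemical_shift), numeric(5)))
  dimnames(m) <- list(vapply(pools, `[[`, "", "name"),
                      c("R1", "R2", "M0", "k", "delta"))
  m
}

#' Simulate the z-spectrum of a pulsed CEST experiment
#'
#' Propagates the coupled Bloch-McConnell equations of all pools through the
#' full saturation train, separately for every requested offset, starting
#' from thermal equilibrium. Each shaped pulse is discretised into
#' piecewise-constant amplitude segments and each segment advanced by the
#' exact matrix-exponential solution of the affine linear system; interpulse
#' gaps evolve freely with B1 = 0 (or with ideal spoiling if requested).
#'
#' @param pools list of \code{\link{pool_parameters}}, water first; solute
#'   pools exchange with water only.
#' @param scheme a \code{\link{saturation_scheme}}.
#' @param offsets saturation offsets in ppm.
#' @param context a \code{\link{scanner_context}}.
#' @return a \code{\link{zspectrum}} with \code{Z = Mz_water / M0_water}.
#' @examples
#' z <- simulate_pulsed_cest(cartilage_pools(),
#'                           saturation_scheme(1.0, 200, 6),
#'                           offsets = seq(-4, 4, 0.5))
#' @export
simulate_pulsed_cest <- function(pools, scheme, offsets,
                                 context = scanner_context()) {
  stopifnot(inherits(scheme, "saturation_scheme"),
            inherits(context, "scanner_context"))
  offsets <- as.numeric(offsets)
  if (length(offsets) == 0L) stop("offsets must be non-empty", call. = FALSE)
  if (any(!is.finite(offsets))) stop("offsets must be finite", call. = FALSE)
  pm <- pools_matrix(pools)
  seg <- pulse_segments(scheme)
  z <- bm_z_train(pm, offsets, seg$amp, seg$dur,
                  interpulse_gap_s(scheme), scheme$np, scheme$spoil,
                  context$f0_hz_per_ppm, context$gamma_hz_per_uT)
  zspectrum(offsets, z)
}
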