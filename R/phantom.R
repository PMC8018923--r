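#' Specify a synthetic ankle-cartilage phantom
#'
#' The phantom emulates a single-slice tibiotalar gagCEST acquisition at 3 T:
#' a circular "body" of free water containing two thin, parallel cartilage
#' bands (tibial and talar layers, a few voxels thick, emulating the roughly
#' 2 mm cartilage of the ankle), imaged with the in-vivo protocol (CEST:
#' 8 Gaussian pulses, tp = 300 ms, B1 = 0.8 uT, DC = 0.5, offsets -3..3 ppm;
#' WASSR: 1 pulse, tp = 54 ms, B1 = 0.25 uT, offsets -1..1 ppm; plus
#' inversion-recovery and multi-echo series). GAG content inside the bands is
#' calibrated per cohort so that the noiseless ROI-mean MTR_asym over
#' 0.9-1.9 ppm hits the cohort design point (healthy 1.49\%, degenerated
#' 0.34\%).
#'
#' @param grid image size in voxels, length 2 (single slice).
#' @param cohort \code{"healthy"} or \code{"patient"}; sets the calibration
#'   design point unless \code{design_mtr_pct} is given.
#' @param seed integer seed, mandatory for any stochastic output.
#' @param noise_sigma noise standard deviation as a fraction of S0.
#' @param noise_model \code{"gaussian"} (high-SNR approximation, default) or
#'   \code{"rician"} (magnitude of complex Gaussian noise).
#' @param b0 B0 field description: \code{list(type = "constant", value = x)}
#'   or \code{list(type = "smooth", amplitude = a)} (low-order harmonic with
#'   peak |B0| = a ppm; a <= 1 required, default 0.1).
#' @param thickness cartilage band thickness in voxels (2-4 typical).
#' @param gag_scale multiplier applied to the literature GAG concentrations
#'   (0.3 M OH / 0.1 M NH); \code{NULL} (default) calibrates it to the
#'   cohort design point by root finding.
#' @param gag_gradient optional length-2 relative multipliers (low, high):
#'   a left-to-right concentration gradient across the bands, quantised to
#'   \code{gag_levels} discrete steps.
#' @param gag_levels number of discrete concentration levels for the gradient.
#' @param design_mtr_pct calibration target in percent (overrides cohort).
#' @param t1_ms,t2_ms cartilage relaxation times (healthy ankle cartilage:
#'   940 / 35 ms).
#' @param s0 unsaturated reference signal level (arbitrary units).
#' @param scheme,wassr_scheme saturation schemes for the CEST and WASSR
#'   series.
#' @param cest_offsets,wassr_offsets nominal offset grids in ppm.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid = c(64, 64), cohort = c("healthy", "patient"),
                         seed, noise_sigma = 0.005,
                         noise_model = c("gaussian", "rician"),
                         b0 = list(type = "smooth", amplitude = 0.1),
                         thickness = 3, gag_scale = NULL,
                         gag_gradient = NULL, gag_levels = 5,
                         design_mtr_pct = NULL,
                         t1_ms = 940, t2_ms = 35, s0 = 1000,
                         scheme = saturation_scheme(0.8, 300, 8),
                         wassr_scheme = saturation_scheme(0.25, 54, 1),
                         cest_offsets = seq(-3, 3, by = 0.25),
                         wassr_offsets = seq(-1, 1, by = 0.1)) {
  cohort <- match.arg(cohort)
  noise_model <- match.arg(noise_model)
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is mandatory for phantom generation", call. = FALSE)
  if (is.null(design_mtr_pct))
    design_mtr_pct <- if (cohort == "healthy") 1.49 else 0.34
  b0_amp <- switch(b0$type, constant = abs(b0$value), smooth = b0$amplitude,
                   stop("b0$type must be 'constant' or 'smooth'", call. = FALSE))
  if (b0_amp > 1) stop("|B0| must stay within the 1 ppm WASSR range", call. = FALSE)
  stopifnot(length(grid) == 2, all(grid >= 16), thickness >= 2, thickness <= 4,
            noise_sigma >= 0, gag_levels >= 1)
  structure(list(grid = as.integer(grid), cohort = cohort, seed = as.integer(seed),
                 noise_sigma = noise_sigma, noise_model = noise_model, b0 = b0,
                 thickness = as.integer(thickness), gag_scale = gag_scale,
                 gag_gradient = gag_gradient, gag_levels = gag_levels,
                 design_mtr_pct = design_mtr_pct, t1_ms = t1_ms, t2_ms = t2_ms,
                 s0 = s0, scheme = scheme, wassr_scheme = wassr_scheme,
                 cest_offsets = cest_offsets, wassr_offsets = wassr_offsets),
            class = "phantom_spec")
}

# window-mean MTR_asym of the cartilage pool model at a given GAG scale,
# simulated on the nominal offset grid (the quantity the calibration targets)
design_mtr_at_scale <- function(scale, scheme, offsets, window = c(0.9, 1.9),
                                context = scanner_context()) {
  pools <- cartilage_pools(0.3 * scale, 0.1 * scale)
  zs <- simulate_pulsed_cest(pools, scheme, offsets, context)
  mean_mtr_asym_in_window(compute_mtr_asym(zs), window)
}

.calibration_cache <- new.env(parent = emptyenv())

#' Calibrate the GAG concentration scale to a target MTR_asym
#'
#' Solves (by root finding on the forward Bloch-McConnell model) for the
#' multiplier of the literature GAG concentrations at which the noiseless
#' window-mean MTR_asym over 0.9-1.9 ppm equals the target. This turns the
#' cohort means into testable design points instead of hard-coded numbers.
#'
#' @param target_pct target window-mean MTR_asym in percent.
#' @param scheme saturation scheme of the emulated acquisition.
#' @param offsets nominal offset grid the acquisition samples.
#' @param window averaging window in ppm.
#' @return the concentration multiplier (1 = literature healthy values).
#' @export
calibrate_gag_scale <- function(target_pct, scheme = saturation_scheme(0.8, 300, 8),
                                offsets = seq(-3, 3, by = 0.25),
                                window = c(0.9, 1.9)) {
  key <- paste(target_pct, scheme$b1_uT, scheme$tp_ms, scheme$np,
               scheme$duty_cycle, scheme$shape, scheme$segments,
               min(offsets), max(offsets), length(offsets),
               window[1], window[2], sep = "|")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  f <- function(s) design_mtr_at_scale(s, scheme, offsets, window) - target_pct
  upper <- 2
  while (f(upper) < 0 && upper < 64) upper <- upper * 2
  s <- stats::uniroot(f, c(1e-6, upper), tol = 1e-7)$root
  .calibration_cache[[key]] <- s
  s
}

smooth_b0_field <- function(nx, ny, amplitude) {
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  f <- sin(2 * pi * x / nx) * cos(pi * y / ny) +
       0.3 * cos(2 * pi * y / ny)
  amplitude * f / max(abs(f))
}

phantom_geometry <- function(spec) {
  nx <- spec$grid[1]; ny <- spec$grid[2]
  x <- matrix(seq_len(nx), nx, ny); y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  body <- (x - cx)^2 + (y - cy)^2 <= (0.45 * min(nx, ny))^2
  th <- spec$thickness
  gap <- 2                                    # joint space between the layers
  r1 <- floor(cy - gap / 2 - th + 1):floor(cy - gap / 2)          # tibial
  r2 <- ceiling(cy + gap / 2):(ceiling(cy + gap / 2) + th - 1)    # talar
  bands <- matrix(FALSE, nx, ny)
  bands[, c(r1, r2)] <- TRUE
  bands <- bands & body
  # ellipsoid ROI in the central load-bearing region, away from the rim
  roi <- bands & (abs(x - cx) <= 0.3 * nx)
  list(body = body, cartilage = bands, roi = roi)
}

add_noise <- function(vol, sigma_abs, model) {
  if (sigma_abs <= 0) return(vol)
  if (model == "gaussian") vol + rnorm(length(vol), sd = sigma_abs)
  else sqrt((vol + rnorm(length(vol), sd = sigma_abs))^2 +
            rnorm(length(vol), sd = sigma_abs)^2)
}

# sample a finely simulated spectrum at nominal offsets seen by a voxel whose
# water centre sits at b0 ppm: observed(w) = true(w - b0)
sample_shifted <- function(fine_fun, nominal, b0) fine_fun(nominal - b0)

#' Generate a synthetic phantom dataset
#'
#' Forward-simulates, voxel by voxel, the CEST and WASSR series of the
#' in-vivo protocol (with the voxel's GAG concentration and B0 shift), plus
#' inversion-recovery and multi-echo relaxometry series, and packages them
#' with the ground-truth maps. All randomness is governed by the spec's seed;
#' identical specs give bit-identical datasets.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param context a \code{\link{scanner_context}}.
#' @return object of class \code{phantom_dataset} with elements \code{cest},
#'   \code{wassr} (series), \code{t1_series}, \code{t2_series} (4-D arrays +
#'   time lists), \code{roi}, \code{masks}, and \code{truth} (b0, MTR_asym,
#'   GAG-OH amplitude, T1, T2 maps and the calibrated \code{gag_scale}).
#' @export
generate_phantom <- function(spec, context = scanner_context()) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  nx <- spec$grid[1]; ny <- spec$grid[2]
  dims <- c(nx, ny, 1L)

  scale0 <- if (is.null(spec$gag_scale))
    calibrate_gag_scale(spec$design_mtr_pct, spec$scheme, spec$cest_offsets)
  else spec$gag_scale

  # per-voxel concentration multiplier, quantised to discrete levels so each
  # level is simulated exactly once
  rel <- matrix(0, nx, ny)
  if (is.null(spec$gag_gradient)) {
    rel[geo$cartilage] <- 1
  } else {
    xs <- matrix(seq_len(nx), nx, ny)
    g <- spec$gag_gradient
    levels <- seq(g[1], g[2], length.out = spec$gag_levels)
    idx <- pmin(spec$gag_levels,
                1L + floor((xs - 1) / nx * spec$gag_levels))
    rel[geo$cartilage] <- levels[idx[geo$cartilage]]
  }
  scale_map <- rel * scale0

  b0_map <- switch(spec$b0$type,
                   constant = matrix(spec$b0$value, nx, ny),
                   smooth = smooth_b0_field(nx, ny, spec$b0$amplitude))
  b0_map[!geo$body] <- 0

  # fine simulation grids: supersets of the nominal grids (so unshifted
  # voxels reproduce the direct simulation exactly at the sampled offsets)
  # padded beyond the B0 excursion
  pad <- 0.5
  fine_cest <- seq(min(spec$cest_offsets) - pad, max(spec$cest_offsets) + pad, by = 0.05)
  fine_wassr <- seq(min(spec$wassr_offsets) - pad, max(spec$wassr_offsets) + pad, by = 0.05)

  uniq <- sort(unique(as.vector(scale_map[geo$body])))
  sim_level <- lapply(uniq, function(s) {
    pools <- cartilage_pools(0.3 * s, 0.1 * s)
    zc <- simulate_pulsed_cest(pools, spec$scheme, fine_cest, context)
    zw <- simulate_pulsed_cest(pools, spec$wassr_scheme, fine_wassr, context)
    zn <- simulate_pulsed_cest(pools, spec$scheme, spec$cest_offsets, context)
    list(cest_fun = splinefun(zc$offsets, zc$z, method = "fmm"),
         wassr_fun = splinefun(zw$offsets, zw$z, method = "fmm"),
         nominal = zn,
         truth_mtr = mean_mtr_asym_in_window(compute_mtr_asym(zn), c(0.9, 1.9)),
         truth_gag = 100 * fit_lorentzian(zn)$amplitudes[["gag_oh"]])
  })

  n_cest <- length(spec$cest_offsets); n_wassr <- length(spec$wassr_offsets)
  cest_vol <- array(0, c(nx, ny, 1, n_cest + 1))
  wassr_vol <- array(0, c(nx, ny, 1, n_wassr + 1))
  truth_mtr <- array(NaN, dims); truth_gag <- array(NaN, dims)

  body_idx <- which(geo$body, arr.ind = TRUE)
  for (r in seq_len(nrow(body_idx))) {
    i <- body_idx[r, 1]; j <- body_idx[r, 2]
    lv <- sim_level[[match(scale_map[i, j], uniq)]]
    b0 <- b0_map[i, j]
    cest_vol[i, j, 1, seq_len(n_cest)] <-
      spec$s0 * sample_shifted(lv$cest_fun, spec$cest_offsets, b0)
    wassr_vol[i, j, 1, seq_len(n_wassr)] <-
      spec$s0 * sample_shifted(lv$wassr_fun, spec$wassr_offsets, b0)
    if (geo$cartilage[i, j]) {
      truth_mtr[i, j, 1] <- lv$truth_mtr
      truth_gag[i, j, 1] <- lv$truth_gag
    }
  }
  cest_vol[, , 1, n_cest + 1] <- spec$s0 * geo$body
  wassr_vol[, , 1, n_wassr + 1] <- spec$s0 * geo$body

  # relaxometry: cartilage vs free-water compartments
  t1_map <- array(NA_real_, dims); t2_map <- array(NA_real_, dims)
  t1_map[geo$body] <- 1200; t2_map[geo$body] <- 39
  t1_map[geo$cartilage] <- spec$t1_ms; t2_map[geo$cartilage] <- spec$t2_ms
  ti <- default_ti_ms(); te <- default_te_ms()
  t1_vol <- array(0, c(nx, ny, 1, length(ti)))
  t2_vol <- array(0, c(nx, ny, 1, length(te)))
  for (v in seq_along(ti)) {
    s <- abs(spec$s0 * (1 - 2 * exp(-ti[v] / t1_map[, , 1])))
    s[!geo$body] <- 0
    t1_vol[, , 1, v] <- s
  }
  for (v in seq_along(te)) {
    s <- spec$s0 * exp(-te[v] / t2_map[, , 1])
    s[!geo$body] <- 0
    t2_vol[, , 1, v] <- s
  }

  sig <- spec$noise_sigma * spec$s0
  with_local_seed(spec$seed, {
    cest_vol <- add_noise(cest_vol, sig, spec$noise_model)
    wassr_vol <- add_noise(wassr_vol, sig, spec$noise_model)
    t1_vol <- add_noise(t1_vol, sig, spec$noise_model)
    t2_vol <- add_noise(t2_vol, sig, spec$noise_model)
  })

  truth_b0 <- array(b0_map, dims)
  truth_b0[!geo$body] <- NA_real_

  structure(list(
    spec = spec,
    cest = cest_series(cest_vol, c(spec$cest_offsets, 300), n_cest + 1),
    wassr = wassr_series(wassr_vol, c(spec$wassr_offsets, 300), n_wassr + 1),
    t1_series = list(times_ms = ti, volumes = t1_vol),
    t2_series = list(times_ms = te, volumes = t2_vol),
    roi = roi_definition(geo$roi, label = "tibiotalar_cartilage"),
    masks = list(body = array(geo$body, dims),
                 cartilage = array(geo$cartilage, dims)),
    truth = list(b0_ppm = truth_b0, mtr_asym_pct = truth_mtr,
                 gag_oh_amplitude_pct = truth_gag,
                 t1_ms = array(t1_map, dims), t2_ms = array(t2_map, dims),
                 gag_scale = scale0)),
    class = "phantom_dataset")
}

#' Generate a seeded cohort of phantom subjects
#'
#' Per-subject biological variability is emulated by a lognormal multiplier
#' (unit mean) on the cohort's calibrated GAG concentration; per-subject
#' seeds are derived deterministically from the master seed, so the whole
#' cohort is reproducible.
#'
#' @param n_subjects number of subjects (17 healthy / 5 patients emulates the
#'   in-vivo study design).
#' @param cohort \code{"healthy"} or \code{"patient"}.
#' @param seed master seed.
#' @param conc_sdlog between-subject lognormal sd on the log scale.
#' @param ... further arguments to \code{\link{phantom_spec}}.
#' @return list of \code{phantom_dataset}.
#' @export
cohort_fixture <- function(n_subjects, cohort = c("healthy", "patient"), seed,
                           conc_sdlog = 0.08, ...) {
  cohort <- match.arg(cohort)
  stopifnot(n_subjects >= 1)
  base <- phantom_spec(cohort = cohort, seed = seed, ...)
  scale0 <- if (is.null(base$gag_scale))
    calibrate_gag_scale(base$design_mtr_pct, base$scheme, base$cest_offsets)
  else base$gag_scale
  jitter <- with_local_seed(seed,
    rlnorm(n_subjects, meanlog = -conc_sdlog^2 / 2, sdlog = conc_sdlog))
  lapply(seq_len(n_subjects), function(i) {
    sp <- base
    sp$gag_scale <- scale0 * jitter[i]
    sp$seed <- (base$seed + 7919L * i) %% .Machine$integer.max
    generate_phantom(sp)
  })
}

#' Run the quantification chain on a phantom (or real) dataset
#'
#' WASSR B0 mapping, MTR_asym mapping over the GAG-specific window inside the
#' ROI, ROI summary, and a six-pool Lorentzian fit of the B0-corrected
#' ROI-mean z-spectrum.
#'
#' @param ds a \code{phantom_dataset} (or a list with \code{cest},
#'   \code{wassr}, \code{roi} entries).
#' @param window MTR_asym averaging window in ppm.
#' @param mask optional processing mask (default: the ROI).
#' @return list: \code{b0} (map), \code{mtr_map}, \code{roi_mtr_pct},
#'   \code{gag_oh_amplitude_pct}, \code{lorentzian} (fitted model).
#' @export
quantify_dataset <- function(ds, window = c(0.9, 1.9), mask = NULL) {
  if (is.null(mask)) mask <- ds$roi$mask
  b0 <- estimate_b0_map(ds$wassr, mask = mask)
  map <- mtr_asym_map(ds$cest, b0, window = window, mask = mask)
  zroi <- roi_zspectrum(ds$cest, ds$roi)
  b0_roi <- mean(b0$offset_ppm[ds$roi$mask & b0$valid], na.rm = TRUE)
  zcorr <- correct_zspectrum(zroi, b0_roi)
  fit <- fit_lorentzian(zcorr)
  list(b0 = b0, mtr_map = map,
       roi_mtr_pct = roi_mean(map, ds$roi),
       gag_oh_amplitude_pct = 100 * fit$amplitudes[["gag_oh"]],
       lorentzian = fit)
}
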