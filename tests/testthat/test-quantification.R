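test_that("maximum-symmetry centring recovers synthetic water lines", {
  # symmetric line centred at 0
  w0 <- wassr_line_series(b0 = 0)
  b0 <- estimate_b0_map(w0)
  expect_equal(b0$offset_ppm[1, 1, 1], 0, tolerance = 1e-9)
  # shifted by +0.05 ppm
  w5 <- wassr_line_series(b0 = 0.05)
  b5 <- estimate_b0_map(w5)
  expect_equal(b5$offset_ppm[1, 1, 1], 0.05, tolerance = 0.002)
})

test_that("noisy centre estimates match the exhaustive grid-search oracle", {
  set.seed(21)
  for (b0_true in c(-0.12, 0.03, 0.2)) {
    w <- wassr_line_series(b0 = b0_true, noise_sd = 0.02, seed = b0_true * 1000)
    est <- estimate_b0_map(w)$offset_ppm[1, 1, 1]
    off <- w$offsets[-w$reference_index]
    z <- w$volumes[1, 1, 1, -w$reference_index] / w$volumes[1, 1, 1, w$reference_index]
    oracle <- mscf_grid_oracle(off, z)
    expect_equal(est, oracle, tolerance = 1e-12)
  }
})

test_that("flat or dead voxels are masked, not errors", {
  vol <- array(0, c(2, 1, 1, 22))
  vol[2, 1, 1, ] <- 500               # flat spectrum, no water line
  w <- wassr_series(vol, c(seq(-1, 1, 0.1), 300), 22)
  b0 <- estimate_b0_map(w)
  expect_false(any(b0$valid))
  expect_true(all(is.na(b0$offset_ppm)))
})

test_that("B0 correction is an identity at zero offset and inverts a shift", {
  off <- seq(-3, 3, 0.25)
  z <- 1 - 0.8 * exp(-2 * off^2) - 0.03 * exp(-(off - 1)^2)
  zs <- zspectrum(off, z)
  z0 <- correct_zspectrum(zs, 0)
  expect_lt(max(abs(z0$z - zs$z)), 1e-12)

  # shift the underlying smooth spectrum by +0.2 then correct with +0.2
  fz <- function(w) 1 - 0.8 * exp(-2 * w^2) - 0.03 * exp(-(w - 1)^2)
  shifted <- zspectrum(off, fz(off - 0.2))
  rec <- correct_zspectrum(shifted, 0.2)
  interior <- abs(off) <= 2.5
  expect_lt(max(abs(rec$z[interior] - fz(off[interior]))), 1e-3)

  # linear spectrum: correction is exact at interior points
  lin <- zspectrum(off, 0.5 + 0.1 * off)
  corr <- correct_zspectrum(lin, 0.1)
  inside <- !attr(corr, "extrapolated")
  expect_equal(corr$z[inside], 0.5 + 0.1 * (off[inside] + 0.1), tolerance = 1e-12)

  expect_error(correct_zspectrum(zs, 1.5), "WASSR")
})

test_that("B0 correction cannot be applied twice", {
  zs <- zspectrum(seq(-3, 3, 0.25), rep(0.9, 25))
  once <- correct_zspectrum(zs, 0.1)
  expect_true(attr(once, "corrected"))
  expect_error(correct_zspectrum(once, 0.1), "already")
})

test_that("water-only voxels map to zero gagCEST", {
  sp <- phantom_spec(cohort = "healthy", seed = 5, noise_sigma = 0,
                     b0 = list(type = "constant", value = 0))
  ds <- generate_phantom(sp)
  water_mask <- ds$masks$body & !ds$masks$cartilage
  b0 <- estimate_b0_map(ds$wassr, mask = water_mask)
  m <- mtr_asym_map(ds$cest, b0, mask = water_mask)
  expect_lt(max(abs(m[water_mask])), 1e-6)
})

test_that("gagCEST map reproduces the phantom ground truth in-mask", {
  sp <- phantom_spec(cohort = "healthy", seed = 6, noise_sigma = 0,
                     b0 = list(type = "constant", value = 0))
  ds <- generate_phantom(sp)
  b0 <- estimate_b0_map(ds$wassr, mask = ds$roi$mask)
  m <- mtr_asym_map(ds$cest, b0, mask = ds$roi$mask)
  diffs <- (m - ds$truth$mtr_asym_pct)[ds$roi$mask]
  expect_lt(max(abs(diffs)), 0.2)
  # masked voxels stay NaN
  expect_true(all(is.nan(m[!ds$roi$mask])))
})

test_that("voxelwise gagCEST is monotone in GAG concentration", {
  sp <- phantom_spec(cohort = "healthy", seed = 7, noise_sigma = 0,
                     b0 = list(type = "constant", value = 0),
                     gag_gradient = c(0.3, 1.5), gag_levels = 5)
  ds <- generate_phantom(sp)
  b0 <- estimate_b0_map(ds$wassr, mask = ds$roi$mask)
  m <- mtr_asym_map(ds$cest, b0, mask = ds$roi$mask)
  conc <- ds$truth$gag_oh_amplitude_pct  # proxy: truth amplitude per level
  mtr_true <- ds$truth$mtr_asym_pct
  sel <- ds$roi$mask & is.finite(m)
  expect_gt(cor(m[sel], mtr_true[sel], method = "spearman"), 0.95)
})

test_that("Lorentzian fitting recovers members of its own model class", {
  off <- seq(-3, 3, 0.25)
  # single pool, noiseless
  z <- lorentzian_z(off, 1, 0.05, 1)
  model <- lorentzian_model(centers = c(gag_oh = 1))
  fit <- fit_lorentzian(zspectrum(off, z), model)
  expect_equal(unname(fit$amplitudes), 0.05, tolerance = 1e-6)
  expect_equal(unname(fit$widths), 1, tolerance = 1e-4)

  # six pools, high SNR: all amplitudes within 10% relative error
  m0 <- lorentzian_model()
  amps <- c(water = 0.85, gag_oh = 0.06, gag_nh = 0.05, noe1 = 0.06,
            noe2 = 0.05, mt = 0.10)
  widths <- c(water = 1.4, gag_oh = 0.8, gag_nh = 1.0, noe1 = 0.8,
              noe2 = 1.0, mt = 6.0)
  off2 <- seq(-5, 5, 0.1)
  z6 <- lorentzian_z(off2, m0$centers, amps, widths)
  set.seed(33)
  z6hi <- z6 + rnorm(length(z6), sd = 0.001)
  fit_hi <- fit_lorentzian(zspectrum(off2, z6hi),
                           lorentzian_model(amplitudes = pmin(amps * 1.5, 0.95),
                                            widths = widths * 0.8))
  expect_true(all(abs(fit_hi$amplitudes - amps) / amps < 0.10))
})

test_that("six-pool amplitude errors at SNR 100 respect the information bound", {
  # the overlapping NOE/MT pools make sub-10% recovery statistically
  # impossible at this noise level; the correct expectation is the
  # Jacobian-based (Fisher-information) standard error of the model
  m0 <- lorentzian_model()
  amps <- c(water = 0.85, gag_oh = 0.06, gag_nh = 0.05, noe1 = 0.06,
            noe2 = 0.05, mt = 0.10)
  widths <- c(water = 1.4, gag_oh = 0.8, gag_nh = 1.0, noe1 = 0.8,
              noe2 = 1.0, mt = 6.0)
  off2 <- seq(-5, 5, 0.1)
  sdn <- 0.01
  p0 <- c(amps, widths)
  f <- function(p) lorentzian_z(off2, m0$centers, p[1:6], p[7:12])
  J <- vapply(seq_along(p0), function(j) {
    dp <- p0; dp[j] <- dp[j] + 1e-6
    (f(dp) - f(p0)) / 1e-6
  }, numeric(length(off2)))
  se_amp <- (sdn * sqrt(diag(solve(crossprod(J)))))[1:6]
  z6 <- lorentzian_z(off2, m0$centers, amps, widths)
  set.seed(34)
  for (rep in 1:3) {
    zn <- z6 + rnorm(length(z6), sd = sdn)
    fit <- fit_lorentzian(zspectrum(off2, zn),
                          lorentzian_model(amplitudes = pmin(amps * 1.5, 0.95),
                                           widths = widths * 0.8))
    expect_true(all(abs(fit$amplitudes - amps) < 4 * se_amp))
  }
})

test_that("Lorentzian fit residual on model-generated data is at the noise floor", {
  off <- seq(-4, 4, 0.2)
  m0 <- lorentzian_model()
  z <- lorentzian_z(off, m0$centers, c(0.8, 0.04, 0.02, 0.03, 0.02, 0.05),
                    c(1.5, 1, 1, 1, 1, 2.5))
  sd <- 0.005
  set.seed(9)
  zn <- z + rnorm(length(z), sd = sd)
  fit <- fit_lorentzian(zspectrum(off, zn))
  # residual sum of squares ~ sigma^2 * chi^2_(n - p); bound at the 99.9% tail
  n <- length(off); p <- 12
  expect_lt(fit$residual_norm^2, sd^2 * qchisq(0.999, n - p))
  expect_error(fit_lorentzian(zspectrum(off[1:10], zn[1:10])), "fewer")
})

test_that("ROI helpers validate masks and average spectra correctly", {
  expect_error(roi_definition(matrix(FALSE, 4, 4)), "empty")
  sp <- phantom_spec(cohort = "healthy", seed = 8, noise_sigma = 0,
                     b0 = list(type = "constant", value = 0))
  ds <- generate_phantom(sp)
  zroi <- roi_zspectrum(ds$cest, ds$roi)
  # uniform concentration + no noise: ROI spectrum equals any voxel spectrum
  ij <- which(ds$roi$mask[, , 1], arr.ind = TRUE)[1, ]
  s <- ds$cest$volumes[ij[1], ij[2], 1, ]
  zvox <- s[-ds$cest$reference_index] / s[ds$cest$reference_index]
  expect_equal(zroi$z, zvox, tolerance = 1e-10)
})
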