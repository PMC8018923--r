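test_that("MTR_asym arithmetic follows its definition", {
  # Z(-1) = 0.90, Z(+1) = 0.88 -> 2.0% at 1 ppm
  zs <- zspectrum(c(-2, -1, 0, 1, 2), c(0.95, 0.90, 0.10, 0.88, 0.93))
  curve <- compute_mtr_asym(zs)
  expect_equal(curve$percent[curve$offsets == 1], 2.0, tolerance = 1e-12)
  # perfectly symmetric spectrum -> all-zero curve
  sym <- zspectrum(seq(-3, 3, 0.5), 1 - 0.8 * exp(-seq(-3, 3, 0.5)^2))
  expect_true(all(abs(compute_mtr_asym(sym)$percent) < 1e-12))
  # one-sided spectrum is rejected
  expect_error(compute_mtr_asym(zspectrum(1:5 / 2, rep(0.9, 5))), "negative")
})

test_that("MTR_asym curves are antisymmetric under mirrored evaluation", {
  set.seed(4)
  off <- seq(-4, 4, 0.25)
  zs <- zspectrum(off, 1 - 0.8 * exp(-off^2) - 0.02 * exp(-(off - 1)^2))
  f <- splinefun(zs$offsets, zs$z)
  dw <- seq(0.25, 3, 0.25)
  expect_equal(100 * (f(-dw) - f(dw)), -100 * (f(dw) - f(-dw)))
  curve <- compute_mtr_asym(zs)
  expect_equal(curve$percent, 100 * (f(-curve$offsets) - f(curve$offsets)))
})

test_that("window maximum matches dense brute force and breaks ties low", {
  # constant curve: tie broken toward the window's low edge
  const <- structure(list(offsets = seq(0.1, 3, 0.1), percent = rep(1, 30)),
                     class = "mtr_asym_curve")
  m <- max_mtr_asym_in_window(const, c(0.5, 1.5), 0.01)
  expect_equal(m$max_pct, 1.0)
  expect_equal(m$argmax_ppm, 0.5)

  set.seed(7)
  for (rep in 1:5) {
    x <- seq(0.05, 3, 0.05)
    y <- as.numeric(2 * sin(runif(1, 1, 3) * x) * exp(-x / runif(1, 1, 4)))
    curve <- structure(list(offsets = x, percent = y), class = "mtr_asym_curve")
    m <- max_mtr_asym_in_window(curve, c(0.5, 2.5), 0.01)
    grid <- seq(0.5, 2.5, 0.01)
    vals <- splinefun(x, y, method = "fmm")(grid)
    expect_equal(m$max_pct, max(vals))
    expect_equal(m$argmax_ppm, grid[which.max(vals)])
  }
  expect_error(max_mtr_asym_in_window(const, c(0.001, 0.002), 0.01), "within")
})

test_that("window maxima are monotone under window containment", {
  zs <- simulate_pulsed_cest(cartilage_pools(), saturation_scheme(1.0, 100, 6),
                             seq(-4, 4, 0.05))
  curve <- compute_mtr_asym(zs)
  inner <- max_mtr_asym_in_window(curve, c(1.0, 1.5), 0.01)$max_pct
  mid <- max_mtr_asym_in_window(curve, c(0.5, 1.5), 0.01)$max_pct
  outer <- max_mtr_asym_in_window(curve, c(0.5, 2.5), 0.01)$max_pct
  expect_lte(inner, mid)
  expect_lte(mid, outer)
})

test_that("reported maxima are insensitive to the search step", {
  zs <- simulate_pulsed_cest(cartilage_pools(), saturation_scheme(0.8, 200, 6),
                             seq(-4, 4, 0.05))
  curve <- compute_mtr_asym(zs)
  m1 <- max_mtr_asym_in_window(curve, c(0.9, 1.9), 0.01)$max_pct
  m5 <- max_mtr_asym_in_window(curve, c(0.9, 1.9), 0.05)$max_pct
  expect_lt(abs(m1 - m5), 0.02)
})

test_that("a single-value sweep equals the direct simulate-and-max pipeline", {
  base <- saturation_scheme(1.0, 100, 6)
  spec <- sweep_spec("tp", 200, base, windows = list(c(0.9, 1.9)))
  res <- run_sweep(spec)
  zs <- simulate_pulsed_cest(cartilage_pools(), saturation_scheme(1.0, 200, 6),
                             seq(-4, 4, 0.05))
  direct <- max_mtr_asym_in_window(compute_mtr_asym(zs), c(0.9, 1.9), 0.01)
  expect_equal(res$max_mtr_asym_pct, direct$max_pct)
  expect_equal(res$argmax_ppm, direct$argmax_ppm)
})

test_that("asymmetry accumulates with pulse number at low saturation power", {
  # far from the spillover regime the pulse-number dependence saturates
  # monotonically
  spec <- sweep_spec("np", c(2, 4, 8, 12), saturation_scheme(0.3, 100, 2),
                     windows = list(c(0.9, 1.9)))
  res <- run_sweep(spec)
  expect_true(all(diff(res$max_mtr_asym_pct) > 0))
})

test_that("the SAR ceiling rejects over-long pulses", {
  base <- saturation_scheme(1.0, 100, 6)
  spec <- sweep_spec("tp", c(200, 400), base)
  expect_error(run_sweep(spec), "SAR")
  spec2 <- sweep_spec("tp", c(200, 400), base, tp_ceiling_ms = 500)
  expect_silent(res <- run_sweep(spec2, offsets = seq(-4, 4, 0.25)))
})

test_that("window mean uses the trapezoidal rule on the interpolation grid", {
  x <- seq(0.05, 3, 0.05)
  curve <- structure(list(offsets = x, percent = 2 * x), class = "mtr_asym_curve")
  # linear curve: trapezoidal mean over [a, b] is the midpoint value
  expect_equal(mean_mtr_asym_in_window(curve, c(0.9, 1.9)), 2 * 1.4,
               tolerance = 1e-9)
})
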