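test_that("pool and scheme constructors validate their physics", {
  expect_error(pool_parameters("w", T1 = 1, T2 = 2, concentration = 88), "T2")
  expect_error(pool_parameters("w", T1 = -1, T2 = 0.04, concentration = 88), "T1")
  expect_error(pool_parameters("w", T1 = 1, T2 = 0.04, concentration = 0), "concentration")
  expect_error(pool_parameters("w", T1 = NaN, T2 = 0.04, concentration = 88), "finite")
  expect_error(pool_parameters("s", 1, 0.01, 0.3, exchange_rate = -5), "exchange")
  expect_error(saturation_scheme(0.8, 300, 0), "np")
  expect_error(saturation_scheme(0.8, 300, 8, duty_cycle = 0), "duty_cycle")
  expect_error(saturation_scheme(0.8, -1, 8), "tp_ms")
  # first pool must be water (no exchange)
  pools <- list(pool_parameters("s", 1, 0.01, 0.3, exchange_rate = 100),
                pool_parameters("water", 1.2, 0.039, 88))
  expect_error(simulate_pulsed_cest(pools, saturation_scheme(1, 100, 2), 1),
               "water")
  expect_error(simulate_pulsed_cest(cartilage_pools(),
                                    saturation_scheme(1, 100, 2),
                                    numeric(0)), "non-empty")
})

test_that("water-only spectra are symmetric and zero-B1 gives Z = 1", {
  water <- cartilage_pools(0, 0)
  off <- seq(-4, 4, 0.5)
  zs <- simulate_pulsed_cest(water, saturation_scheme(1.0, 100, 4), off)
  expect_equal(zs$z, rev(zs$z), tolerance = 1e-9)
  asym <- compute_mtr_asym(zs)
  expect_true(all(abs(asym$percent) < 1e-7))

  z0 <- simulate_pulsed_cest(cartilage_pools(), saturation_scheme(0, 300, 8),
                             c(-1, 0.5, 1, 3.2))
  expect_equal(z0$z, rep(1, 4), tolerance = 1e-9)
})

test_that("noiseless z-values stay within [0, 1]", {
  off <- seq(-4, 4, 0.25)
  for (b1 in c(0.4, 0.8, 1.4)) {
    zs <- simulate_pulsed_cest(cartilage_pools(), saturation_scheme(b1, 200, 8), off)
    expect_true(all(zs$z >= 0 & zs$z <= 1 + 1e-9))
  }
})

test_that("matrix-exponential propagation matches the stiff ODE oracle", {
  # a couple of deterministic configurations here; the randomized batch of
  # 20+ configurations runs in the acceptance suite
  set.seed(11)
  for (rep in 1:3) {
    pools <- random_pools()
    scheme <- random_scheme()
    offs <- sort(runif(3, -4, 4))
    za <- simulate_pulsed_cest(pools, scheme, offs)$z
    zo <- ode_z_oracle(pools, scheme, offs)
    expect_lt(max(abs(za - zo)), 1e-6)
  }
})

test_that("saturation at the solute resonance deepens with pulse count", {
  z_at_1ppm <- vapply(c(1, 2, 4, 8, 14), function(np)
    simulate_pulsed_cest(cartilage_pools(), saturation_scheme(1.0, 100, np), 1)$z,
    numeric(1))
  expect_true(all(diff(z_at_1ppm) < 0))
})

test_that("the CEST effect vanishes as solute concentration goes to zero", {
  off <- seq(-2.5, 2.5, 0.1)
  maxima <- vapply(c(0.3, 0.1, 0.03, 0.01, 0.003), function(conc) {
    zs <- simulate_pulsed_cest(cartilage_pools(conc, 0),
                               saturation_scheme(1.0, 100, 4), off)
    max(compute_mtr_asym(zs)$percent)
  }, numeric(1))
  expect_true(all(diff(maxima) < 0))
  expect_lt(maxima[length(maxima)], 0.05)
})

test_that("Gaussian discretization is converged at the default segment count", {
  off <- seq(-4, 4, 0.05)
  m <- vapply(c(64, 128), function(nseg) {
    zs <- simulate_pulsed_cest(cartilage_pools(),
                               saturation_scheme(0.8, 300, 8, segments = nseg), off)
    max_mtr_asym_in_window(compute_mtr_asym(zs), c(0.9, 1.9))$max_pct
  }, numeric(1))
  expect_lt(abs(m[2] - m[1]), 0.1)
})

test_that("ideal interpulse spoiling is a testable, small perturbation", {
  off <- c(-1, 1)
  z_free <- simulate_pulsed_cest(cartilage_pools(),
                                 saturation_scheme(1.0, 100, 4), off)$z
  z_spoil <- simulate_pulsed_cest(cartilage_pools(),
                                  saturation_scheme(1.0, 100, 4, spoil = TRUE), off)$z
  expect_false(identical(z_free, z_spoil))
  expect_lt(max(abs(z_free - z_spoil)), 0.01)  # gaps >> T2, transverse decayed
})

test_that("zspectrum enforces monotonic offsets of matching length", {
  expect_error(zspectrum(c(1, 1, 2), c(0.9, 0.8, 0.7)), "monotonic")
  expect_error(zspectrum(c(1, 2), c(0.9, 0.8, 0.7)), "length")
  # descending input is normalised to ascending
  zs <- zspectrum(c(2, 1, -1), c(0.7, 0.8, 0.9))
  expect_equal(zs$offsets, c(-1, 1, 2))
  expect_equal(zs$z, c(0.9, 0.8, 0.7))
})
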