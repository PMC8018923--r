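# Independent oracles used across the suite.

# --- Bloch-McConnell ODE oracle -------------------------------------------
# Integrates the same piecewise-constant BM system with deSolve's stiff
# solver; completely independent of the matrix-exponential propagation.

bm_deriv_oracle <- function(t, y, parms) {
  P <- parms$P
  n <- nrow(P)
  dy <- numeric(3 * n)
  for (i in seq_len(n)) {
    xi <- 3 * i - 2; yi <- 3 * i - 1; zi <- 3 * i
    dw <- 2 * pi * parms$f0 * (P[i, "delta"] - parms$offset)
    dy[xi] <- -P[i, "R2"] * y[xi] + dw * y[yi]
    dy[yi] <- -dw * y[xi] - P[i, "R2"] * y[yi] + parms$w1 * y[zi]
    dy[zi] <- -parms$w1 * y[yi] - P[i, "R1"] * (y[zi] - P[i, "M0"])
    if (i > 1) {
      kb <- P[i, "k"]; kf <- kb * P[i, "M0"] / P[1, "M0"]
      for (c in 0:2) {
        dy[3 * i - 2 + c] <- dy[3 * i - 2 + c] - kb * y[3 * i - 2 + c] + kf * y[c + 1]
        dy[c + 1] <- dy[c + 1] - kf * y[c + 1] + kb * y[3 * i - 2 + c]
      }
    }
  }
  list(dy)
}

ode_z_oracle <- function(pools, scheme, offsets, context = scanner_context()) {
  P <- gagcest:::pools_matrix(pools)
  seg <- gagcest:::pulse_segments(scheme)
  gap <- gagcest:::interpulse_gap_s(scheme)
  vapply(offsets, function(off) {
    y <- as.vector(rbind(0, 0, P[, "M0"]))
    step <- function(y, dur, b1) {
      out <- deSolve::lsoda(y, c(0, dur), bm_deriv_oracle,
                            parms = list(P = P, offset = off,
                                         w1 = 2 * pi * context$gamma_hz_per_uT * b1,
                                         f0 = context$f0_hz_per_ppm),
                            rtol = 1e-10, atol = 1e-12, maxsteps = 1e5)
      as.numeric(out[2, -1])
    }
    for (k in seq_len(scheme$np)) {
      for (s in seq_along(seg$amp)) y <- step(y, seg$dur[s], seg$amp[s])
      if (k < scheme$np && gap > 0) {
        if (scheme$spoil) for (i in seq_len(nrow(P))) y[c(3 * i - 2, 3 * i - 1)] <- 0
        y <- step(y, gap, 0)
      }
    }
    y[3] / P[1, "M0"]
  }, numeric(1))
}

# --- naive maximum-symmetry grid search ------------------------------------
# Double-loop implementation of the mirror-symmetry cost on the dense grid.

mscf_grid_oracle <- function(offsets, z, search_ppm = 0.5, dense_step = 0.001) {
  grid <- seq(min(offsets), max(offsets), by = dense_step)
  zd <- spline(offsets, z, xout = grid, method = "fmm")$y
  ci <- which(abs(grid) <= search_ppm + 1e-12)
  lags <- seq(10L, floor((max(offsets) - search_ppm) / dense_step), by = 10L)
  best_c <- NA; best_cost <- Inf
  for (idx in ci) {
    cost <- 0
    for (l in lags) cost <- cost + (zd[idx + l] - zd[idx - l])^2
    if (cost < best_cost) { best_cost <- cost; best_c <- grid[idx] }
  }
  best_c
}

# --- textbook ICC from ANOVA sums of squares -------------------------------

icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1); msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  list(
    sicc = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    aicc = (msr - mse) / (msr + (msc - mse) / n))
}

# --- helpers to build small inputs -----------------------------------------

lorentzian_z <- function(offsets, centers, amps, widths) {
  z <- rep(1, length(offsets))
  for (i in seq_along(centers))
    z <- z - amps[i] * (widths[i] / 2)^2 / ((widths[i] / 2)^2 + (offsets - centers[i])^2)
  z
}

wassr_line_series <- function(b0 = 0, nx = 1, ny = 1, noise_sd = 0,
                              offsets = seq(-1, 1, 0.1), s0 = 1000, seed = 1) {
  # Lorentzian direct-saturation line of width 0.35 ppm centred at b0
  z <- 1 - 0.85 * (0.175)^2 / (0.175^2 + (offsets - b0)^2)
  vol <- array(0, c(nx, ny, 1, length(offsets) + 1))
  set.seed(seed)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    vol[i, j, 1, seq_along(offsets)] <- s0 * (z + rnorm(length(z), sd = noise_sd))
    vol[i, j, 1, length(offsets) + 1] <- s0 * (1 + rnorm(1, sd = noise_sd))
  }
  wassr_series(vol, c(offsets, 300), length(offsets) + 1)
}

random_pools <- function() {
  t2w <- runif(1, 0.02, 0.08)
  water <- pool_parameters("water", T1 = runif(1, 0.8, 2), T2 = t2w,
                           concentration = 88)
  t2s <- runif(1, 0.005, 0.02)
  sol <- pool_parameters("solute", T1 = runif(1, 0.5, 1.5), T2 = t2s,
                         concentration = runif(1, 0.05, 0.5),
                         exchange_rate = runif(1, 20, 2000),
                         chemical_shift = runif(1, 0.5, 3.5))
  list(water, sol)
}

random_scheme <- function() {
  saturation_scheme(b1_uT = runif(1, 0.2, 1.5),
                    tp_ms = runif(1, 20, 120),
                    np = sample(1:3, 1),
                    duty_cycle = runif(1, 0.3, 0.9),
                    shape = sample(c("gaussian", "block"), 1),
                    segments = 8)
}
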