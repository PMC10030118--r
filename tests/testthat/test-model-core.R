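# Coupling kernels, simulator dynamics and raster binning.

test_that("coupling weights follow the closed-form kernels", {
  nt <- tibble::tibble(id = 1:3,
                       x = c(0, 4.5, 0), y = c(0, 0, 4.5), z = c(0, 0, 0),
                       hemisphere = c("L", "L", "L"),
                       ap = c(0, 0, 4.5), ml = c(0, 4.5, 0))
  p <- model_params(g_e = 2, g_i = 0.5, sigma_e = 4.5, sigma_i = 4.5,
                    tau_e = 0.05, tau_i = 24, mu = -5)
  W <- build_coupling(nt, p)
  # d = 0: weight g (self-coupling present)
  expect_equal(W$E[1, 1], 2)
  expect_equal(W$I[1, 1], 0.5)
  # d = sigma, gaussian: g exp(-1/2)
  expect_equal(W$E[1, 2], 2 * exp(-0.5))
  # exponential variant at d = sigma: g exp(-1)
  pe <- model_params(g_e = 2, g_i = 0.5, sigma_e = 4.5, sigma_i = 4.5,
                     tau_e = 0.05, tau_i = 24, mu = -5,
                     kernel_shape = "exponential")
  We <- build_coupling(nt, pe)
  expect_equal(We$E[1, 2], 2 * exp(-1))
  # symmetry of the distance kernel
  expect_equal(W$E[2, 1], W$E[1, 2])
})

test_that("cross-hemisphere coupling is scaled by the interhemisphere factor", {
  nt <- tibble::tibble(id = 1:2, x = c(-2, 2.5), y = c(0, 0), z = c(0, 0),
                       hemisphere = c("L", "R"), ap = c(0, 0), ml = c(2, 2.5))
  p <- model_params(g_e = 3, g_i = 1, sigma_e = 4.5, sigma_i = 40,
                    tau_e = 0.05, tau_i = 24, mu = -5)
  W <- build_coupling(nt, p)
  expect_equal(W$E[1, 2], 0.01 * 3 * exp(-4.5^2 / (2 * 4.5^2)))
})

test_that("pruning removes the stated fraction and rescales survivors", {
  nt <- generate_positions(80, seed = 7)
  p0 <- optimized_params()
  p1 <- optimized_params(prune_fraction = 0.2)
  W0 <- build_coupling(nt, p0, seed = 5)
  W1 <- build_coupling(nt, p1, seed = 5)
  off0 <- Matrix::which(W0$I != 0, arr.ind = TRUE)
  off0 <- off0[off0[, 1] != off0[, 2], ]
  n0 <- nrow(off0)
  off1 <- Matrix::which(W1$I != 0, arr.ind = TRUE)
  off1 <- off1[off1[, 1] != off1[, 2], ]
  expect_equal(nrow(off1) / n0, 0.8, tolerance = 0.01)
  # surviving weights rescaled by 1 / (1 - p)
  i <- off1[1, 1]; j <- off1[1, 2]
  expect_equal(W1$I[i, j], W0$I[i, j] / 0.8)
  # expected total coupling preserved
  expect_equal(sum(W1$I), sum(W0$I), tolerance = 0.05)
})

test_that("coupling is invariant under rigid translation and rejects bad input", {
  nt <- generate_positions(50, seed = 9)
  p <- optimized_params()
  W1 <- build_coupling(nt, p)
  nt2 <- nt
  nt2$x <- nt2$x + 123.4; nt2$y <- nt2$y - 55; nt2$z <- nt2$z + 7
  W2 <- build_coupling(nt2, p)
  expect_equal(as.matrix(W1$E), as.matrix(W2$E), tolerance = 1e-10)
  nt3 <- nt; nt3$x[1] <- NA
  expect_error(build_coupling(nt3, p), "finite")
  expect_error(model_params(g_e = 1, g_i = 1, sigma_e = 4.5, sigma_i = 40,
                            tau_e = 0.05, tau_i = 24, mu = -5,
                            prune_fraction = 1), "prune")
})

test_that("binning sums counts in windows and conserves spikes", {
  r <- spike_raster(matrix(c(1, 0, 0, 2, 0, 1, 0, 0), nrow = 1), 0.05)
  b <- bin_raster(r, 4)
  expect_equal(as.numeric(b$counts), c(3, 1))
  expect_equal(b$frame_dt, 0.2)
  # all-zero raster stays zero
  z <- bin_raster(spike_raster(matrix(0, 3, 8), 0.05), 4)
  expect_equal(sum(z$counts), 0)
  # random raster: window sums match a brute-force computation per neuron
  set.seed(42)
  m <- matrix(rpois(5 * 23, 1), 5)
  rb <- bin_raster(spike_raster(m, 0.05), 4)
  for (i in 1:5) {
    expected <- sapply(seq_len(5), function(w) sum(m[i, (4 * w - 3):(4 * w)]))
    expect_equal(as.numeric(rb$counts[i, ]), expected)
  }
  expect_error(bin_raster(r, 0), "bin_factor")
})

test_that("uncoupled network is Poisson at rate exp(mu) and passes dispersion", {
  nt <- tiny_neurons()[1:100, ]
  mu <- -3.5
  p <- model_params(g_e = 0, g_i = 0, sigma_e = 4.5, sigma_i = 40,
                    tau_e = 0.05, tau_i = 24, mu = mu)
  sim <- simulate_network(nt, p, sim_config(duration = 500, seed = 5,
                                            log_drive = "none"))
  counts <- sim$raster$counts
  n_draws <- length(counts)
  emp <- sum(counts) / n_draws
  se <- sqrt(exp(mu) / n_draws)
  expect_lt(abs(emp - exp(mu)), 3 * se)
  # index of dispersion ~ 1 for Poisson; chi-square bounds at alpha ~ 1e-4
  x <- as.numeric(as.matrix(counts[1:20, ]))
  disp <- var(x) / mean(x)
  df <- length(x) - 1
  expect_gt(disp, qchisq(1e-4, df) / df)
  expect_lt(disp, qchisq(1 - 1e-4, df) / df)
})

test_that("identical seeds give bit-identical rasters, different seeds differ", {
  nt <- tiny_neurons()[1:150, ]
  p <- optimized_params()
  cfg <- sim_config(duration = 60, seed = 77, log_drive = "none")
  s1 <- simulate_network(nt, p, cfg)
  s2 <- simulate_network(nt, p, cfg)
  expect_identical(as.matrix(s1$raster$counts), as.matrix(s2$raster$counts))
  cfg2 <- sim_config(duration = 60, seed = 78, log_drive = "none")
  s3 <- simulate_network(nt, p, cfg2)
  expect_false(identical(as.matrix(s1$raster$counts),
                         as.matrix(s3$raster$counts)))
})

test_that("a single forced spike produces the closed-form filter response", {
  # silence the network (very negative bias), force one spike, compare the
  # logged drive with w_E exp(-t/tau_e) - w_I exp(-t/tau_i)
  nt <- tiny_neurons()[1:120, ]
  p <- optimized_params(mu = -25)
  cfg <- sim_config(duration = 40, seed = 3, bin_factor = 1L)
  W <- build_coupling(nt, p)
  src <- 5L
  t0_step <- 100L
  sim <- simulate_network(nt, p, cfg, coupling = W,
                          forced_spikes = data.frame(neuron = src,
                                                     step = t0_step,
                                                     count = 1))
  drive <- sim$drive # bin_factor 1: per-step recurrent drive
  dt <- cfg$dt_fast
  # probe a handful of target neurons at several lags
  lags <- c(1L, 2L, 5L, 20L)
  for (j in c(src, 6L, 30L)) {
    for (lag in lags) {
      t_s <- lag * dt
      expected_e <- W$E[src, j] * exp(-t_s / p$tau_e)
      got <- drive[j, t0_step + lag]
      # the slow inhibitory pathway ramps in within the window, so the
      # total can deviate from the excitatory closed form by at most the
      # (small) inhibitory weight
      expect_lt(abs(got - expected_e), W$I[src, j] + 1e-12)
    }
  }
  # after several slow windows the inhibitory part dominates: drive is
  # negative and decays with tau_i
  lag_slow <- round(12 / dt) # 12 s, past two knots
  val <- drive[6L, t0_step + lag_slow]
  expect_lt(val, 0)
  expected_i <- -W$I[src, 6L] * exp(-(12 - 2.5) / p$tau_i)
  expect_equal(val, expected_i, tolerance = 0.25)
})

test_that("two-timescale slow pathway tracks an exact fast computation", {
  # 200-neuron network, tau_i >= 10 dt_slow; compare the simulator's logged
  # recurrent drive against an exact per-step reconstruction from the spike
  # raster using the same spike history
  nt <- tiny_neurons()[1:200, ]
  p <- optimized_params(tau_i = 60)
  # zero-init so both computations share the same initial condition
  cfg <- sim_config(duration = 120, seed = 10, bin_factor = 1L,
                    init_inhibition = "zero")
  W <- build_coupling(nt, p)
  sim <- simulate_network(nt, p, cfg, coupling = W)
  counts <- as.matrix(sim$raster$counts)
  n <- nrow(counts); n_steps <- ncol(counts)
  dec_e <- exp(-cfg$dt_fast / p$tau_e)
  dec_i <- exp(-cfg$dt_fast / p$tau_i)
  WEt <- Matrix::t(W$E); WIt <- Matrix::t(W$I)
  eE <- numeric(n); iI <- numeric(n)
  exact <- matrix(0, n, n_steps)
  for (t in seq_len(n_steps)) {
    exact[, t] <- eE - iI
    y <- counts[, t]
    eE <- (eE + as.numeric(WEt %*% y)) * dec_e
    iI <- (iI + as.numeric(WIt %*% y)) * dec_i
  }
  got <- sim$drive
  # compare the slow (inhibitory-dominated) component over the second half,
  # after the filters are loaded
  idx <- (n_steps %/% 2):n_steps
  err <- mean(abs(got[, idx] - exact[, idx]))
  scale <- mean(abs(exact[, idx]))
  expect_lt(err / scale, 0.15)
})

test_that("inhibition-free network is tonically active at higher rate", {
  nt <- small_hemisphere()
  base <- small_sim()
  p0 <- optimized_params(g_i = 0)
  sim0 <- simulate_network(nt, p0, sim_config(duration = 240, discard = 120,
                                              seed = 303, log_drive = "none"))
  r0 <- binned_raster(sim0)
  rate0 <- sum(r0$counts) / nrow(r0$counts) / raster_duration(r0)
  rate1 <- sum(base$raster$counts) / nrow(base$raster$counts) /
    raster_duration(base$raster)
  expect_gt(rate0, 2 * rate1)
})
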