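# Receptive fields, protocols, external input, responsive cells,
# suppression and adaptation analyses.

test_that("noiseless Gaussian tuning is recovered exactly and exclusions apply", {
  a <- seq(-55, 55, by = 5)
  resp <- 3 * exp(-(a - 40)^2 / (2 * 10^2))
  f <- fit_receptive_field(a, resp)
  expect_equal(f$A, 3, tolerance = 1e-6)
  expect_equal(f$mu, 40, tolerance = 1e-4)
  expect_equal(f$sigma, 10, tolerance = 1e-4)
  expect_gt(f$r2, 0.9999)
  expect_false(f$excluded)
  # narrow tuning (sigma < 3 deg) is excluded
  f2 <- fit_receptive_field(a, 3 * exp(-a^2 / (2 * 2^2)))
  expect_true(f2$excluded)
  expect_equal(f2$reason, "narrow")
  # population-level low-peak exclusion at the 20th percentile
  set.seed(4)
  amps <- c(rep(0.1, 4), seq(1, 3, length.out = 16))
  tuning <- t(sapply(amps, function(A) A * exp(-(a - 10)^2 / (2 * 144))))
  fits <- fit_receptive_fields(tuning, a)
  expect_true(all(fits$excluded[fits$A < attr(fits, "peak_threshold")]))
  expect_equal(sum(fits$excluded), 4)
})

test_that("external input follows the scaled receptive-field formula", {
  rfs <- tibble::tibble(id = 1:2, A = c(2e-3, 1e-3), mu = c(0, 20),
                        sigma = c(10, 10), r2 = 1,
                        elevation = c("high", "high"),
                        excluded = c(FALSE, TRUE), reason = NA)
  proto <- build_protocol("single_isi", elevations = "high", isi = 60,
                          duration = 70, lead_in_s = 10)
  dt <- 0.05
  n_steps <- round(70 / dt)
  x <- make_external_input(rfs, proto, dt, n_steps)
  # alpha(t) = -55 + 20 t; alpha = mu_1 = 0 at t = 2.75 s after onset
  step_peak <- round((10 + 2.75) / dt) + 1L
  expect_equal(x[1, step_peak], 2.5e3 * 2e-3, tolerance = 1e-3)
  # at alpha = mu + 0.8 sigma the drive is down by exp(-1/2)
  step_off <- round((10 + (0 + 0.8 * 10 + 55) / 20) / dt) + 1L
  expect_equal(x[1, step_off], 2.5e3 * 2e-3 * exp(-0.5), tolerance = 1e-2)
  # excluded receptive fields receive zero input
  expect_equal(sum(x[2, ]), 0)
  # input is zero outside sweeps
  before <- seq_len(round(10 / dt) - 1)
  expect_equal(sum(x[, before]), 0)
})

test_that("responsive-cell rule applies percentile and baseline-fold thresholds", {
  # 10-cell toy: rates constructed so membership is known by direct rule
  # application; strict inequality at the 90th percentile boundary
  nf <- 600L
  m <- matrix(0, 10, nf)
  # ongoing baseline: cell 1 fires steadily (high baseline)
  m[1, seq(1, nf, by = 2)] <- 1
  events <- tibble::tibble(onset = c(40, 80), elevation = "high")
  sweep_s <- 5
  # response frames for events at 40 s and 80 s (frame_dt 0.2): 201..226,
  # 401..426
  resp_frames <- c(201:226, 401:426)
  m[1, resp_frames] <- 1 # no increase over its own baseline
  m[2, resp_frames] <- 2 # strong response, near-zero baseline
  m[3, resp_frames] <- 1 # moderate response
  r <- spike_raster(m, 0.2)
  sets <- identify_responsive(r, events, sweep_s)
  # cell 2 has the top response and far exceeds 5x its floored baseline
  expect_true(2 %in% sets$high)
  # cell 1 fails the 5x-baseline rule despite responding
  expect_false(1 %in% sets$high)
  # a cell exactly at the population 90th percentile is not responsive
  rates <- attr(sets, "rates")
  thr <- quantile(rates[, "high"], 0.9, names = FALSE)
  at_thr <- which(abs(rates[, "high"] - thr) < 1e-12)
  expect_false(any(at_thr %in% sets$high))
})

test_that("protocols are deterministic and respect ISIs, breaks and blocks", {
  p1 <- build_protocol("single_isi", elevations = "high", isi = 300,
                       duration = 1800, lead_in_s = 60)
  p2 <- build_protocol("single_isi", elevations = "high", isi = 300,
                       duration = 1800, lead_in_s = 60)
  expect_identical(p1$events, p2$events)
  # 5-min ISI over 30 min with a 60 s lead-in: onsets 60, 360, ..., 1860 ->
  # but the last sweep must finish inside the session: 6 events
  expect_equal(nrow(p1$events), 6)
  expect_equal(diff(p1$events$onset), rep(300, 5))
  mx <- build_protocol("mixed_isi",
                       elevations = list(common = c("high", "low"),
                                         deviant = c("low", "high")),
                       n_blocks = 2)
  ev <- mx$events
  # commons respect the 30 s grid; no common within 90 s after a deviant
  for (b in 1:2) {
    dev <- ev$onset[ev$block == b & ev$role == "deviant"]
    com <- ev$onset[ev$block == b & ev$role == "common"]
    for (d in dev) {
      expect_false(any(com > d & com <= d + 90))
    }
  }
  # deviants every 5 min within the block
  expect_equal(diff(ev$onset[ev$block == 1 & ev$role == "deviant"]),
               rep(300, 4))
  # infeasible config: break longer than the block
  expect_error(build_protocol("mixed_isi",
                              elevations = list(common = "a", deviant = "b"),
                              n_blocks = 1, block_s = 60, break_s = 90),
               "break")
  # empty stimulation config: rest-only protocol has zero events
  p0 <- build_protocol("single_isi", elevations = "high", isi = 600,
                       duration = 500, lead_in_s = 600)
  expect_equal(nrow(p0$events), 0)
})

test_that("post-stimulus suppression normalises activity as stated", {
  nt <- tiny_neurons()
  nf <- 1000L
  set.seed(6)
  # stationary raster with no stimulus effect: values near 1
  m <- matrix(rpois(nrow(nt) * nf, 0.4), nrow(nt))
  r <- spike_raster(m, 0.2)
  events <- tibble::tibble(onset = c(50, 120), elevation = "high")
  sets <- list(high = 1:50, low = 51:100)
  out <- post_stimulus_suppression(r, events, sets, sweep_s = 5)
  agg <- out[is.na(out$event), ]
  expect_true(all(abs(agg$value - 1) < 0.15))
  # hand-built 50% rate drop in the first window gives value 0.5
  m2 <- matrix(2, 20, nf)
  ev2 <- tibble::tibble(onset = 100, elevation = "high")
  # windows: offset at 105 s -> frames 526..575 for 0-10 s
  m2[, 526:575] <- 1
  r2 <- spike_raster(m2, 0.2)
  out2 <- post_stimulus_suppression(r2, ev2, list(high = 1:20), sweep_s = 5,
                                    windows = list(c(0, 10)))
  agg2 <- out2[is.na(out2$event), ]
  expect_equal(agg2$value, 0.5, tolerance = 0.02)
})

test_that("adaptation gain decays for commons and recovers during breaks", {
  mx <- build_protocol("mixed_isi",
                       elevations = list(common = c("high", "low"),
                                         deviant = c("low", "high")),
                       n_blocks = 2)
  g <- adaptation_gain(mx)
  ev <- mx$events
  expect_true(all(g[ev$role == "deviant"] == 1))
  com1 <- which(ev$role == "common" & ev$block == 1)
  # monotone-ish decay towards the plateau within an uninterrupted run
  expect_lt(g[com1[8]], g[com1[2]])
  expect_gt(min(g), 0.45)
  # partial recovery after a 90 s break: the first common after a deviant
  # has higher gain than the last one before it
  dev1 <- ev$onset[ev$role == "deviant" & ev$block == 1][1]
  before <- max(com1[ev$onset[com1] < dev1])
  after <- min(com1[ev$onset[com1] > dev1 + 90])
  expect_gt(g[after], g[before])
  # gains are deterministic
  expect_identical(g, adaptation_gain(mx))
})

test_that("modulation analysis returns per-cell baselines and a regression", {
  # synthetic responses: common responses in block 2 attenuated by 30%
  nt <- tiny_neurons()
  mx <- build_protocol("mixed_isi",
                       elevations = list(common = c("low", "high"),
                                         deviant = c("high", "low")),
                       n_blocks = 2, block_s = 600, rest_s = 120,
                       lead_in_s = 60, deviant_isi = 200,
                       baseline_block = TRUE, baseline_s = 400)
  ev <- mx$events
  nf <- ceiling((mx$duration + 60) / 0.2)
  m <- matrix(0, nrow(nt), nf)
  amp <- runif(nrow(nt), 0.5, 2)
  for (k in seq_len(nrow(ev))) {
    f0 <- floor(ev$onset[k] / 0.2) + 1L
    gain <- if (ev$elevation[k] == "high" && ev$block[k] == 2) 0.7 else 1
    m[, f0:(f0 + 27L)] <- m[, f0:(f0 + 27L)] +
      matrix(rpois(nrow(nt) * 28, amp * gain / 4), nrow(nt))
  }
  r <- spike_raster(m, 0.2)
  rm <- response_modulation(r, mx, block = 2)
  pc <- rm$per_cell
  com <- pc[pc$stimulus == "common", ] # high elevation in block 2
  dev <- pc[pc$stimulus == "deviant", ]
  expect_equal(mean(com$ratio, na.rm = TRUE), 0.7, tolerance = 0.1)
  expect_equal(mean(dev$ratio, na.rm = TRUE), 1.0, tolerance = 0.1)
  expect_s3_class(rm$regression, "lm")
  # attenuation magnitude correlates with baseline response
  expect_lt(coef(rm$regression)[2], 0)
})
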