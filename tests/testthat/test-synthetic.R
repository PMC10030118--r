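# Synthetic data generation, fluorescence preprocessing and persistence.

test_that("position generation is reproducible with correct counts and spacing", {
  nt <- generate_positions(100, seed = 1)
  expect_equal(nrow(nt), 200)
  expect_equal(unname(table(nt$hemisphere)["L"]), 100, ignore_attr = TRUE)
  expect_true(all(is.finite(nt$x)))
  expect_equal(nt$id, seq_len(200))
  # minimum pairwise distance respects the exclusion radius (brute force)
  d <- as.matrix(dist(nt[, c("x", "y", "z")]))
  diag(d) <- Inf
  expect_gte(min(d), 4)
  # reproducible
  nt2 <- generate_positions(100, seed = 1)
  expect_identical(nt$x, nt2$x)
  # hemispheres on opposite sides of the midline
  expect_true(all(nt$x[nt$hemisphere == "L"] < 0))
  expect_true(all(nt$x[nt$hemisphere == "R"] > 0))
  # projected coordinates present and finite
  expect_true(all(is.finite(nt$ap)) && all(is.finite(nt$ml)))
})

test_that("implanted receptive fields separate elevations anatomically", {
  nt <- small_hemisphere()
  rfs <- implant_receptive_fields(nt, seed = 3)
  expect_equal(nrow(rfs), nrow(nt))
  hi <- nt$ap[rfs$elevation == "high"]
  lo <- nt$ap[rfs$elevation == "low"]
  # bands along the anterior-posterior axis are disjoint
  expect_true(max(hi) <= min(lo) || max(lo) <= min(hi))
  # tuning widths: population 2.5 sigma near 38 degrees
  expect_equal(mean(2.5 * rfs$sigma), 38, tolerance = 0.15)
})

test_that("surrogate datasets break history-dependent burst structure", {
  # a memoryless surrogate still produces chance coincidence clusters, but
  # they carry no post-event suppression; the simulator's bursts do
  cfg <- synthetic_config(n_per_hemisphere = 600, seed = 8,
                          mode = "surrogate")
  ds <- generate_dataset(cfg, duration = 420, discard = 120,
                         hemisphere = "L")
  bursts <- detect_bursts(ds$raster, ds$neurons)
  sim_ds <- generate_dataset(synthetic_config(n_per_hemisphere = 600,
                                              seed = 8),
                             duration = 420, discard = 120,
                             hemisphere = "L")
  sim_bursts <- detect_bursts(sim_ds$raster, sim_ds$neurons)
  ratio <- function(b, r) {
    s <- burst_statistics(b, r, seed = 2)$suppression
    post <- mean(s$value[s$lag_s > 5 & s$lag_s <= 40])
    pre <- mean(s$value[s$lag_s < -5 & s$lag_s >= -40])
    post / pre
  }
  expect_gt(nrow(sim_bursts), 3)
  r_sim <- ratio(sim_bursts, sim_ds$raster)
  expect_lt(r_sim, 0.9)
  if (nrow(bursts) > 3) {
    r_sur <- ratio(bursts, ds$raster)
    expect_gt(r_sur, r_sim)
    expect_gt(r_sur, 0.8)
  }
})

test_that("simulator datasets carry aligned ground-truth drive", {
  cfg <- synthetic_config(n_per_hemisphere = 400, seed = 9)
  ds <- generate_dataset(cfg, duration = 380, discard = 100, n_events = 3)
  expect_equal(ncol(ds$drive), n_frames(ds$raster))
  expect_equal(attr(ds$drive, "frame_dt"), ds$raster$frame_dt)
  expect_equal(nrow(ds$drive), nrow(ds$neurons))
  expect_true(all(ds$events$time > ds$raster$t0 + 60))
  expect_true(all(ds$events$time < ds$raster$t0 + raster_duration(ds$raster)))
})

test_that("dF/F0 baseline, drift exclusion and the forward model behave", {
  # constant trace: F0 = c, dFF = 0, ROI kept
  out <- dff_preprocess(matrix(100, 2, 60))
  expect_true(all(out$f0 == 100))
  expect_true(all(abs(out$dff) < 1e-12))
  expect_true(all(out$kept))
  # constructed drift: a linear baseline ramp whose mean-normalised F0
  # standard deviation exceeds 0.45 is discarded (oracle: direct SD)
  tt <- seq_len(400)
  ramp <- 100 * (1 + 9 * tt / 400)
  flat <- rep(100, 400)
  f <- rbind(ramp, flat)
  out2 <- dff_preprocess(f)
  norm_sd <- sd((ramp) / mean(ramp)) # F0 tracks the ramp closely
  expect_gt(norm_sd, 0.45)
  expect_false(out2$kept[1])
  expect_true(out2$kept[2])
  # window longer than trace rejected
  expect_error(dff_preprocess(matrix(10, 1, 10), window = 20), "window")
  # forward calcium model produces positive fluorescence that dF/F0 keeps
  r <- spike_raster(matrix(rpois(10 * 200, 0.2), 10), 0.2)
  fl <- simulate_fluorescence(r, seed = 2)
  expect_true(all(fl > 0))
  out3 <- dff_preprocess(fl)
  expect_gte(sum(out3$kept), 9)
})

test_that("persistence round-trips are the identity", {
  td <- withr::local_tempdir()
  nt <- generate_positions(50, seed = 4)
  write_neurons(nt, file.path(td, "n.csv"))
  nt2 <- read_neurons(file.path(td, "n.csv"))
  expect_equal(nt2$hemisphere, nt$hemisphere)
  expect_equal(nt2$x, nt$x, tolerance = 1e-12)
  set.seed(5)
  r <- spike_raster(matrix(rpois(50 * 80, 0.5), 50), 0.2, t0 = 12)
  write_raster(r, file.path(td, "r.mtx"))
  r2 <- read_raster(file.path(td, "r.mtx"))
  expect_identical(as.matrix(r2$counts), as.matrix(r$counts))
  expect_equal(r2$frame_dt, 0.2)
  expect_equal(r2$t0, 12)
  p <- optimized_params()
  write_params(p, file.path(td, "p.yaml"))
  p2 <- read_params(file.path(td, "p.yaml"))
  expect_equal(unclass(p2), unclass(p))
  ev <- tibble::tibble(time = c(10.5, 80.25))
  write_events(ev, file.path(td, "e.json"))
  expect_equal(read_events(file.path(td, "e.json"))$time, ev$time)
  # schema validation names the missing column
  bad <- nt[, setdiff(names(nt), "hemisphere")]
  utils::write.csv(bad, file.path(td, "bad.csv"), row.names = FALSE)
  expect_error(read_neurons(file.path(td, "bad.csv")), "hemisphere")
  # bundle round trip
  ds <- list(neurons = nt, raster = r, events = ev, params = p)
  write_bundle(ds, file.path(td, "bundle"))
  back <- read_bundle(file.path(td, "bundle"))
  expect_identical(as.matrix(back$raster$counts), as.matrix(r$counts))
  expect_equal(back$events$time, ev$time)
})

test_that("plot constructors return ggplot objects", {
  dat <- small_sim()
  bursts <- detect_bursts(dat$raster, dat$neurons)
  stats <- burst_statistics(bursts, dat$raster, seed = 2)
  expect_s3_class(autoplot(stats, "size"), "ggplot")
  expect_s3_class(autoplot(stats, "suppression"), "ggplot")
  expect_s3_class(plot_raster(dat$raster, dat$neurons), "ggplot")
})
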