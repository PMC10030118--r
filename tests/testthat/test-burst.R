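# Burst detection: population peaks, density clustering, Poisson-filtered
# extents, statistics.

test_that("population peaks are local maxima of the smoothed trace", {
  nt <- tiny_neurons()[1:40, ]
  # flat raster: no peaks
  flat <- spike_raster(matrix(1, 40, 50), 0.2)
  expect_length(find_population_peaks(flat, nt), 0)
  # one isolated bump: exactly one peak at the apex (brute-force argmax)
  m <- matrix(0, 40, 60)
  m[, 30] <- 3; m[, 29] <- 1; m[, 31] <- 1
  r <- spike_raster(m, 0.2)
  peaks <- find_population_peaks(r, nt)
  sm <- numeric(60)
  trace <- colMeans(m)
  for (t in 1:60) sm[t] <- mean(trace[max(1, t - 1):min(60, t + 1)])
  expect_equal(peaks, which.max(sm))
  # empty raster
  expect_length(find_population_peaks(spike_raster(matrix(0, 40, 50), 0.2), nt), 0)
})

test_that("bilateral activation peaks are excluded", {
  nt <- tiny_neurons() # 200 per hemisphere
  n <- nrow(nt)
  m <- matrix(0, n, 40)
  # 12% of neurons active, split 50/50 across hemispheres, at frame 20
  left <- which(nt$hemisphere == "L")[1:24]
  right <- which(nt$hemisphere == "R")[1:24]
  m[c(left, right), 20] <- 2
  r <- spike_raster(m, 0.2)
  expect_length(find_population_peaks(r, nt), 0)
  # same activation confined to one hemisphere: retained
  # same activation confined to one hemisphere: retained (smoothing makes a
  # 3-frame plateau; the first plateau frame is reported)
  m2 <- matrix(0, n, 40)
  m2[which(nt$hemisphere == "L")[1:48], 20] <- 2
  expect_equal(find_population_peaks(spike_raster(m2, 0.2), nt), 19L)
})

test_that("density clustering matches the exhaustive density-connectivity oracle", {
  set.seed(11)
  for (rep in 1:6) {
    n <- sample(30:180, 1)
    # mixture of a few tight groups plus scattered noise
    k <- sample(1:3, 1)
    centres <- matrix(runif(3 * k, 0, 120), ncol = 3)
    pts <- do.call(rbind, lapply(seq_len(k), function(g) {
      sweep(matrix(rnorm(3 * 20, 0, 4), ncol = 3), 2, centres[g, ], `+`)
    }))
    pts <- rbind(pts, matrix(runif(3 * (n %% 23 + 5), 0, 120), ncol = 3))
    labs <- tectalnp:::dbscan_labels(pts, eps = 15, min_pts = 12)
    oracle <- brute_dbscan(pts, eps = 15, min_pts = 12)
    # core-point partitioning must agree exactly (border points may attach
    # to either adjacent cluster under DBSCAN semantics; compare cores)
    d <- as.matrix(dist(pts))
    core <- rowSums(d <= 15) >= 12
    expect_equal(cluster_sets(ifelse(core, labs, 0L)),
                 cluster_sets(ifelse(core, oracle, 0L)))
    # noise/cluster status must agree everywhere
    expect_equal(labs > 0, oracle > 0)
  }
})

test_that("clustering of active cells follows MinPts and eps rules", {
  nt <- tiny_neurons()
  n <- nrow(nt)
  # pick 15 mutually close cells (within a 10 um ball) by construction
  centre <- c(mean(nt$x[nt$hemisphere == "L"]), mean(nt$y), mean(nt$z))
  d2 <- (nt$x - centre[1])^2 + (nt$y - centre[2])^2 + (nt$z - centre[3])^2
  close15 <- order(d2)[1:15]
  m <- matrix(0, n, 20)
  m[close15, 10] <- 1
  r <- spike_raster(m, 0.2)
  cl <- cluster_burst_cells(10L, r, nt, eps = 15, min_pts = 12)
  expect_length(cl, 1)
  expect_setequal(cl[[1]], close15)
  # 11 co-located active cells cannot reach MinPts = 12
  m2 <- matrix(0, n, 20)
  m2[close15[1:11], 10] <- 1
  expect_length(cluster_burst_cells(10L, spike_raster(m2, 0.2), nt,
                                    eps = 15, min_pts = 12), 0)
  # no active cells
  expect_length(cluster_burst_cells(5L, spike_raster(matrix(0, n, 20), 0.2),
                                    nt, 15, 12), 0)
})

test_that("MinPts selection returns small values for sparse independent spiking", {
  nt <- tiny_neurons()
  set.seed(33)
  m <- matrix(rpois(nrow(nt) * 250, 0.02), nrow(nt))
  r <- spike_raster(m, 0.2)
  mp <- select_min_pts(r, nt, candidates = 4:14, n_perms = 2, seed = 5)
  expect_true(is.finite(mp) && mp <= 12)
  # single-neuron raster: no clusters possible at any candidate
  r1 <- spike_raster(matrix(rpois(300, 0.5), 1), 0.2)
  nt1 <- nt[1, ]
  expect_true(is.finite(select_min_pts(r1, nt1, candidates = 2:4,
                                       n_perms = 1, seed = 1)))
})

test_that("burst extent applies the Poisson CDF filter as an exact oracle", {
  nt <- tiny_neurons()
  cluster <- 1:10
  nfr <- 80
  m <- matrix(0, nrow(nt), nfr)
  # uniform activity: every cell fires 1 spike per frame in frames 35..45
  m[cluster, 35:45] <- 1
  r <- spike_raster(m, 0.2)
  ext <- burst_extent(cluster, r, peak_frame = 40L)
  expect_false(ext$degenerate)
  # window counts equal the cluster mean, so nothing is discarded:
  # smallest k with ppois(k, lambda) >= 0.6 is >= lambda for integer counts
  # here; the filtered trace is non-zero across the active period
  expect_lte(ext$t_init, 35 + 2)
  expect_gte(ext$t_term, 45 - 3)
  expect_lte(ext$t_init, 40)
  expect_gte(ext$t_term, 40)
  # an outlier cell with 20 spikes against cluster mean ~1 is discarded:
  # exhaustive CDF evaluation gives the threshold
  win <- m[cluster, 38:43]
  win[1, ] <- 0; win[1, 1] <- 20
  lambda <- mean(rowSums(win))
  kmax <- min(which(ppois(0:40, lambda) >= 0.6)) - 1L
  expect_lt(kmax, 20)
  m2 <- m
  m2[cluster[1], 35:45] <- 0
  m2[cluster[1], 38] <- 20
  ext2 <- burst_extent(cluster, spike_raster(m2, 0.2), peak_frame = 40L)
  # the outlier's windows lose that cell but remain non-degenerate
  expect_false(ext2$degenerate)
  # silent cluster: degenerate extent flagged
  ext3 <- burst_extent(cluster, spike_raster(matrix(0, nrow(nt), nfr), 0.2),
                       peak_frame = 40L)
  expect_true(ext3$degenerate)
})

test_that("every burst extent contains its peak and spikes lie within it", {
  dat <- small_sim()
  bursts <- detect_bursts(dat$raster, dat$neurons)
  expect_gt(nrow(bursts), 0)
  expect_true(all(bursts$t_init <= bursts$peak_frame))
  expect_true(all(bursts$peak_frame <= bursts$t_term))
  expect_true(all(bursts$size >= 12))
  expect_true(all(bursts$duration > 0))
})

test_that("burst counts add across concatenated sessions", {
  dat <- small_sim()
  r <- dat$raster
  n1 <- nrow(detect_bursts(r, dat$neurons))
  nf <- n_frames(r)
  half1 <- spike_raster(r$counts[, 1:(nf %/% 2)], r$frame_dt)
  half2 <- spike_raster(r$counts[, (nf %/% 2 + 1):nf], r$frame_dt)
  n_a <- nrow(detect_bursts(half1, dat$neurons))
  n_b <- nrow(detect_bursts(half2, dat$neurons))
  # concatenation equals the sum up to boundary effects at the split frame
  expect_lt(abs(n1 - (n_a + n_b)), 4)
})

test_that("burst statistics summarise rates and single events correctly", {
  nt <- tiny_neurons()
  # one hand-built burst of 10 neurons in a 1-minute raster
  m <- matrix(0, nrow(nt), 300)
  anchor <- which(nt$hemisphere == "L")[1]
  d2 <- (nt$x - nt$x[anchor])^2 + (nt$y - nt$y[anchor])^2 +
    (nt$z - nt$z[anchor])^2
  centre <- order(d2)[1:10]
  m[centre, 148:152] <- 2
  r <- spike_raster(m, 0.2)
  bursts <- detect_bursts(r, nt, min_pts = 8)
  expect_equal(nrow(bursts), 1)
  stats <- burst_statistics(bursts, r, seed = 4)
  expect_equal(stats$rate_per_min, 1)
  # size histogram mass in the bin containing 10
  hit <- stats$size_hist[stats$size_hist$count > 0, ]
  expect_equal(nrow(hit), 1)
  expect_lt(abs(hit$log10_mid - log10(10)), 1 / 8)
  # zero bursts: empty statistics
  empty <- burst_statistics(bursts[0, ], r)
  expect_equal(empty$rate_per_min, 0)
  expect_null(empty$suppression)
})

test_that("simulated bursting shows post-burst suppression of participants", {
  dat <- small_sim()
  bursts <- detect_bursts(dat$raster, dat$neurons)
  stats <- burst_statistics(bursts, dat$raster, seed = 7)
  s <- stats$suppression
  post <- mean(s$value[s$lag_s > 5 & s$lag_s <= 40])
  pre <- mean(s$value[s$lag_s < -5 & s$lag_s >= -40])
  peak <- max(s$value[abs(s$lag_s) <= 1])
  # activity peaks at the burst and is lower after it than before
  expect_gt(peak, pre)
  expect_lt(post, pre)
})
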