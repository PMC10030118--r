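# Burst-level statistics: rates, log-binned size/duration histograms,
# burst-triggered suppression and participation profiles.

# Fixed decade grids (8 bins per decade) so curves from different
# simulations are comparable bin-by-bin.
size_breaks <- function() 10^seq(0, 4, by = 1 / 8)
duration_breaks <- function() 10^seq(-1, 2.5, by = 1 / 8)

log_binned_rates <- function(values, breaks, duration_min) {
  counts <- graphics::hist(values[values >= breaks[1] &
                                    values <= breaks[length(breaks)]],
                           breaks = breaks, plot = FALSE)$counts
  mid <- sqrt(breaks[-1] * breaks[-length(breaks)])
  rate <- counts / duration_min
  tibble(mid = mid, log10_mid = log10(mid), count = counts, rate = rate,
         log10_rate = ifelse(counts > 0, log10(rate), NA_real_))
}

# Triggered average of matrix rows around event frames.
# events: tibble(neuron, frame). Returns per-lag mean across (event) pairs,
# with edge-clipped denominators.
triggered_average <- function(mat, events, lags, weights = NULL) {
  nf <- ncol(mat)
  acc <- numeric(length(lags))
  denom <- numeric(length(lags))
  w <- if (is.null(weights)) rep(1, nrow(events)) else weights
  for (k in seq_len(nrow(events))) {
    fr <- events$frame[k] + lags
    ok <- fr >= 1L & fr <= nf
    vals <- as.numeric(mat[events$neuron[k], fr[ok]])
    acc[ok] <- acc[ok] + w[k] * vals
    denom[ok] <- denom[ok] + w[k]
  }
  acc / pmax(denom, 1e-12)
}

#' Burst statistics and burst-triggered profiles
#'
#' Summarises a detected burst table: the burst rate (bursts per minute),
#' log-binned rate histograms of burst sizes and durations (fixed decade
#' grid, 8 bins per decade), the post-burst activity suppression profile
#' (burst-triggered mean spiking of participating neurons, normalised per
#' neuron by its mean activity at randomly sampled trigger times), and the
#' burst-participation profile (burst-triggered probability that a
#' participant takes part in another burst, normalised by a circular
#' permutation of burst times).
#'
#' @param bursts A [detect_bursts()] table.
#' @param raster The raster the bursts were detected in.
#' @param lag_max_s Profile half-width, seconds (default 60).
#' @param n_random Random trigger times per neuron for the suppression
#'   baseline (default 100).
#' @param n_null Circular permutations for the participation null
#'   (default 20).
#' @param seed Seed for the random triggers and permutations.
#' @return An object of class `burst_statistics`: a list with `rate_per_min`,
#'   `size_hist`, `duration_hist` (tibbles), `suppression` and
#'   `participation` (tibbles with `lag_s` and normalised `value`), and
#'   `n_bursts`. With zero bursts the histograms are empty and the profiles
#'   are `NULL`.
#' @export
burst_statistics <- function(bursts, raster, lag_max_s = 60,
                             n_random = 100L, n_null = 20L, seed = 1L) {
  dur_min <- raster_duration(raster) / 60
  if (dur_min <= 0) abort("raster has zero duration")
  out <- list(n_bursts = nrow(bursts), rate_per_min = nrow(bursts) / dur_min,
              size_hist = log_binned_rates(numeric(0), size_breaks(), dur_min),
              duration_hist = log_binned_rates(numeric(0), duration_breaks(),
                                               dur_min),
              suppression = NULL, participation = NULL)
  class(out) <- "burst_statistics"
  if (nrow(bursts) == 0L) return(out)
  out$size_hist <- log_binned_rates(bursts$size, size_breaks(), dur_min)
  out$duration_hist <- log_binned_rates(bursts$duration, duration_breaks(),
                                        dur_min)

  lag_frames <- round(lag_max_s / raster$frame_dt)
  lags <- seq(-lag_frames, lag_frames)
  pairs <- tibble(
    neuron = unlist(bursts$members),
    frame = rep.int(bursts$peak_frame, vapply(bursts$members, length,
                                              integer(1))))
  nf <- n_frames(raster)
  # per-neuron random-trigger baseline ~ mean rate over random frames
  participants <- sort(unique(pairs$neuron))
  base <- with_seed(child_seed(seed, 1L), {
    vapply(participants, function(i) {
      fr <- sample.int(nf, n_random, replace = TRUE)
      mean(as.numeric(raster$counts[i, fr]))
    }, numeric(1))
  })
  base <- pmax(base, 1 / nf) # floor: one spike per session
  base_of <- setNames(base, participants)
  norm_counts <- raster$counts[participants, , drop = FALSE] / base
  idx_of <- setNames(seq_along(participants), participants)
  pairs_idx <- tibble(neuron = idx_of[as.character(pairs$neuron)],
                      frame = pairs$frame)
  supp <- triggered_average(norm_counts, pairs_idx, lags)
  out$suppression <- tibble(lag_s = lags * raster$frame_dt, value = supp)

  # participation: sparse indicator of (member, peak frame)
  P <- sparseMatrix(i = pairs_idx$neuron, j = pmin(pmax(pairs$frame, 1L), nf),
                    x = 1, dims = c(length(participants), nf))
  P@x[] <- pmin(P@x, 1)
  part <- triggered_average(P, pairs_idx, lags)
  null_prof <- matrix(0, n_null, length(lags))
  offs <- with_seed(child_seed(seed, 2L), sample.int(nf, n_null))
  for (k in seq_len(n_null)) {
    shifted <- pairs_idx
    shifted$frame <- ((pairs$frame - 1L + offs[k]) %% nf) + 1L
    Pn <- sparseMatrix(i = shifted$neuron, j = shifted$frame, x = 1,
                       dims = c(length(participants), nf))
    Pn@x[] <- pmin(Pn@x, 1)
    null_prof[k, ] <- triggered_average(Pn, shifted, lags)
  }
  null_mean <- pmax(colMeans(null_prof), 1e-12)
  out$participation <- tibble(lag_s = lags * raster$frame_dt,
                              value = part / null_mean)
  out
}

#' @export
print.burst_statistics <- function(x, ...) {
  cat(sprintf("Burst statistics: %d bursts, %.3g per minute\n",
              x$n_bursts, x$rate_per_min))
  invisible(x)
}

#' Objective curves for model calibration
#'
#' Computes the three calibration objectives from a detected burst table:
#' (a) log-rates of bursts binned by the logarithm of size, (b) log-rates
#' binned by the logarithm of duration, and (c) the burst-triggered mean
#' spiking of participating neurons (averaged per neuron over the bursts it
#' participated in, then across neurons), spline-smoothed and scaled to
#' `[0, 1]` by its own 5th and 95th percentiles.
#'
#' @inheritParams burst_statistics
#' @param lag_max_s Half-width of the suppression timecourse, seconds.
#' @return An object of class `objective_set`: list with `size` and
#'   `duration` (tibbles with `log10_mid`, `log10_rate`) and `suppression`
#'   (tibble with `lag_s`, `value` scaled to `[0, 1]`), or `NULL` curves if
#'   no bursts were found.
#' @export
objective_curves <- function(bursts, raster, lag_max_s = 40) {
  dur_min <- raster_duration(raster) / 60
  if (nrow(bursts) == 0L) {
    out <- list(size = NULL, duration = NULL, suppression = NULL)
    class(out) <- "objective_set"
    return(out)
  }
  size <- log_binned_rates(bursts$size, size_breaks(), dur_min)
  duration <- log_binned_rates(bursts$duration, duration_breaks(), dur_min)

  lag_frames <- round(lag_max_s / raster$frame_dt)
  lags <- seq(-lag_frames, lag_frames)
  # average per neuron over its own bursts, then across neurons
  members <- unlist(bursts$members)
  frames <- rep.int(bursts$peak_frame,
                    vapply(bursts$members, length, integer(1)))
  per_neuron <- split(frames, members)
  prof_acc <- numeric(length(lags))
  nf <- n_frames(raster)
  n_used <- 0L
  for (nm in names(per_neuron)) {
    i <- as.integer(nm)
    fr <- per_neuron[[nm]]
    ev <- tibble(neuron = 1L, frame = fr)
    prof_acc <- prof_acc +
      triggered_average(raster$counts[i, , drop = FALSE], ev, lags)
    n_used <- n_used + 1L
  }
  prof <- prof_acc / n_used
  sm <- tryCatch(
    stats::predict(stats::smooth.spline(lags, prof), lags)$y,
    error = function(e) prof)
  q <- quantile(sm, c(0.05, 0.95), names = FALSE)
  scaled <- if (diff(q) > 0) (sm - q[1]) / (q[2] - q[1]) else sm * 0
  out <- list(size = size[, c("log10_mid", "log10_rate")],
              duration = duration[, c("log10_mid", "log10_rate")],
              suppression = tibble(lag_s = lags * raster$frame_dt,
                                   value = scaled))
  class(out) <- "objective_set"
  out
}

#' Reference objective curves from published bursting statistics
#'
#' Constructs synthetic calibration targets shaped like the burst
#' statistics of larval zebrafish tecta: power-law size and duration
#' distributions (log-binned log-rates falling linearly in log-log space)
#' whose total rate matches the observed ~46 bursts/min scaled to the
#' network size, and a burst-triggered activity timecourse that peaks at
#' the burst, dips below its pre-burst level afterwards and recovers over
#' tens of seconds, scaled to `[0, 1]`.
#'
#' @param n_neurons Network size the targets are scaled to (the observed
#'   rate refers to ~14,733 cells).
#' @param rate_per_min Total burst rate at full scale (default 46).
#' @param size_range,duration_range Supports of the power laws (defaults
#'   12..1200 neurons and 0.8..25 s).
#' @param size_exponent,duration_exponent Power-law exponents (defaults
#'   1.5 and 2).
#' @param lag_max_s Half-width of the suppression timecourse (default 40).
#' @return An `objective_set` like [objective_curves()] returns.
#' @export
reference_objectives <- function(n_neurons, rate_per_min = 46,
                                 size_range = c(12, 1200),
                                 duration_range = c(0.8, 25),
                                 size_exponent = 1.5,
                                 duration_exponent = 2,
                                 lag_max_s = 40) {
  scaled_rate <- rate_per_min * n_neurons / 14733
  power_law_curve <- function(breaks, rng, alpha, total_rate) {
    mid <- sqrt(breaks[-1] * breaks[-length(breaks)])
    in_rng <- mid >= rng[1] & mid <= rng[2]
    w <- numeric(length(mid))
    # probability mass per log-bin of a power law p(x) ~ x^-alpha
    w[in_rng] <- mid[in_rng]^(1 - alpha)
    w <- w / sum(w)
    rate <- w * total_rate
    tibble(log10_mid = log10(mid),
           log10_rate = ifelse(rate > 0, log10(rate), NA_real_))
  }
  size <- power_law_curve(size_breaks(), size_range, size_exponent,
                          scaled_rate)
  duration <- power_law_curve(duration_breaks(), duration_range,
                              duration_exponent, scaled_rate)
  lags <- seq(-lag_max_s, lag_max_s, by = 0.2)
  base <- 0.25
  prof <- base +
    0.9 * exp(-lags^2 / (2 * 0.8^2)) -
    ifelse(lags > 0, 0.15 * (1 - exp(-lags / 5)) * exp(-lags / 25), 0)
  q <- quantile(prof, c(0.05, 0.95), names = FALSE)
  out <- list(size = size, duration = duration,
              suppression = tibble(lag_s = lags,
                                   value = (prof - q[1]) / (q[2] - q[1])))
  class(out) <- "objective_set"
  out
}
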