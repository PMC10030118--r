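# Synthetic dataset generation: the simulator doubles as the generator so
# ground-truth drive is available; a surrogate-Poisson mode provides
# history-independent negative controls.

#' Synthetic dataset configuration
#'
#' Bundles the knobs of the synthetic-data generator. Tiers: `tiny`
#' (200 neurons per hemisphere, minutes of data; fast checks), `standard`
#' (1,500 per hemisphere; the scale used by the package's own analyses),
#' `full` (7,366 per hemisphere, approximating the full-scale network of
#' ~1.4e4 cells).
#'
#' @param n_per_hemisphere Neurons per hemisphere.
#' @param density Cells per um^3 (default 1/180; about 5.7 um spacing,
#'   matching densely packed periventricular somata).
#' @param gap Midline gap, um.
#' @param mode `"simulator"` (default; rasters generated by the recurrent
#'   network, ground-truth drive logged) or `"surrogate"` (independent
#'   Poisson spike trains matched in mean rate; breaks every
#'   history-dependent effect).
#' @param seed Master seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_hemisphere = 1500, density = 1 / 180,
                             gap = 40, mode = c("simulator", "surrogate"),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (n_per_hemisphere <= 0) abort("`n_per_hemisphere` must be positive")
  structure(list(n_per_hemisphere = n_per_hemisphere, density = density,
                 gap = gap, mode = mode, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a complete synthetic dataset
#'
#' Produces everything the analysis pipeline consumes: neuron positions,
#' an imaging-equivalent spike raster, optional event times, the
#' ground-truth recurrent drive (simulator mode), and optionally implanted
#' Gaussian receptive fields converted to external input under a stimulus
#' protocol.
#'
#' In simulator mode the raster is the binned output of
#' [simulate_network()]; in surrogate mode each neuron fires as an
#' independent homogeneous Poisson process with the rate profile of a
#' reference simulation (default `exp(mu)` per step), which preserves
#' first-order statistics but removes all history dependence.
#'
#' Saccade-like event times, if requested, are sampled preferentially at
#' times of high mean drive in the anterior quarter of the tectum
#' (probability proportional to `exp(beta * mean anterior drive)`),
#' emulating the link between excitability and spontaneous behaviour; in
#' surrogate mode they are uniform.
#'
#' @param config [synthetic_config()].
#' @param params [model_params()] (default [optimized_params()]).
#' @param duration Raster length, s.
#' @param discard Warm-up discard, s (default 120).
#' @param protocol Optional [build_protocol()]; implants receptive fields
#'   and drives the network with the corresponding external input.
#' @param n_events Number of saccade-like ongoing events to sample
#'   (default 0).
#' @param event_beta Sharpness of the drive preference for event sampling
#'   (default 2).
#' @param event_spacing Minimum separation between events, s (default 75,
#'   so that 60 s history windows do not overlap).
#' @param hemisphere `"both"` (default) or `"L"`/`"R"` for a single
#'   hemisphere.
#' @param rf_elevations Elevation labels used when implanting receptive
#'   fields (default `c("high", "low")`).
#' @return A list of class `synthetic_dataset`: `neurons`, `raster`
#'   (imaging-equivalent, warm-up dropped), `drive` (ground-truth binned
#'   recurrent drive aligned to `raster`, simulator mode only), `events`
#'   (tibble with `time`), `rfs` (implanted receptive fields, if a
#'   protocol was given), `external_input` sparse matrix (if protocol),
#'   `params`, `config`, `sim` (the raw simulation object).
#' @export
generate_dataset <- function(config, params = optimized_params(), duration,
                             discard = 120, protocol = NULL, n_events = 0L,
                             event_beta = 2, event_spacing = 75,
                             hemisphere = "both",
                             rf_elevations = c("high", "low")) {
  neurons <- generate_positions(config$n_per_hemisphere,
                                density = config$density, gap = config$gap,
                                seed = child_seed(config$seed, 1L))
  if (hemisphere %in% c("L", "R")) {
    neurons <- neurons[neurons$hemisphere == hemisphere, ]
    neurons$id <- seq_len(nrow(neurons))
  }
  scfg <- sim_config(duration = duration, discard = discard,
                     seed = child_seed(config$seed, 2L))
  rfs <- NULL
  ext <- NULL
  if (!is.null(protocol)) {
    rfs <- implant_receptive_fields(neurons, rf_elevations,
                                    seed = child_seed(config$seed, 3L))
    n_steps <- round(duration / scfg$dt_fast)
    ext <- make_external_input(rfs, protocol, scfg$dt_fast, n_steps)
  }
  sim <- simulate_network(neurons, params, scfg, external_input = ext)
  raster <- binned_raster(sim)
  drive <- NULL
  if (!is.null(sim$drive)) {
    nb_drop <- sim$discard_frames %/% scfg$bin_factor
    drive <- sim$drive[, -(seq_len(nb_drop)), drop = FALSE]
    attr(drive, "frame_dt") <- attr(sim$drive, "frame_dt")
    attr(drive, "t0") <- nb_drop * attr(sim$drive, "frame_dt")
  }
  if (config$mode == "surrogate") {
    # homogeneous Poisson at the population mean rate: history-independent
    # and spatially structureless, so every history- or locality-dependent
    # effect (bursts, drive recovery, suppression) collapses
    rate_per_frame <- sum(raster$counts) / length(raster$counts)
    counts <- with_seed(child_seed(config$seed, 4L), {
      matrix(rpois(nrow(raster$counts) * n_frames(raster), rate_per_frame),
             nrow = nrow(raster$counts))
    })
    raster <- spike_raster(counts, frame_dt = raster$frame_dt, t0 = raster$t0)
  }
  events <- NULL
  if (n_events > 0L) {
    events <- tibble(time = sample_event_times(
      raster, drive, neurons, n_events, event_beta,
      surrogate = config$mode == "surrogate",
      seed = child_seed(config$seed, 5L), min_spacing = event_spacing))
  }
  structure(list(neurons = neurons, raster = raster, drive = drive,
                 events = events, rfs = rfs, external_input = ext,
                 params = params, config = config, sim = sim),
            class = "synthetic_dataset")
}

# Saccade-like event times: preferentially where mean anterior drive is
# high; min 70 s history and `min_spacing` seconds between events (wide
# spacing keeps 60 s estimation windows from overlapping, so per-event
# drive estimates are effectively independent).
sample_event_times <- function(raster, drive, neurons, n_events, beta,
                               surrogate = FALSE, seed = 1L,
                               min_spacing = 75) {
  t0 <- raster$t0
  t_end <- t0 + raster_duration(raster)
  cand <- seq(t0 + 70, t_end - 1, by = raster$frame_dt)
  if (!length(cand)) abort("raster too short to host events")
  w <- rep(1, length(cand))
  if (!surrogate && !is.null(drive)) {
    ant <- which(neurons$ap >= quantile(neurons$ap, 0.75))
    fd <- attr(drive, "frame_dt")
    dt0 <- attr(drive, "t0")
    idx <- pmin(pmax(floor((cand - dt0) / fd) + 1L, 1L), ncol(drive))
    ant_drive <- colMeans(drive[ant, , drop = FALSE])
    w <- exp(beta * scale(ant_drive[idx])[, 1])
  }
  with_seed(seed, {
    times <- numeric(0)
    tries <- 0L
    while (length(times) < n_events && tries < 500L) {
      t_new <- sample(cand, 1L, prob = w)
      if (!length(times) || min(abs(times - t_new)) >= min_spacing) {
        times <- c(times, t_new)
      }
      tries <- tries + 1L
    }
    if (length(times) < n_events) {
      # deterministic fill at evenly spaced free slots
      grid <- seq(min(cand), max(cand), by = min_spacing)
      for (g in grid) {
        if (length(times) >= n_events) break
        if (!length(times) || min(abs(times - g)) >= min_spacing) {
          times <- c(times, g)
        }
      }
      if (length(times) < n_events) {
        warn("could not place all events at the requested spacing")
      }
    }
    sort(times)
  })
}

#' Implant Gaussian azimuth tuning in a synthetic population
#'
#' Assigns each neuron a receptive field consistent with tectal
#' retinotopy: tuning widths are drawn so that the population width
#' (2.5 sigma) averages about 38 degrees with wide scatter, gains are
#' log-normal, and elevation preference forms bands along the
#' anterior-posterior axis with preferred azimuth mapping linearly onto
#' position within each band. In fish, elevation maps mediolaterally;
#' the synthetic generator uses the long anterior-posterior axis for the
#' elevation bands so that, at reduced network scale, the anatomical
#' separation between the responsive sets exceeds the inhibitory space
#' constant — the property the suppression and adaptation analyses rely
#' on. About `frac_tuned` of cells are visually tuned; the rest are
#' flagged excluded and receive no input.
#'
#' @param neurons Neuron table.
#' @param elevations Elevation category labels.
#' @param frac_tuned Fraction of tuned cells (default 0.4).
#' @param mean_A Mean response gain in drive units after the standard
#'   2.5e3 input scaling of about 3 log-rate units at peak
#'   (default `1.2e-3`).
#' @param seed RNG seed.
#' @return Tibble like [fit_receptive_fields()] output: `id`, `A`, `mu`,
#'   `sigma`, `r2`, `elevation`, `excluded`, `reason`.
#' @export
implant_receptive_fields <- function(neurons, elevations = c("high", "low"),
                                     frac_tuned = 0.4, mean_A = 1.2e-3,
                                     seed = 1L) {
  n <- nrow(neurons)
  with_seed(seed, {
    ap_rank <- rank(neurons$ap, ties.method = "first") / n
    band <- pmin(floor(ap_rank * length(elevations)) + 1L,
                 length(elevations))
    within <- ap_rank * length(elevations) - (band - 1L)
    mu <- -55 + 110 * within + rnorm(n, 0, 5)
    sigma <- pmax(38 / 2.5 + rnorm(n, 0, 9.6), 3.2)
    A <- mean_A * exp(rnorm(n, 0, 0.3))
    elev <- elevations[band]
    tuned <- runif(n) < frac_tuned
    tibble(id = neurons$id, A = A, mu = mu, sigma = sigma, r2 = 1,
           elevation = elev, excluded = !tuned,
           reason = ifelse(tuned, NA_character_, "untuned"))
  })
}

#' Fluorescence preprocessing (dF/F0)
#'
#' Computes the slowly varying baseline `F0(t)` of each raw fluorescence
#' trace as the 10th percentile of a sliding 20-volume window, the
#' proportional change `dFF = (F - F0)/F0` (zero-centred per ROI), and
#' flags ROIs with slow baseline drift: an ROI is discarded if the
#' standard deviation of its mean-normalised `F0(t)` exceeds
#' `drift_sd_threshold`.
#'
#' @param f_raw Matrix ROIs x timepoints of raw fluorescence (> 0).
#' @param window Sliding window length in volumes (default 20).
#' @param percentile Baseline percentile (default 0.10).
#' @param drift_sd_threshold Drift exclusion threshold (default 0.45).
#' @return List of class `fluorescence_trace`: `f0`, `dff` (matrices),
#'   `kept` (logical per ROI), `drift_sd` (numeric per ROI).
#' @export
dff_preprocess <- function(f_raw, window = 20L, percentile = 0.10,
                           drift_sd_threshold = 0.45) {
  f_raw <- as.matrix(f_raw)
  if (any(f_raw <= 0)) abort("`f_raw` must be strictly positive")
  nt <- ncol(f_raw)
  if (window > nt) abort("window longer than trace")
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  f0 <- t(apply(f_raw, 1L, function(x) {
    vapply(seq_len(nt), function(t) {
      lo <- max(1L, t - half_lo)
      hi <- min(nt, t + half_hi)
      quantile(x[lo:hi], percentile, names = FALSE, type = 7)
    }, numeric(1))
  }))
  dff <- (f_raw - f0) / f0
  dff <- dff - rowMeans(dff)
  norm_f0 <- f0 / rowMeans(f0)
  drift_sd <- apply(norm_f0, 1L, sd)
  structure(list(f0 = f0, dff = dff, kept = drift_sd <= drift_sd_threshold,
                 drift_sd = drift_sd),
            class = "fluorescence_trace")
}

#' Forward calcium model
#'
#' Convolves a spike raster with an exponential calcium kernel and adds a
#' baseline and multiplicative noise, producing synthetic raw fluorescence
#' to exercise [dff_preprocess()]. Not a realistic optics model.
#'
#' @param raster [spike_raster()] (imaging-equivalent).
#' @param tau Calcium decay, s (default 1.8, nuclear GCaMP6s-like).
#' @param amplitude Fluorescence per spike (default 0.25 of baseline).
#' @param baseline Baseline fluorescence level (default 100).
#' @param noise_sd Additive noise SD (default 2).
#' @param drift Optional per-ROI multiplicative linear drift amplitude
#'   (default 0: none).
#' @param seed RNG seed.
#' @return Matrix ROIs x timepoints of positive raw fluorescence.
#' @export
simulate_fluorescence <- function(raster, tau = 1.8, amplitude = 0.25,
                                  baseline = 100, noise_sd = 2, drift = 0,
                                  seed = 1L) {
  counts <- as.matrix(raster$counts)
  dec <- exp(-raster$frame_dt / tau)
  conv <- counts
  for (t in 2:ncol(conv)) {
    conv[, t] <- conv[, t] + dec * conv[, t - 1L]
  }
  nt <- ncol(counts)
  with_seed(seed, {
    f <- baseline * (1 + amplitude * conv)
    if (drift != 0) {
      slopes <- runif(nrow(f), -drift, drift)
      f <- f * (1 + outer(slopes, seq_len(nt) / nt))
    }
    pmax(f + matrix(rnorm(length(f), 0, noise_sd), nrow(f)), 1e-3)
  })
}
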