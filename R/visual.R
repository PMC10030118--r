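# Receptive fields, stimulus protocols, external input construction,
# responsive-cell identification, post-stimulus suppression and
# stimulus-specific adaptation analyses.

#' Fit a Gaussian receptive field
#'
#' Fits `lambda(alpha) = A exp(-(alpha - mu)^2 / (2 sigma^2))` to a mean
#' spike-count tuning curve over stimulus azimuth. Fits are excluded (with
#' a reason) if the optimiser fails, if the tuning is implausibly narrow
#' (`sigma < 3` degrees), or if the fitted peak falls below `peak_threshold`
#' (set by [fit_receptive_fields()] to the population 20th percentile).
#'
#' @param azimuth Stimulus azimuth grid, degrees.
#' @param response Mean spike count at each azimuth.
#' @param min_sigma Exclusion width (default 3 degrees).
#' @param peak_threshold Optional minimum fitted gain.
#' @return Object of class `rf_fit`: list with `A`, `mu`, `sigma`, `r2`,
#'   `excluded`, `reason`.
#' @examples
#' a <- seq(-55, 55, 5)
#' fit_receptive_field(a, 3 * exp(-(a - 40)^2 / (2 * 10^2)))
#' @export
fit_receptive_field <- function(azimuth, response, min_sigma = 3,
                                peak_threshold = NULL) {
  ok <- is.finite(azimuth) & is.finite(response)
  azimuth <- azimuth[ok]; response <- response[ok]
  if (length(azimuth) < 4L) abort("need at least 4 azimuth samples")
  init <- c(A = max(response), mu = azimuth[which.max(response)],
            sigma = max(diff(range(azimuth)) / 6, 5))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = init,
      lower = c(A = 0, mu = min(azimuth) - 30, sigma = 0.5),
      upper = c(A = Inf, mu = max(azimuth) + 30, sigma = 360),
      fn = function(p, a, y) y - p["A"] * exp(-(a - p["mu"])^2 / (2 * p["sigma"]^2)),
      a = azimuth, y = response,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(A = NA_real_, mu = NA_real_, sigma = NA_real_,
                          r2 = NA_real_, excluded = TRUE,
                          reason = "non-convergence"), class = "rf_fit"))
  }
  p <- coef(fit)
  ss_tot <- sum((response - mean(response))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$fvec^2) / ss_tot else NA_real_
  excluded <- FALSE; reason <- NA_character_
  if (is.finite(p["sigma"]) && p["sigma"] < min_sigma) {
    excluded <- TRUE; reason <- "narrow"
  } else if (!is.null(peak_threshold) && p["A"] < peak_threshold) {
    excluded <- TRUE; reason <- "low peak"
  }
  structure(list(A = unname(p["A"]), mu = unname(p["mu"]),
                 sigma = unname(p["sigma"]), r2 = r2, excluded = excluded,
                 reason = reason), class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("RF fit: A = %.3g, mu = %.3g deg, sigma = %.3g deg, r2 = %.3f%s\n",
              x$A, x$mu, x$sigma, x$r2,
              if (x$excluded) paste0(" [excluded: ", x$reason, "]") else ""))
  invisible(x)
}

#' @export
tidy.rf_fit <- function(x, ...) {
  tibble(term = c("A", "mu", "sigma"), estimate = c(x$A, x$mu, x$sigma))
}

#' @export
glance.rf_fit <- function(x, ...) {
  tibble(r.squared = x$r2, excluded = x$excluded, reason = x$reason)
}

#' Fit receptive fields for a population
#'
#' Runs [fit_receptive_field()] on each row of a tuning matrix and applies
#' the population-level low-peak exclusion: cells whose fitted gain falls
#' below the `peak_quantile` (default 0.2) population quantile are flagged.
#'
#' @param tuning Matrix neurons x azimuths of mean responses.
#' @param azimuth Azimuth grid, degrees.
#' @param elevation Optional per-neuron elevation category labels.
#' @param peak_quantile Population quantile for the low-peak exclusion.
#' @param min_sigma Width exclusion (degrees).
#' @return Tibble with `id`, `A`, `mu`, `sigma`, `r2`, `elevation`,
#'   `excluded`, `reason`.
#' @export
fit_receptive_fields <- function(tuning, azimuth, elevation = NULL,
                                 peak_quantile = 0.2, min_sigma = 3) {
  fits <- lapply(seq_len(nrow(tuning)), function(i) {
    f <- fit_receptive_field(azimuth, tuning[i, ], min_sigma = min_sigma)
    tibble(id = i, A = f$A, mu = f$mu, sigma = f$sigma, r2 = f$r2,
           excluded = f$excluded, reason = f$reason)
  })
  out <- bind_rows(fits)
  thr <- quantile(out$A[!out$excluded & is.finite(out$A)], peak_quantile,
                  names = FALSE, na.rm = TRUE)
  low <- !out$excluded & is.finite(out$A) & out$A < thr
  out$excluded[low] <- TRUE
  out$reason[low] <- "low peak"
  out$elevation <- if (is.null(elevation)) NA_character_ else elevation
  attr(out, "peak_threshold") <- thr
  out
}

#' Build a visual stimulation protocol
#'
#' Deterministic event schedules for moving-spot experiments. Sweeps are
#' 10 degree spots moving at 20 degrees per second across about 110 degrees
#' of frontal azimuth (5.5 s per sweep). Two kinds are supported:
#' `"single_isi"` presents one stimulus elevation at a fixed
#' inter-stimulus interval; `"mixed_isi"` builds the oddball-style design:
#' 30-minute stimulation blocks in which a common stimulus is presented
#' every `common_isi` (30 s) and a deviant every `deviant_isi` (5 min),
#' each deviant followed by a 90 s break in common presentations;
#' stimulation blocks are separated by rest blocks with no stimuli.
#'
#' @param kind `"single_isi"`, `"alternating"` (two elevations presented in
#'   alternation, each at interval `isi`, offset by `isi / 2`) or
#'   `"mixed_isi"`.
#' @param elevations For `single_isi`: one elevation label. For
#'   `mixed_isi`: per-block data frame or list with `common` and `deviant`
#'   labels per stimulation block.
#' @param isi Single-ISI inter-stimulus interval, s (default 300).
#' @param n_blocks Number of stimulation blocks (mixed; default 2).
#' @param block_s Stimulation block length, s (default 1800).
#' @param rest_s Rest block length, s (default 1800).
#' @param common_isi,deviant_isi Mixed-ISI intervals, s (defaults 30 and
#'   300).
#' @param break_s Post-deviant break, s (default 90).
#' @param lead_in_s Quiet time before the first block, s (default 60).
#' @param baseline_block Prepend a block (mixed design) in which every
#'   stimulus is presented sparsely (at `deviant_isi`, role `"single"`,
#'   block 0) to establish per-cell baseline responses (default FALSE).
#' @param baseline_s Length of that baseline block, s (default `block_s`).
#' @param duration For `single_isi`: total protocol length, s.
#' @param sweep_speed Degrees per second (default 20).
#' @param sweep_range Azimuth extent covered, degrees (default 110, from
#'   -55 to +55).
#' @param direction `"leftward"` or `"rightward"`.
#' @return Object of class `stim_protocol`: list with `events` (tibble:
#'   `onset`, `elevation`, `role`, `block`, `direction`), `sweep_s`,
#'   `duration`, and the configuration fields.
#' @export
build_protocol <- function(kind = c("single_isi", "alternating", "mixed_isi"),
                           elevations, isi = 300, n_blocks = 2L,
                           block_s = 1800, rest_s = 1800, common_isi = 30,
                           deviant_isi = 300, break_s = 90, lead_in_s = 60,
                           duration = NULL, sweep_speed = 20,
                           sweep_range = 110, baseline_block = FALSE,
                           baseline_s = block_s,
                           direction = "leftward") {
  kind <- match.arg(kind)
  sweep_s <- sweep_range / sweep_speed
  if (kind == "single_isi") {
    if (is.null(duration)) abort("`duration` required for single_isi")
    if (isi < sweep_s) abort("`isi` shorter than the sweep itself")
    onsets <- if (lead_in_s > duration - sweep_s) {
      numeric(0)
    } else {
      seq(lead_in_s, duration - sweep_s, by = isi)
    }
    events <- tibble(onset = onsets,
                     elevation = rep(elevations[1L], length(onsets)),
                     role = rep("single", length(onsets)),
                     block = rep(1L, length(onsets)),
                     direction = rep(direction, length(onsets)))
    total <- duration
  } else if (kind == "alternating") {
    if (is.null(duration)) abort("`duration` required for alternating")
    stopifnot(length(elevations) == 2L)
    if (isi / 2 < sweep_s) abort("`isi` too short for alternating sweeps")
    on1 <- seq(lead_in_s, duration - sweep_s, by = isi)
    on2 <- on1 + isi / 2
    on2 <- on2[on2 <= duration - sweep_s]
    events <- arrange(bind_rows(
      tibble(onset = on1, elevation = elevations[1L], role = "single",
             block = 1L, direction = direction),
      tibble(onset = on2, elevation = elevations[2L], role = "single",
             block = 1L, direction = direction)), .data$onset)
    total <- duration
  } else {
    if (break_s > block_s) abort("post-deviant break longer than the block")
    if (is.data.frame(elevations)) elevations <- as.list(elevations)
    stopifnot(length(elevations$common) >= n_blocks,
              length(elevations$deviant) >= n_blocks)
    rows <- list()
    t_block <- lead_in_s
    if (isTRUE(baseline_block)) {
      # sparse presentations of every stimulus establish per-cell baseline
      # responses before the stimulation blocks
      labels <- unique(c(elevations$common, elevations$deviant))
      base_onsets <- seq(t_block, t_block + baseline_s - sweep_s,
                         by = deviant_isi)
      for (li in seq_along(labels)) {
        on <- base_onsets + (li - 1L) * (deviant_isi / length(labels))
        on <- on[on <= t_block + baseline_s - sweep_s]
        rows[[length(rows) + 1L]] <- tibble(
          onset = on, elevation = labels[li], role = "single", block = 0L,
          direction = direction)
      }
      t_block <- t_block + baseline_s + rest_s
    }
    for (b in seq_len(n_blocks)) {
      dev_onsets <- seq(t_block + deviant_isi, t_block + block_s - sweep_s,
                        by = deviant_isi)
      com_onsets <- seq(t_block, t_block + block_s - sweep_s, by = common_isi)
      # drop common presentations within the post-deviant break
      in_break <- vapply(com_onsets, function(o) {
        any(o > dev_onsets & o <= dev_onsets + break_s)
      }, logical(1))
      com_onsets <- com_onsets[!in_break]
      # no overlap with a deviant sweep
      clash <- vapply(com_onsets, function(o) {
        any(abs(o - dev_onsets) < sweep_s)
      }, logical(1))
      com_onsets <- com_onsets[!clash]
      rows[[length(rows) + 1L]] <- tibble(
        onset = com_onsets, elevation = elevations$common[b],
        role = "common", block = b, direction = direction)
      rows[[length(rows) + 1L]] <- tibble(
        onset = dev_onsets, elevation = elevations$deviant[b],
        role = "deviant", block = b, direction = direction)
      t_block <- t_block + block_s + rest_s
    }
    events <- arrange(bind_rows(rows), .data$onset)
    total <- t_block
  }
  structure(list(events = events, sweep_s = sweep_s, duration = total,
                 sweep_speed = sweep_speed, sweep_range = sweep_range,
                 kind = kind),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol (%s): %d events over %.0f s (%.1f s sweeps)\n",
              x$kind, nrow(x$events), x$duration, x$sweep_s))
  invisible(x)
}

#' Azimuth of the sweeping spot at a given time within a sweep
#' @param protocol A [build_protocol()] result.
#' @param t_rel Time since sweep onset, seconds.
#' @param direction Sweep direction.
#' @return Azimuth in degrees (`NA` outside the sweep).
#' @export
sweep_azimuth <- function(protocol, t_rel, direction = "leftward") {
  half <- protocol$sweep_range / 2
  a <- -half + protocol$sweep_speed * t_rel
  a[t_rel < 0 | t_rel > protocol$sweep_s] <- NA_real_
  if (direction == "leftward") a else -a
}

#' Construct external input drive from receptive fields and a protocol
#'
#' Builds the per-neuron external drive time series at the fast simulation
#' step: during a sweep whose elevation matches a cell's receptive-field
#' elevation, `x_j(t) = gain_scale * A_j * exp(-(alpha(t) - mu_j)^2 /
#' (2 (width_shrink * sigma_j)^2))`, zero otherwise. The default scaling
#' (`gain_scale = 2.5e3`, `width_shrink = 0.8`) converts measured response
#' gains into input drive while compensating for the apparent
#' receptive-field widening caused by recurrent excitation. Excluded
#' receptive fields receive zero input. An optional per-event multiplicative
#' `adaptation_gain` (e.g. retinal-input adaptation for the common
#' stimulus) scales individual presentations.
#'
#' @param rfs Tibble from [fit_receptive_fields()] (needs `A`, `mu`,
#'   `sigma`, `elevation`, `excluded`).
#' @param protocol A [build_protocol()] result.
#' @param dt_fast Fast step, s.
#' @param n_steps Number of fast steps to cover.
#' @param gain_scale,width_shrink Scaling constants (defaults 2.5e3, 0.8).
#' @param adaptation_gain Optional numeric vector, one gain per protocol
#'   event (default all 1).
#' @return Sparse matrix neurons x steps of external drive.
#' @export
make_external_input <- function(rfs, protocol, dt_fast, n_steps,
                                gain_scale = 2.5e3, width_shrink = 0.8,
                                adaptation_gain = NULL) {
  ev <- protocol$events
  if (is.null(adaptation_gain)) adaptation_gain <- rep(1, nrow(ev))
  stopifnot(length(adaptation_gain) == nrow(ev))
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  active <- which(!rfs$excluded)
  for (k in seq_len(nrow(ev))) {
    steps <- which((seq_len(n_steps) - 1L) * dt_fast >= ev$onset[k] &
                     (seq_len(n_steps) - 1L) * dt_fast < ev$onset[k] + protocol$sweep_s)
    if (!length(steps)) next
    alpha <- sweep_azimuth(protocol, (steps - 1L) * dt_fast - ev$onset[k],
                           ev$direction[k])
    cells <- active[rfs$elevation[active] == ev$elevation[k]]
    if (!length(cells)) next
    for (j in cells) {
      x <- gain_scale * rfs$A[j] *
        exp(-(alpha - rfs$mu[j])^2 / (2 * (width_shrink * rfs$sigma[j])^2)) *
        adaptation_gain[k]
      nz <- which(x > 1e-8)
      if (!length(nz)) next
      trip_i[[length(trip_i) + 1L]] <- rep.int(j, length(nz))
      trip_j[[length(trip_j) + 1L]] <- steps[nz]
      trip_x[[length(trip_x) + 1L]] <- x[nz]
    }
  }
  sparseMatrix(i = unlist(trip_i) %||% integer(0),
               j = unlist(trip_j) %||% integer(0),
               x = unlist(trip_x) %||% numeric(0),
               dims = c(nrow(rfs), n_steps))
}

#' Identify stimulus-responsive neurons
#'
#' A neuron is responsive to a stimulus elevation if its mean response
#' firing rate across that elevation's presentations strictly exceeds the
#' population 90th percentile of mean responses and is at least five times
#' its own baseline (ongoing) rate. Baseline rates are floored at the
#' equivalent of one spike per session to guard zero-baseline cells.
#'
#' @param raster Imaging-equivalent [spike_raster()].
#' @param events Event tibble (needs `onset`, `elevation`).
#' @param sweep_s Response window length after onset, s.
#' @param percentile Population percentile (default 0.9).
#' @param fold Baseline multiple (default 5).
#' @return A named list of integer vectors: responsive neuron ids per
#'   elevation. Attribute `rates` carries the per-neuron mean response
#'   rates per elevation (spikes/s).
#' @export
identify_responsive <- function(raster, events, sweep_s, percentile = 0.9,
                                fold = 5) {
  if (nrow(events) == 0L) abort("need at least one event")
  n <- nrow(raster$counts)
  stim_frames <- integer(0)
  by_elev <- split(events$onset, events$elevation)
  rates <- matrix(NA_real_, n, length(by_elev),
                  dimnames = list(NULL, names(by_elev)))
  for (e in seq_along(by_elev)) {
    resp <- matrix(0, n, length(by_elev[[e]]))
    for (k in seq_along(by_elev[[e]])) {
      f0 <- frame_at(raster, by_elev[[e]][k])
      f1 <- min(frame_at(raster, by_elev[[e]][k] + sweep_s), n_frames(raster))
      if (f0 < 1L || f0 > n_frames(raster)) next
      resp[, k] <- Matrix::rowSums(raster$counts[, f0:f1, drop = FALSE]) /
        ((f1 - f0 + 1L) * raster$frame_dt)
      stim_frames <- c(stim_frames, f0:f1)
    }
    rates[, e] <- rowMeans(resp)
  }
  ongoing_frames <- setdiff(seq_len(n_frames(raster)), unique(stim_frames))
  baseline <- Matrix::rowSums(raster$counts[, ongoing_frames, drop = FALSE]) /
    (length(ongoing_frames) * raster$frame_dt)
  floor_rate <- 1 / raster_duration(raster)
  baseline <- pmax(baseline, floor_rate)
  out <- lapply(colnames(rates), function(e) {
    thr <- quantile(rates[, e], percentile, names = FALSE)
    which(rates[, e] > thr & rates[, e] >= fold * baseline)
  })
  names(out) <- colnames(rates)
  attr(out, "rates") <- rates
  attr(out, "baseline") <- baseline
  out
}

#' Post-stimulus suppression of ongoing activity
#'
#' Mean activity of each responsive set in windows following stimulus
#' offset, normalised by that set's mean ongoing activity (frames outside
#' stimulus sweeps and analysis windows). Values below 1 indicate
#' suppression.
#'
#' @param raster Imaging-equivalent [spike_raster()].
#' @param events Event tibble (`onset`, `elevation`).
#' @param responsive Named list from [identify_responsive()].
#' @param sweep_s Sweep length, s.
#' @param windows List of `c(from, to)` offsets after stimulus end, s
#'   (default `list(c(0, 10), c(10, 30))`).
#' @return Tibble: `event`, `stim_elevation`, `set_elevation`, `window`,
#'   `value` (normalised activity), plus aggregate rows (`event = NA`)
#'   with the across-event medians (the median is used because ongoing
#'   activity is burst-dominated and heavy-tailed, so a single burst
#'   inside one window would otherwise dominate a session mean).
#' @export
post_stimulus_suppression <- function(raster, events, responsive, sweep_s,
                                      windows = list(c(0, 10), c(10, 30))) {
  nf <- n_frames(raster)
  # ongoing frames: away from stimuli and their analysis windows
  excl <- integer(0)
  max_off <- max(vapply(windows, max, numeric(1)))
  for (k in seq_len(nrow(events))) {
    f0 <- frame_at(raster, events$onset[k])
    f1 <- frame_at(raster, events$onset[k] + sweep_s + max_off)
    excl <- c(excl, max(f0, 1L):min(f1, nf))
  }
  ongoing <- setdiff(seq_len(nf), unique(excl))
  rows <- list()
  for (set_e in names(responsive)) {
    ids <- responsive[[set_e]]
    if (!length(ids)) next
    ongoing_rate <- mean(Matrix::rowMeans(raster$counts[ids, ongoing,
                                                        drop = FALSE]))
    if (ongoing_rate <= 0) ongoing_rate <- 1 / (length(ids) * nf)
    for (k in seq_len(nrow(events))) {
      offset_t <- events$onset[k] + sweep_s
      for (w in seq_along(windows)) {
        f0 <- frame_at(raster, offset_t + windows[[w]][1])
        f1 <- frame_at(raster, offset_t + windows[[w]][2]) - 1L
        if (f1 > nf || f0 < 1L) next
        val <- mean(Matrix::rowMeans(raster$counts[ids, f0:f1,
                                                   drop = FALSE])) /
          ongoing_rate
        rows[[length(rows) + 1L]] <- tibble(
          event = k, stim_elevation = events$elevation[k],
          set_elevation = set_e, window = w, value = val)
      }
    }
  }
  per_event <- bind_rows(rows)
  agg <- per_event |>
    group_by(.data$stim_elevation, .data$set_elevation, .data$window) |>
    summarise(value = median(.data$value), .groups = "drop") |>
    mutate(event = NA_integer_, .before = 1L)
  bind_rows(per_event, agg)
}

#' Per-presentation response scalars
#'
#' Spike count of each neuron during each presentation's sweep window.
#'
#' @inheritParams identify_responsive
#' @return Matrix neurons x events.
#' @export
event_responses <- function(raster, events, sweep_s) {
  n <- nrow(raster$counts)
  out <- matrix(NA_real_, n, nrow(events))
  for (k in seq_len(nrow(events))) {
    f0 <- frame_at(raster, events$onset[k])
    f1 <- min(frame_at(raster, events$onset[k] + sweep_s), n_frames(raster))
    if (f0 < 1L || f0 > n_frames(raster)) next
    out[, k] <- Matrix::rowSums(raster$counts[, f0:f1, drop = FALSE])
  }
  out
}

#' Stimulus-specific response modulation
#'
#' Compares each cell's mean response during a stimulation block to its
#' baseline response, defined as the mean response to the low-frequency
#' (deviant-role or single-ISI) presentations of the same stimulus in
#' other blocks. Returns per-cell modulation (difference and ratio) for
#' the common and deviant stimulus of the analysis block, and a linear
#' regression of modulation on the baseline response to the common
#' stimulus.
#'
#' @param raster Imaging-equivalent [spike_raster()].
#' @param protocol Mixed-ISI [build_protocol()] result.
#' @param block Analysis block (default 2).
#' @param sweep_s Override of the protocol sweep length.
#' @param cells Optional subset of neuron ids.
#' @return List of class `response_modulation`: `per_cell` (tibble with
#'   `id`, `stimulus` (common/deviant), `baseline`, `block_response`,
#'   `modulation`, `ratio`), `regression` (lm of common-stimulus
#'   modulation on baseline), `timecourse` (per-presentation population
#'   mean responses normalised by first response).
#' @export
response_modulation <- function(raster, protocol, block = 2L,
                                sweep_s = NULL, cells = NULL) {
  ev <- protocol$events
  if (is.null(sweep_s)) sweep_s <- protocol$sweep_s
  resp <- event_responses(raster, ev, sweep_s)
  if (is.null(cells)) cells <- seq_len(nrow(resp))
  blk <- ev$block == block
  elevs <- list(common = unique(ev$elevation[blk & ev$role == "common"]),
                deviant = unique(ev$elevation[blk & ev$role == "deviant"]))
  per_cell <- list()
  for (stim in names(elevs)) {
    e <- elevs[[stim]]
    base_cols <- which(ev$elevation == e & ev$role %in% c("deviant", "single") &
                         ev$block != block)
    blk_cols <- which(blk & ev$elevation == e & ev$role == stim)
    if (!length(base_cols) || !length(blk_cols)) next
    baseline <- rowMeans(resp[cells, base_cols, drop = FALSE])
    blk_resp <- rowMeans(resp[cells, blk_cols, drop = FALSE])
    per_cell[[stim]] <- tibble(
      id = cells, stimulus = stim, baseline = baseline,
      block_response = blk_resp, modulation = blk_resp - baseline,
      ratio = ifelse(baseline > 0, blk_resp / baseline, NA_real_))
  }
  per_cell <- bind_rows(per_cell)
  regression <- NULL
  if (all(c("common", "deviant") %in% per_cell$stimulus)) {
    com <- per_cell[per_cell$stimulus == "common", ]
    if (nrow(com) > 3L && var(com$baseline) > 0) {
      regression <- lm(modulation ~ baseline, data = com)
    }
  }
  # population timecourse per elevation, normalised by first response
  tc <- lapply(unique(ev$elevation), function(e) {
    cols <- which(ev$elevation == e)
    m <- colMeans(resp[cells, cols, drop = FALSE])
    first <- m[1L]
    tibble(elevation = e, onset = ev$onset[cols], role = ev$role[cols],
           block = ev$block[cols], response = m,
           norm_response = if (first > 0) m / first else m)
  })
  structure(list(per_cell = per_cell, regression = regression,
                 timecourse = bind_rows(tc)),
            class = "response_modulation")
}

#' Synthetic retinal-input adaptation gain profile
#'
#' Multiplicative input gain per protocol event emulating adaptation of
#' retinal ganglion cell terminals to frequent stimulation: every common
#' presentation multiplies the gain towards a plateau
#' (`gain <- plateau + (gain - plateau) * per_event`), and the gain
#' recovers towards 1 between presentations with time constant
#' `tau_recover` (so 90 s breaks and rest blocks produce partial or full
#' recovery). Deviant and single presentations are unaffected (gain 1).
#'
#' @param protocol A [build_protocol()] result.
#' @param plateau Asymptotic gain under sustained stimulation (default
#'   0.5).
#' @param per_event Per-presentation decay factor towards the plateau
#'   (default 0.8).
#' @param tau_recover Recovery time constant, s (default 300). The default
#'   profile settles near 0.7 under 30 s inter-stimulus intervals, with
#'   partial recovery during 90 s breaks.
#' @return Numeric vector of gains, one per protocol event.
#' @export
adaptation_gain <- function(protocol, plateau = 0.5, per_event = 0.8,
                            tau_recover = 300) {
  ev <- protocol$events
  gains <- rep(1, nrow(ev))
  state <- list()
  for (k in seq_len(nrow(ev))) {
    e <- as.character(ev$elevation[k])
    st <- state[[e]]
    if (is.null(st)) st <- list(g = 1, t = -Inf)
    g <- 1 - (1 - st$g) * exp(-(ev$onset[k] - st$t) / tau_recover)
    if (ev$role[k] == "common") {
      gains[k] <- g
      g <- plateau + (g - plateau) * per_event
      state[[e]] <- list(g = g, t = ev$onset[k])
    } else {
      gains[k] <- 1
    }
  }
  gains
}

#' Population-level adaptation summary
#'
#' Compares, for the common and deviant stimulus of one stimulation block,
#' the mean response of the cells tuned to that stimulus against their mean
#' baseline response (low-frequency presentations in other blocks),
#' population-level (total spikes over cells), which is robust to the
#' near-zero per-cell baselines of sparse protocols. Also reports the mean
#' response recovery across post-deviant breaks: the first common response
#' after each break minus the last response before the deviant.
#'
#' @param raster Imaging-equivalent [spike_raster()].
#' @param protocol Mixed-ISI [build_protocol()] result.
#' @param rfs Receptive-field table with `elevation` and `excluded`.
#' @param block Analysis block (default 2).
#' @return List with `common_ratio`, `deviant_ratio`, `recovery` (spikes
#'   per presentation, positive = partial recovery after breaks).
#' @export
population_adaptation <- function(raster, protocol, rfs, block = 2L) {
  ev <- protocol$events
  resp <- event_responses(raster, ev, protocol$sweep_s)
  pop_ratio <- function(elev, role2) {
    cells <- which(rfs$elevation == elev & !rfs$excluded)
    base_cols <- which(ev$elevation == elev &
                         ev$role %in% c("single", "deviant") &
                         ev$block != block)
    blk_cols <- which(ev$block == block & ev$elevation == elev &
                        ev$role == role2)
    if (!length(cells) || !length(base_cols) || !length(blk_cols)) {
      return(NA_real_)
    }
    mean(resp[cells, blk_cols]) / mean(resp[cells, base_cols])
  }
  com_elev <- unique(ev$elevation[ev$block == block & ev$role == "common"])
  dev_elev <- unique(ev$elevation[ev$block == block & ev$role == "deviant"])
  tuned_com <- which(rfs$elevation == com_elev & !rfs$excluded)
  com_cols <- which(ev$block == block & ev$role == "common")
  dev_cols <- which(ev$block == block & ev$role == "deviant")
  # responses alternate strongly under self-suppression, so recovery is
  # measured on window means: all commons between this deviant's break and
  # the next deviant, against all commons since the previous break
  bounds_prev <- c(-Inf, ev$onset[dev_cols])
  bounds_next <- c(ev$onset[dev_cols], Inf)
  recovery <- vapply(seq_along(dev_cols), function(i) {
    d_on <- ev$onset[dev_cols[i]]
    before <- com_cols[ev$onset[com_cols] < d_on &
                         ev$onset[com_cols] > bounds_prev[i]]
    after <- com_cols[ev$onset[com_cols] > d_on + 90 &
                        ev$onset[com_cols] < bounds_next[i + 1L]]
    if (!length(before) || !length(after)) return(NA_real_)
    mean(resp[tuned_com, after, drop = FALSE]) -
      mean(resp[tuned_com, before, drop = FALSE])
  }, numeric(1))
  list(common_ratio = pop_ratio(com_elev, "common"),
       deviant_ratio = pop_ratio(dev_elev, "deviant"),
       recovery = mean(recovery, na.rm = TRUE))
}
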