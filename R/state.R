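#' Estimate pre-event linear drive from spiking history
#'
#' Applies the model's spatiotemporal coupling filters to observed spiking
#' (an imaging-equivalent raster) to estimate the recurrent linear drive —
#' the excitability proxy — of every neuron over the 60 s preceding an
#' event. Only spikes in the window from 60 s to 5 s before the event are
#' used; the final 5 s are ignored to reflect the uncertainty of
#' spike inference near the event. The bias `mu` and any external input are
#' excluded, so the estimate is the recurrent component
#' `sum_i (I_E(i,j) - I_I(i,j)) y_i` alone.
#'
#' @param raster Imaging-equivalent [spike_raster()] (5 Hz framing).
#' @param neurons Neuron table.
#' @param params [model_params()] used for the filters.
#' @param event_time Event time in seconds (same clock as `raster$t0`).
#' @param coupling Optional precomputed [build_coupling()] result.
#' @param history_s,blank_s History length and ignored tail, seconds
#'   (defaults 60 and 5).
#' @return A matrix (neurons x frames over the 60 s window) of raw drive
#'   values, with attribute `frame_dt`; or `NULL` (with a warning) if the
#'   event starts less than `history_s` after the raster start.
#' @export
estimate_drive <- function(raster, neurons, params, event_time,
                           coupling = NULL, history_s = 60, blank_s = 5) {
  if (event_time - history_s < raster$t0 - 1e-9) {
    warn(sprintf("event at %.1f s has insufficient history; skipped", event_time))
    return(NULL)
  }
  if (is.null(coupling)) coupling <- build_coupling(neurons, params)
  f0 <- frame_at(raster, event_time - history_s)
  f1 <- min(frame_at(raster, event_time) - 1L, n_frames(raster))
  nf <- f1 - f0 + 1L
  counts <- raster$counts[, f0:f1, drop = FALSE]
  blank_frames <- round(blank_s / raster$frame_dt)
  if (blank_frames > 0L) {
    keep <- nf - blank_frames
    counts[, (keep + 1L):nf] <- 0
  }
  drive_from_counts(counts, coupling, params, raster$frame_dt)
}

# Recursive filtering of frame-resolution spike counts with the two
# exponential coupling filters. A spike in frame s contributes from frame
# s + 1 onward, decayed per elapsed frame.
drive_from_counts <- function(counts, coupling, params, frame_dt) {
  WEt <- t(coupling$E)
  WIt <- t(coupling$I)
  n <- nrow(counts)
  nf <- ncol(counts)
  dec_e <- exp(-frame_dt / params$tau_e)
  dec_i <- exp(-frame_dt / params$tau_i)
  eE <- numeric(n)
  iI <- numeric(n)
  out <- matrix(0, n, nf)
  for (t in seq_len(nf)) {
    out[, t] <- eE - iI
    y <- counts[, t]
    spikers <- which(y > 0)
    eE <- eE * dec_e
    iI <- iI * dec_i
    if (length(spikers)) {
      ys <- y[spikers]
      eE <- eE + as.numeric(WEt[, spikers, drop = FALSE] %*% ys) * dec_e
      iI <- iI + as.numeric(WIt[, spikers, drop = FALSE] %*% ys) * dec_i
    }
  }
  attr(out, "frame_dt") <- frame_dt
  out
}

#' Baseline-correct drive estimates and reduce to point estimates
#'
#' Corrects raw pre-event drive vectors for cell-specific biases (such as
#' spatial edge effects) by subtracting, timepoint-wise, the mean drive
#' vector over `n_epochs` randomly placed epochs of ongoing activity; the
#' point estimate per neuron is the mean of the final 10 s of the corrected
#' vector. Baseline epochs are sampled uniformly among window positions
#' whose end lies at least `exclusion_s` away from any event, without
#' replacement where possible; if fewer positions exist the count is
#' reduced with a warning.
#'
#' @param raw Raw drive matrix from [estimate_drive()] (or a list of them
#'   for several events).
#' @param raster,neurons,params,coupling As in [estimate_drive()].
#' @param event_times All event times (used to keep baseline epochs away
#'   from events).
#' @param n_epochs Number of baseline epochs (default 60).
#' @param exclusion_s Minimum distance of a baseline epoch end from any
#'   event, seconds (default 90).
#' @param average_s Final averaging window, seconds (default 10).
#' @param seed RNG seed for epoch placement.
#' @return A tibble of class `drive_estimate` with one row per neuron and
#'   event: `event`, `id`, `drive` (baseline-corrected point estimate, log
#'   rate units).
#' @export
baseline_correct <- function(raw, raster, neurons, params, event_times,
                             coupling = NULL, n_epochs = 60L,
                             exclusion_s = 90, average_s = 10, seed = 1L,
                             history_s = 60, blank_s = 5) {
  if (is.null(coupling)) coupling <- build_coupling(neurons, params)
  if (is.matrix(raw)) raw <- list(raw)
  frame_dt <- raster$frame_dt
  hist_frames <- round(history_s / frame_dt)
  nf <- n_frames(raster)
  # candidate epoch end frames: enough history before, far from events
  cand0 <- which(seq_len(nf) > hist_frames)
  t_end <- raster$t0 + cand0 * frame_dt
  excl <- exclusion_s
  repeat {
    cand <- cand0
    if (length(event_times)) {
      far <- vapply(t_end, function(tt) min(abs(tt - event_times)) >= excl,
                    logical(1))
      cand <- cand0[far]
    }
    if (length(cand) >= 1L || excl < frame_dt) break
    excl <- excl / 2
    warn(sprintf("no ongoing epochs at %g s exclusion; relaxing to %g s",
                 excl * 2, excl))
  }
  if (length(cand) == 0L) abort("no ongoing epochs available for baseline")
  n_use <- min(n_epochs, length(cand))
  if (n_use < n_epochs) {
    warn(sprintf("only %d ongoing epochs available (%d requested)",
                 n_use, n_epochs))
  }
  ends <- with_seed(seed, sample(cand, n_use, replace = FALSE))
  base_acc <- NULL
  for (e in ends) {
    tt <- raster$t0 + e * frame_dt
    d <- estimate_drive(raster, neurons, params, tt, coupling = coupling,
                        history_s = history_s, blank_s = blank_s)
    base_acc <- if (is.null(base_acc)) d else base_acc + d
  }
  base_mean <- base_acc / n_use
  avg_frames <- round(average_s / frame_dt)
  reduce <- function(mat) {
    corr <- mat - base_mean[, seq_len(ncol(mat)), drop = FALSE]
    idx <- (ncol(corr) - avg_frames + 1L):ncol(corr)
    rowMeans(corr[, idx, drop = FALSE])
  }
  rows <- lapply(seq_along(raw), function(k) {
    tibble(event = k, id = seq_len(nrow(raw[[k]])), drive = reduce(raw[[k]]))
  })
  out <- bind_rows(rows)
  attr(out, "n_baseline_epochs") <- n_use
  class(out) <- c("drive_estimate", class(out))
  out
}

#' Threshold-linear fit of response versus drive
#'
#' Least-squares fit of the rectified-linear model
#' `y = (a (x - x0) + |a (x - x0)|) / 2 + c` (flat at `c` below the
#' threshold `x0`, slope `a >= 0` above it). The threshold is profiled over
#' candidate values (data quantiles and observed abscissae) with `a` and
#' `c` solved by constrained linear least squares at each candidate,
#' followed by a local refinement; the best solution by SSE is kept.
#'
#' @param x Drive estimates per trial.
#' @param y Responses per trial.
#' @return An object of class `threshold_linear_fit`: list with `a`, `x0`,
#'   `c`, `r2`, `n`. Degenerate inputs (constant `x` or `y`) give `a = 0`,
#'   `c = mean(y)`, `r2 = 0`.
#' @examples
#' x <- seq(-2, 2, length.out = 30)
#' y <- pmax(2 * (x - 0), 0) + 1
#' fit_threshold_linear(x, y)
#' @export
fit_threshold_linear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) abort("need at least 4 finite trials")
  degenerate <- function() {
    structure(list(a = 0, x0 = stats::median(x), c = mean(y), r2 = 0,
                   n = length(x)), class = "threshold_linear_fit")
  }
  if (var(x) == 0 || var(y) == 0) return(degenerate())
  ss_tot <- sum((y - mean(y))^2)
  solve_at <- function(x0) {
    basis <- pmax(x - x0, 0)
    if (all(basis == 0) || var(basis) == 0) {
      return(list(a = 0, c = mean(y), sse = ss_tot))
    }
    fit <- lm(y ~ basis)
    a <- coef(fit)[2]
    if (!is.finite(a) || a < 0) {
      return(list(a = 0, c = mean(y), sse = ss_tot))
    }
    list(a = unname(a), c = unname(coef(fit)[1]), sse = sum(fit$residuals^2))
  }
  cands <- unique(c(quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
                    sort(x)[-length(x)]))
  sols <- lapply(cands, solve_at)
  best_i <- which.min(vapply(sols, `[[`, numeric(1), "sse"))
  x0 <- cands[best_i]
  # local refinement of the threshold
  span <- diff(range(x))
  opt <- optimize(function(t) solve_at(t)$sse,
                  lower = max(min(x), x0 - 0.25 * span),
                  upper = min(max(x), x0 + 0.25 * span))
  if (opt$objective < sols[[best_i]]$sse) x0 <- opt$minimum
  sol <- solve_at(x0)
  structure(list(a = sol$a, x0 = x0, c = sol$c,
                 r2 = max(0, 1 - sol$sse / ss_tot), n = length(x)),
            class = "threshold_linear_fit")
}

#' @export
print.threshold_linear_fit <- function(x, ...) {
  cat(sprintf("Threshold-linear fit: a = %.4g, x0 = %.4g, c = %.4g, r2 = %.3f (n = %d)\n",
              x$a, x$x0, x$c, x$r2, x$n))
  invisible(x)
}

#' @export
tidy.threshold_linear_fit <- function(x, ...) {
  tibble(term = c("a", "x0", "c"), estimate = c(x$a, x$x0, x$c))
}

#' @export
glance.threshold_linear_fit <- function(x, ...) {
  tibble(r.squared = x$r2, nobs = x$n)
}

#' Predict from a threshold-linear fit
#' @param object A [fit_threshold_linear()] result.
#' @param newdata Numeric abscissae.
#' @param ... Unused.
#' @export
predict.threshold_linear_fit <- function(object, newdata, ...) {
  object$a * pmax(newdata - object$x0, 0) + object$c
}

#' Explained response variance: real versus null drive estimates
#'
#' For each neuron, fits the threshold-linear model of per-trial responses
#' against (a) the model-estimated pre-event drive and (b) a null estimate
#' computed at randomly sampled timepoints with the same history
#' constraint, and returns both r-squared values. Neurons with zero median
#' response across trials are excluded.
#'
#' @param raster Imaging-equivalent [spike_raster()].
#' @param neurons,params As elsewhere.
#' @param event_times Event times, seconds.
#' @param responses Matrix neurons x events of per-trial response scalars.
#' @param n_null Number of null timepoints (default: number of events).
#' @param seed RNG seed.
#' @param coupling Optional precomputed coupling.
#' @param ... Passed to [baseline_correct()] (epoch counts etc.).
#' @return A tibble with `id`, `r2_real`, `r2_null` for included neurons.
#' @export
r2_vs_null <- function(raster, neurons, params, event_times, responses,
                       n_null = NULL, seed = 1L, coupling = NULL, ...) {
  if (length(event_times) != ncol(responses)) {
    abort("`responses` must have one column per event")
  }
  if (is.null(coupling)) coupling <- build_coupling(neurons, params)
  est <- function(times, seed_offset) {
    raws <- lapply(times, function(tt) {
      estimate_drive(raster, neurons, params, tt, coupling = coupling)
    })
    keep <- !vapply(raws, is.null, logical(1))
    bc <- baseline_correct(raws[keep], raster, neurons, params,
                           event_times = event_times, coupling = coupling,
                           seed = child_seed(seed, seed_offset), ...)
    drv <- matrix(NA_real_, nrow(raster$counts), length(times))
    for (k in seq_along(which(keep))) {
      drv[, which(keep)[k]] <- bc$drive[bc$event == k]
    }
    drv
  }
  drive_real <- est(event_times, 1L)
  t_min <- raster$t0 + 60 + raster$frame_dt
  t_max <- raster$t0 + raster_duration(raster)
  if (is.null(n_null)) n_null <- length(event_times)
  null_times <- with_seed(child_seed(seed, 3L),
                          runif(n_null, t_min, t_max))
  drive_null <- est(null_times, 2L)

  med_resp <- apply(responses, 1L, median)
  rows <- lapply(which(med_resp != 0), function(i) {
    xr <- drive_real[i, ]
    xn <- drive_null[i, seq_len(min(ncol(drive_null), ncol(responses)))]
    yr <- responses[i, ]
    ok_r <- is.finite(xr) & is.finite(yr)
    if (sum(ok_r) < 4L) return(NULL)
    f_real <- fit_threshold_linear(xr[ok_r], yr[ok_r])
    ok_n <- is.finite(xn) & is.finite(yr[seq_along(xn)])
    if (sum(ok_n) < 4L) return(NULL)
    f_null <- fit_threshold_linear(xn[ok_n], yr[seq_along(xn)][ok_n])
    tibble(id = i, r2_real = f_real$r2, r2_null = f_null$r2)
  })
  bind_rows(rows)
}

#' Ground-truth recovery of pre-event drive
#'
#' For a simulator-generated dataset with logged true recurrent drive,
#' estimates the pre-event drive from the spike raster alone
#' ([estimate_drive()]) and correlates it, per neuron across events, with
#' the true drive averaged over the same final window. The summary is the
#' median across neurons of the per-neuron across-event Pearson
#' correlation — the trial-to-trial excitability-recovery score. On a
#' surrogate (history-independent) raster the score collapses towards
#' zero.
#'
#' @param raster Imaging-equivalent raster used for estimation.
#' @param drive Logged true recurrent drive matrix (attributes `frame_dt`,
#'   `t0`), e.g. `generate_dataset()$drive`.
#' @param neurons,params As elsewhere.
#' @param event_times Event times, s.
#' @param average_s Final averaging window, s (default 10).
#' @param coupling Optional precomputed coupling.
#' @return List with `median_r`, `per_neuron` (tibble `id`, `r`), and the
#'   matrices `truth` and `estimate` (neurons x events).
#' @export
drive_recovery <- function(raster, drive, neurons, params, event_times,
                           average_s = 10, coupling = NULL) {
  if (is.null(coupling)) coupling <- build_coupling(neurons, params)
  raws <- lapply(event_times, function(tt) {
    estimate_drive(raster, neurons, params, tt, coupling = coupling)
  })
  keep <- !vapply(raws, is.null, logical(1))
  if (sum(keep) < 3L) abort("need at least 3 events with sufficient history")
  fd <- attr(drive, "frame_dt")
  dt0 <- attr(drive, "t0") %||% 0
  avg_f <- round(average_s / fd)
  truth <- vapply(event_times[keep], function(tt) {
    i1 <- min(floor((tt - dt0) / fd), ncol(drive))
    rowMeans(drive[, (i1 - avg_f + 1L):i1, drop = FALSE])
  }, numeric(nrow(drive)))
  est <- vapply(raws[keep], function(m) {
    nfr <- ncol(m)
    avg_e <- round(average_s / attr(m, "frame_dt"))
    rowMeans(m[, (nfr - avg_e + 1L):nfr, drop = FALSE])
  }, numeric(nrow(drive)))
  ok <- apply(truth, 1L, sd) > 0 & apply(est, 1L, sd) > 0
  r <- rep(NA_real_, nrow(drive))
  r[ok] <- vapply(which(ok), function(j) cor(truth[j, ], est[j, ]),
                  numeric(1))
  list(median_r = median(r, na.rm = TRUE),
       per_neuron = tibble(id = seq_len(nrow(drive)), r = r),
       truth = truth, estimate = est)
}
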