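#' Seed-based pairwise correlation map
#'
#' Pearson correlation between the activity of one seed neuron and every
#' other neuron, after smoothing each spike-count trace with a Gaussian
#' window (sigma = 1.4 frames, i.e. 280 ms at 5 Hz; kernel truncated at
#' +/- 4 sigma and normalised to unit sum). Traces are mean-subtracted by
#' the correlation itself; frames belonging to a simulation warm-up can be
#' excluded via `drop_frames`.
#'
#' @param seed_id Row index of the seed neuron.
#' @param raster Imaging-equivalent [spike_raster()].
#' @param smoothing_sigma_frames Gaussian smoothing sigma in frames
#'   (default 1.4).
#' @param drop_frames Optional integer vector of frames to exclude.
#' @return A tibble with `id`, `r` (Pearson correlation; `NA` for
#'   zero-variance target traces, which are counted in attribute
#'   `n_undefined`). The seed's own row carries `r = 1` but is excluded from
#'   downstream fitting.
#' @export
correlation_map <- function(seed_id, raster, smoothing_sigma_frames = 1.4,
                            drop_frames = NULL) {
  counts <- as.matrix(raster$counts)
  if (!is.null(drop_frames)) counts <- counts[, -drop_frames, drop = FALSE]
  if (ncol(counts) < 2L) abort("need at least 2 frames")
  sm <- gaussian_smooth_rows(counts, smoothing_sigma_frames)
  seed_trace <- sm[seed_id, ]
  if (sd(seed_trace) == 0) abort("seed trace has zero variance after smoothing")
  sds <- apply(sm, 1L, sd)
  r <- rep(NA_real_, nrow(sm))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(seed_trace, t(sm[ok, , drop = FALSE])))
  out <- tibble(id = seq_len(nrow(sm)), r = r)
  attr(out, "seed_id") <- seed_id
  attr(out, "n_undefined") <- sum(!ok)
  out
}

#' Fit a spatial model to a correlation map
#'
#' Fits the correlation values of one seed, as a function of the projected
#' anterior-posterior (`ap`) and medial-lateral (`ml`) coordinates, with
#' either a general bivariate normal density (gain `A`, bias `b`, means
#' `mu_x`, `mu_y`, standard deviations `sigma_x`, `sigma_y` and correlation
#' coefficient `rho`) or an exponential decay
#' `A exp(-sqrt(((x - mu_x)/sigma_x)^2 + ((y - mu_y)/sigma_y)^2)) + b`.
#' Bounded least squares with the bounds `b in [0, 0.8]`, `A >= 0`,
#' `mu_x in [-100, 1200]`, `mu_y in [-100, 250]`, `sigma in (0, 500]`,
#' `rho in [-1, 1]`. The initial peak guess is drawn within 100 um of the
#' seed position; `n_restarts` random restarts are made and the best fit by
#' r-squared kept. The seed neuron itself is excluded.
#'
#' @param map Result of [correlation_map()].
#' @param neurons Neuron table with `ap`, `ml` columns (um).
#' @param model `"gaussian"` or `"exponential"`.
#' @param n_restarts Random restarts of the initial peak guess (default 5).
#' @param seed RNG seed for the restarts.
#' @return An object of class `corr_map_fit` with elements `seed_id`,
#'   `model`, `coef` (named vector), `r2`, `converged`, `n_points`.
#'   Non-convergent fits are flagged with `r2 = NA`.
#' @export
fit_correlation_map <- function(map, neurons, model = c("gaussian", "exponential"),
                                n_restarts = 5L, seed = 1L) {
  model <- match.arg(model)
  seed_id <- attr(map, "seed_id")
  dat <- tibble(x = neurons$ap, y = neurons$ml, r = map$r)
  dat <- dat[-seed_id, ]
  dat <- dat[is.finite(dat$r), ]
  if (nrow(dat) < 20L) abort("need at least 20 finite data points")
  seed_x <- neurons$ap[seed_id]
  seed_y <- neurons$ml[seed_id]

  lower <- c(A = 0, b = 0, mu_x = -100, mu_y = -100, sigma_x = 1e-6,
             sigma_y = 1e-6)
  upper <- c(A = Inf, b = 0.8, mu_x = 1200, mu_y = 250, sigma_x = 500,
             sigma_y = 500)
  if (model == "gaussian") {
    lower <- c(lower, rho = -1)
    upper <- c(upper, rho = 1)
  }
  predict_fun <- function(p, x, y) {
    if (model == "gaussian") {
      z <- ((x - p["mu_x"]) / p["sigma_x"])^2 +
        ((y - p["mu_y"]) / p["sigma_y"])^2 -
        2 * p["rho"] * (x - p["mu_x"]) * (y - p["mu_y"]) /
          (p["sigma_x"] * p["sigma_y"])
      p["A"] / (2 * pi * p["sigma_x"] * p["sigma_y"] *
                  sqrt(pmax(1 - p["rho"]^2, 1e-10))) *
        exp(-z / (2 * pmax(1 - p["rho"]^2, 1e-10))) + p["b"]
    } else {
      p["A"] * exp(-sqrt(((x - p["mu_x"]) / p["sigma_x"])^2 +
                           ((y - p["mu_y"]) / p["sigma_y"])^2)) + p["b"]
    }
  }
  ss_tot <- sum((dat$r - mean(dat$r))^2)
  best <- NULL
  # random initial peak guesses within 100 um of the seed, kept inside the
  # data bounding box; one extra start at the observed maximum
  box_x <- range(dat$x) + c(-20, 20)
  box_y <- range(dat$y) + c(-20, 20)
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(k) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 100)
      c(mu_x = seed_x + rad * cos(ang), mu_y = seed_y + rad * sin(ang))
    })
  })
  i_max <- which.max(dat$r)
  starts <- c(starts, list(c(mu_x = dat$x[i_max], mu_y = dat$y[i_max])))
  b0 <- min(max(quantile(dat$r, 0.1, names = FALSE), 0), 0.8)
  amp0 <- max(max(dat$r) - b0, 0.01)
  sx0 <- min(diff(range(dat$x)) / 3, 60)
  sy0 <- min(diff(range(dat$y)) / 3, 60)
  for (st in starts) {
    init <- c(A = if (model == "gaussian") {
      amp0 * 2 * pi * sx0 * sy0
    } else {
      amp0
    },
    b = b0,
    mu_x = min(max(st["mu_x"], max(box_x[1], -100)), min(box_x[2], 1200)),
    mu_y = min(max(st["mu_y"], max(box_y[1], -100)), min(box_y[2], 250)),
    sigma_x = sx0, sigma_y = sy0)
    if (model == "gaussian") init <- c(init, rho = 0)
    names(init) <- names(lower)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = init,
        lower = lower, upper = pmin(upper, 1e12),
        fn = function(p, x, y, r) r - predict_fun(setNames(p, names(lower)), x, y),
        x = dat$x, y = dat$y, r = dat$r,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- setNames(coef(fit), names(lower))
    r2 <- if (ss_tot > 0) 1 - sum(fit$fvec^2) / ss_tot else 0
    if (is.null(best) || (is.finite(r2) && r2 > best$r2)) {
      best <- list(coef = p, r2 = r2)
    }
  }
  if (is.null(best)) {
    best <- list(coef = setNames(rep(NA_real_, length(lower)), names(lower)),
                 r2 = NA_real_)
  }
  structure(list(seed_id = seed_id, model = model, coef = best$coef,
                 r2 = best$r2, converged = is.finite(best$r2),
                 n_points = nrow(dat),
                 seed_ap = seed_x, seed_ml = seed_y),
            class = "corr_map_fit")
}

#' @export
print.corr_map_fit <- function(x, ...) {
  cat(sprintf("Correlation-map fit (%s), seed %d: r2 = %.3f\n",
              x$model, x$seed_id, x$r2))
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
tidy.corr_map_fit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @export
glance.corr_map_fit <- function(x, ...) {
  tibble(r.squared = x$r2, nobs = x$n_points, model = x$model,
         converged = x$converged)
}

#' Correlation maps and fits for many seeds
#'
#' Convenience wrapper: computes [correlation_map()] and
#' [fit_correlation_map()] for a set of seed neurons and returns one row per
#' seed (broom-style), including the distance between the fitted peak and
#' the seed position.
#'
#' @param raster Imaging-equivalent [spike_raster()].
#' @param neurons Neuron table.
#' @param seeds Seed row indices.
#' @param model Passed to [fit_correlation_map()].
#' @param ... Passed to [correlation_map()].
#' @return A tibble with `seed_id`, fitted parameters, `r2`,
#'   `peak_offset_um`.
#' @export
fit_correlation_maps <- function(raster, neurons, seeds,
                                 model = "gaussian", ...) {
  rows <- lapply(seeds, function(s) {
    m <- correlation_map(s, raster, ...)
    f <- fit_correlation_map(m, neurons, model = model)
    est <- as_tibble(as.list(f$coef))
    mutate(est, seed_id = s, r2 = f$r2,
           peak_offset_um = sqrt((f$coef[["mu_x"]] - f$seed_ap)^2 +
                                   (f$coef[["mu_y"]] - f$seed_ml)^2),
           .before = 1L)
  })
  bind_rows(rows)
}
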