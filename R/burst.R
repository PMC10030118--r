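#' Find population activity peaks
#'
#' Local maxima of the population activity trace: the mean spike count
#' across neurons per frame, smoothed with a 3-frame (600 ms at 5 Hz)
#' sliding window. A peak must be strictly greater than the preceding
#' smoothed frame and at least as large as the following one; plateaus are
#' assigned to their first frame. Peaks occurring during episodes of strong
#' bilateral activation are excluded: a peak is removed if more than
#' `max_active_fraction` of all neurons are active in the 1 s window centred
#' on it *and* less than `min_same_hemisphere` of those active cells lie in
#' the same hemisphere. "Active" means at least one spike within the 5-frame
#' window centred on the peak.
#'
#' @param raster Imaging-equivalent [spike_raster()] (5 Hz framing).
#' @param neurons Neuron table (for hemisphere labels).
#' @param smooth_frames Width of the smoothing window (default 3 frames).
#' @param max_active_fraction,min_same_hemisphere Bilateral-activation
#'   exclusion thresholds (defaults 0.10 and 0.70).
#' @return Sorted integer vector of peak frames.
#' @export
find_population_peaks <- function(raster, neurons, smooth_frames = 3L,
                                  max_active_fraction = 0.10,
                                  min_same_hemisphere = 0.70) {
  nf <- n_frames(raster)
  if (nf == 0L) return(integer(0))
  trace <- Matrix::colMeans(raster$counts)
  sm <- moving_average(trace, smooth_frames)
  if (nf < 3L) return(integer(0))
  peaks <- integer(0)
  t <- 2L
  while (t <= nf - 1L) {
    if (sm[t] > sm[t - 1L] && sm[t] >= sm[t + 1L]) {
      # plateau: keep first frame, require an eventual drop before a rise
      u <- t
      while (u < nf && sm[u + 1L] == sm[t]) u <- u + 1L
      if (u == nf || sm[u + 1L] < sm[t]) peaks <- c(peaks, t)
      t <- u + 1L
    } else {
      t <- t + 1L
    }
  }
  if (length(peaks) == 0L) return(integer(0))
  keep <- vapply(peaks, function(p) {
    act <- active_in_window(raster, p)
    frac <- length(act) / nrow(raster$counts)
    if (frac <= max_active_fraction) return(TRUE)
    tab <- table(neurons$hemisphere[act])
    max(tab) / length(act) >= min_same_hemisphere
  }, logical(1))
  sort(peaks[keep])
}

# Neurons with >= 1 spike in the 5-frame (1 s at 5 Hz) window centred on a
# peak frame (2 frames either side).
active_in_window <- function(raster, peak_frame, half = 2L) {
  lo <- max(1L, peak_frame - half)
  hi <- min(n_frames(raster), peak_frame + half)
  which(Matrix::rowSums(raster$counts[, lo:hi, drop = FALSE]) > 0)
}

#' Density-based spatial clustering of burst cells
#'
#' Clusters the cells active in the 1 s window centred on a population peak
#' by their 3D soma positions using DBSCAN semantics: a core point has at
#' least `min_pts` neighbours (itself included) within radius `eps`;
#' clusters are maximal density-connected sets; non-core points within `eps`
#' of a core point join its cluster; remaining points are noise and
#' excluded.
#'
#' @param peak_frame Frame index of the population peak.
#' @param raster Imaging-equivalent [spike_raster()].
#' @param neurons Neuron table with `x`, `y`, `z`.
#' @param eps Clustering distance threshold, micrometres (default 15, about
#'   three cell diameters).
#' @param min_pts Minimum neighbourhood size (default 12); see
#'   [select_min_pts()] for the permutation-based selection rule.
#' @return A list of integer vectors of neuron ids (row indices into
#'   `neurons`), one per cluster; empty list if no cluster forms.
#' @export
cluster_burst_cells <- function(peak_frame, raster, neurons, eps = 15,
                                min_pts = 12L) {
  if (eps <= 0) abort("`eps` must be positive")
  act <- active_in_window(raster, peak_frame)
  if (length(act) == 0L) return(list())
  pts <- as.matrix(neurons[act, c("x", "y", "z")])
  labs <- dbscan_labels(pts, eps, min_pts)
  ids <- split(act, labs)
  ids[names(ids) != "0"]
}

# Plain DBSCAN on a small point set. Returns integer labels (0 = noise).
dbscan_labels <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d2 <- as.matrix(stats::dist(pts))^2
  nbr <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nbr, length, integer(1)) >= min_pts
  labs <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labs[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labs[i] <- cl
    frontier <- nbr[[i]]
    while (length(frontier)) {
      nxt <- integer(0)
      for (j in frontier) {
        if (labs[j] == 0L) {
          labs[j] <- cl
          if (core[j]) nxt <- c(nxt, nbr[[j]])
        }
      }
      frontier <- unique(nxt)
    }
  }
  labs
}

#' Select MinPts by circular-permutation control
#'
#' Chooses the density-clustering `min_pts` as the smallest candidate for
#' which no cluster is detected on temporally scrambled data: each neuron's
#' spike train is independently circularly shifted, the burst-cell
#' clustering is run at every population peak of the permuted raster, and a
#' candidate passes if no permutation yields any cluster.
#'
#' @param raster Imaging-equivalent [spike_raster()].
#' @param neurons Neuron table.
#' @param eps Clustering radius, um.
#' @param candidates Increasing integer candidates for `min_pts`.
#' @param n_perms Number of independent circular permutations per candidate.
#' @param seed Seed for the permutation draws.
#' @return The selected `min_pts`, or `NA` with a warning if no candidate
#'   passes.
#' @export
select_min_pts <- function(raster, neurons, eps = 15,
                           candidates = 4:20, n_perms = 5L, seed = 1L) {
  if (n_perms < 1L) abort("`n_perms` must be >= 1")
  candidates <- sort(as.integer(candidates))
  shifts <- with_seed(seed, {
    replicate(n_perms, sample.int(n_frames(raster), nrow(raster$counts),
                                  replace = TRUE), simplify = FALSE)
  })
  permuted <- lapply(shifts, function(s) circular_permute(raster, s))
  for (cand in candidates) {
    any_cluster <- FALSE
    for (pr in permuted) {
      peaks <- find_population_peaks(pr, neurons)
      for (p in peaks) {
        if (length(cluster_burst_cells(p, pr, neurons, eps, cand)) > 0L) {
          any_cluster <- TRUE
          break
        }
      }
      if (any_cluster) break
    }
    if (!any_cluster) return(cand)
  }
  warn("no MinPts candidate eliminated all clusters on permuted data")
  NA_integer_
}

# Independently circularly shift each neuron's spike train.
circular_permute <- function(raster, shifts) {
  nf <- n_frames(raster)
  cm <- methods::as(raster$counts, "TsparseMatrix")
  j_new <- (cm@j + shifts[cm@i + 1L]) %% nf
  spike_raster(sparseMatrix(i = cm@i + 1L, j = j_new + 1L, x = cm@x,
                            dims = dim(raster$counts)),
               frame_dt = raster$frame_dt, t0 = raster$t0)
}

#' Temporal extent of a burst by Poisson filtering
#'
#' Determines when the spiking of a clustered cell group starts and stops. A
#' sliding window six frames wide (1.2 s at 5 Hz) is advanced one frame at a
#' time over a span around the peak. Within each window, per-cell spike
#' counts are discarded if they exceed the 60th percentile of a Poisson
#' cumulative distribution with rate equal to the mean count across the
#' cluster cells in that window (i.e. counts strictly greater than the
#' smallest `k` with `CDF(k) >= 0.6` are dropped); the mean of the surviving
#' counts gives one value of the filtered activity vector. The burst
#' initiation and termination frames are the first and last non-zero entries
#' of the contiguous non-zero run containing the peak.
#'
#' @param cluster Integer vector of member neuron indices.
#' @param raster Imaging-equivalent [spike_raster()].
#' @param peak_frame Population peak frame the cluster came from.
#' @param window Filter window width in frames (default 6).
#' @param percentile Poisson CDF cut (default 0.6).
#' @param span Frames either side of the peak over which windows are
#'   evaluated (default 75, i.e. 15 s at 5 Hz).
#' @return A list with `t_init`, `t_term` (frame indices), `peak_frame`
#'   (frame of maximal filtered activity), `filtered` (tibble with `frame`,
#'   `value`), and `degenerate` (TRUE if the cluster produced no non-zero
#'   filtered activity near the peak).
#' @export
burst_extent <- function(cluster, raster, peak_frame, window = 6L,
                         percentile = 0.6, span = 75L) {
  if (length(cluster) == 0L) abort("`cluster` is empty")
  nf <- n_frames(raster)
  lo <- max(1L, peak_frame - span)
  hi <- min(nf, peak_frame + span)
  counts <- as.matrix(raster$counts[cluster, lo:hi, drop = FALSE])
  n_pos <- ncol(counts) - window + 1L
  if (n_pos < 1L) {
    return(list(t_init = NA_integer_, t_term = NA_integer_,
                peak_frame = peak_frame,
                filtered = tibble(frame = integer(0), value = numeric(0)),
                degenerate = TRUE))
  }
  # per-cell counts within each window position (cells x positions)
  cs <- cbind(0, t(apply(counts, 1L, cumsum)))
  win_counts <- cs[, (window + 1L):(window + n_pos), drop = FALSE] -
    cs[, 1:n_pos, drop = FALSE]
  lambda <- colMeans(win_counts)
  kmax <- qpois(percentile, lambda) # smallest k with CDF(k) >= percentile
  filtered <- vapply(seq_len(n_pos), function(w) {
    kept <- win_counts[, w][win_counts[, w] <= kmax[w]]
    if (length(kept) == 0L) 0 else mean(kept)
  }, numeric(1))
  # window position w covers frames (lo+w-1) .. (lo+w+window-2); assign its
  # value to the window centre
  centre <- lo + seq_len(n_pos) - 1L + (window %/% 2L)
  nz <- filtered > 0
  if (!any(nz)) {
    return(list(t_init = NA_integer_, t_term = NA_integer_,
                peak_frame = peak_frame,
                filtered = tibble(frame = centre, value = filtered),
                degenerate = TRUE))
  }
  # contiguous non-zero run containing (or nearest to) the peak
  runs <- rle(nz)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  nz_runs <- which(runs$values)
  peak_pos <- which.min(abs(centre - peak_frame))
  in_run <- nz_runs[starts[nz_runs] <= peak_pos & ends[nz_runs] >= peak_pos]
  run <- if (length(in_run)) {
    in_run[1L]
  } else {
    nz_runs[which.min(pmin(abs(starts[nz_runs] - peak_pos),
                           abs(ends[nz_runs] - peak_pos)))]
  }
  sel <- starts[run]:ends[run]
  list(t_init = centre[sel[1L]],
       t_term = centre[sel[length(sel)]],
       peak_frame = centre[sel][which.max(filtered[sel])],
       filtered = tibble(frame = centre, value = filtered),
       degenerate = FALSE)
}

#' Detect localised bursts in a raster
#'
#' Full burst-detection pipeline: population peaks
#' ([find_population_peaks()]), density clustering of active cells at each
#' peak ([cluster_burst_cells()]), and Poisson-filtered temporal extent per
#' cluster ([burst_extent()]). Each surviving cluster becomes one burst.
#' Optionally, clusters from consecutive peaks that share more than half
#' their membership and have overlapping extents can be merged
#' (`merge_duplicates = TRUE`); the default keeps per-peak counting.
#'
#' @inheritParams cluster_burst_cells
#' @param merge_duplicates Merge near-duplicate bursts from adjacent peaks
#'   (default FALSE).
#' @param ... Passed to [burst_extent()].
#' @return A tibble of class `tectal_bursts`, one row per burst: `burst_id`,
#'   `peak_frame`, `t_init`, `t_term`, `size`, `duration` (s),
#'   `centroid_x/y/z` (um), and `members` (list column of neuron indices).
#' @examples
#' \donttest{
#' nt <- generate_positions(300, seed = 2)
#' sim <- simulate_network(nt, optimized_params(),
#'                         sim_config(duration = 120, discard = 30, seed = 2))
#' detect_bursts(binned_raster(sim), nt)
#' }
#' @export
detect_bursts <- function(raster, neurons, eps = 15, min_pts = 12L,
                          merge_duplicates = FALSE, ...) {
  peaks <- find_population_peaks(raster, neurons)
  rows <- list()
  for (p in peaks) {
    clusters <- cluster_burst_cells(p, raster, neurons, eps, min_pts)
    for (cl in clusters) {
      ext <- burst_extent(cl, raster, p, ...)
      if (ext$degenerate) next
      pos <- neurons[cl, c("x", "y", "z")]
      rows[[length(rows) + 1L]] <- tibble(
        peak_frame = ext$peak_frame, t_init = ext$t_init,
        t_term = ext$t_term, size = length(cl),
        duration = (ext$t_term - ext$t_init + 1L) * raster$frame_dt,
        centroid_x = mean(pos$x), centroid_y = mean(pos$y),
        centroid_z = mean(pos$z), members = list(sort(cl)))
    }
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(
    peak_frame = integer(0), t_init = integer(0), t_term = integer(0),
    size = integer(0), duration = numeric(0), centroid_x = numeric(0),
    centroid_y = numeric(0), centroid_z = numeric(0), members = list())
  if (merge_duplicates && nrow(out) > 1L) {
    out <- merge_burst_rows(out)
    out$duration <- (out$t_term - out$t_init + 1L) * raster$frame_dt
  }
  out <- mutate(out, burst_id = dplyr::row_number(), .before = 1L)
  class(out) <- c("tectal_bursts", class(out))
  attr(out, "frame_dt") <- raster$frame_dt
  out
}

# Merge bursts from consecutive peaks sharing > 50% membership with
# overlapping extents.
merge_burst_rows <- function(b) {
  b <- arrange(b, .data$peak_frame)
  keep <- rep(TRUE, nrow(b))
  i <- 1L
  while (i < nrow(b)) {
    j <- i + 1L
    while (j <= nrow(b) && keep[i]) {
      if (!keep[j]) { j <- j + 1L; next }
      mi <- b$members[[i]]; mj <- b$members[[j]]
      overlap <- length(intersect(mi, mj)) / min(length(mi), length(mj))
      t_overlap <- b$t_init[j] <= b$t_term[i] && b$t_term[j] >= b$t_init[i]
      if (overlap > 0.5 && t_overlap) {
        b$members[[i]] <- sort(union(mi, mj))
        b$size[i] <- length(b$members[[i]])
        b$t_init[i] <- min(b$t_init[i], b$t_init[j])
        b$t_term[i] <- max(b$t_term[i], b$t_term[j])
        keep[j] <- FALSE
      }
      j <- j + 1L
    }
    i <- i + 1L
  }
  b[keep, ]
}
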