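#' Spike raster container
#'
#' A spike raster holds non-negative spike counts for `n` neurons over
#' equally spaced time frames, stored as a sparse matrix, together with the
#' frame duration `frame_dt` (seconds) and the absolute time `t0` of the
#' start of the first frame. Imaging-equivalent rasters use
#' `frame_dt = 0.2` (5 Hz).
#'
#' @param counts Matrix-like object of non-negative counts
#'   (neurons x frames); coerced to a sparse matrix.
#' @param frame_dt Frame duration, seconds.
#' @param t0 Time of the first frame start, seconds (default 0).
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(counts, frame_dt, t0 = 0) {
  counts <- methods::as(Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (any(counts@x < 0)) abort("spike counts must be non-negative")
  stopifnot_scalar(frame_dt, "frame_dt", lower = 0, strict_lower = TRUE)
  structure(list(counts = counts, frame_dt = frame_dt, t0 = t0),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("Spike raster: %d neurons x %d frames (%.3g s/frame, t0 = %.3g s, %d spikes)\n",
              nrow(x$counts), ncol(x$counts), x$frame_dt, x$t0,
              sum(x$counts)))
  invisible(x)
}

#' @export
dim.spike_raster <- function(x) dim(x$counts)

#' Number of frames and total duration of a raster
#' @param raster A [spike_raster()].
#' @return `n_frames()`: integer; `raster_duration()`: seconds.
#' @export
n_frames <- function(raster) ncol(raster$counts)

#' @rdname n_frames
#' @export
raster_duration <- function(raster) ncol(raster$counts) * raster$frame_dt

#' Bin a raster into coarser frames
#'
#' Sums spike counts within non-overlapping windows of `bin_factor` frames
#' (e.g. 4 x 50 ms simulation steps into 200 ms imaging-equivalent frames).
#' A trailing partial window is dropped, so total spikes are conserved up to
#' the dropped remainder.
#'
#' @param raster A [spike_raster()].
#' @param bin_factor Frames per output bin, `>= 1`.
#' @return A [spike_raster()] with `frame_dt` multiplied by `bin_factor`.
#' @examples
#' r <- spike_raster(matrix(c(1, 0, 0, 2, 0, 1, 0, 0), nrow = 1), 0.05)
#' as.matrix(bin_raster(r, 4)$counts)
#' @export
bin_raster <- function(raster, bin_factor) {
  bin_factor <- as.integer(bin_factor)
  if (is.na(bin_factor) || bin_factor < 1L) abort("`bin_factor` must be >= 1")
  if (bin_factor == 1L) return(raster)
  n_bins <- ncol(raster$counts) %/% bin_factor
  if (n_bins == 0L) abort("raster shorter than one bin")
  sub <- raster$counts[, seq_len(n_bins * bin_factor), drop = FALSE]
  # aggregation matrix: frames x bins
  agg <- sparseMatrix(i = seq_len(n_bins * bin_factor),
                      j = rep(seq_len(n_bins), each = bin_factor), x = 1)
  spike_raster(sub %*% agg, frame_dt = raster$frame_dt * bin_factor,
               t0 = raster$t0)
}

# Frame index containing absolute time t (1-based); frames span
# [t0 + (k-1) dt, t0 + k dt).
frame_at <- function(raster, t) {
  as.integer(floor((t - raster$t0) / raster$frame_dt)) + 1L
}
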