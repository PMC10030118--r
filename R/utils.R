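# Internal helpers shared across modules.

# Derive an independent child seed from a master seed. Keeps results below
# .Machine$integer.max so seeds remain valid R integers.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * stream) %% 2147483587 + 1
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %g", name, lower))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %g", name, upper))
  }
  invisible(x)
}

# Moving average with a centred window of `k` frames (k odd). Edges use the
# available frames only (partial windows), matching a sliding-window smooth.
moving_average <- function(x, k) {
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Gaussian smoothing of rows of a matrix along time, kernel truncated at
# +/- 4 sigma and renormalised to unit sum.
gaussian_smooth_rows <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(4 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  t(apply(mat, 1L, function(x) {
    as.numeric(stats::filter(c(rep(x[1], half), x, rep(x[length(x)], half)),
                             kern, sides = 2L))[(half + 1L):(half + length(x))]
  }))
}
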