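#' Synthetic tectal neuron positions
#'
#' Generates per-neuron 3D coordinates emulating the periventricular cell
#' body layer (SPV) of the two tectal hemispheres: uniform samples inside two
#' mirrored ellipsoids separated by a midline gap, with a minimum pairwise
#' separation mimicking nuclear exclusion. An anterior-posterior reference
#' curve per hemisphere is generated alongside and used to assign curved
#' anterior-posterior (`ap`) and medial-lateral (`ml`) coordinates via
#' [project_coordinates()].
#'
#' Hemisphere extents scale with the requested cell count so that the cell
#' density (cells per cubic micrometre) stays constant across tiers; at the
#' default density the full-scale network of roughly 1.4e4 cells occupies
#' ellipsoids a few hundred micrometres long, comparable to the larval
#' tectum.
#'
#' @param n_per_hemisphere Number of neurons in each hemisphere.
#' @param density Cells per cubic micrometre (default `1/180`, i.e. one soma
#'   per 180 um^3, about 5.7 um centre-to-centre spacing — tightly packed
#'   periventricular somata).
#' @param gap Midline gap between hemispheres, micrometres.
#' @param min_separation Minimum pairwise distance between somata, um.
#' @param axis_ratio Length-3 ratio of ellipsoid semi-axes
#'   (medial-lateral : anterior-posterior : dorsal-ventral).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble of class `tectal_neurons` with columns `id`, `x`, `y`,
#'   `z` (um; `x` is medial-lateral with the midline at 0, `y` is
#'   anterior-posterior, `z` dorsal-ventral), `hemisphere` (`"L"`/`"R"`),
#'   `ap`, `ml` (um). The per-hemisphere anterior-posterior polylines are
#'   attached as attribute `ap_curves`.
#' @examples
#' nt <- generate_positions(100, seed = 1)
#' table(nt$hemisphere)
#' @export
generate_positions <- function(n_per_hemisphere, density = 1 / 180, gap = 40,
                               min_separation = 4,
                               axis_ratio = c(0.8, 3, 0.5), seed = 1L) {
  if (n_per_hemisphere < 1) abort("`n_per_hemisphere` must be positive")
  stopifnot_scalar(density, "density", lower = 0, strict_lower = TRUE)
  volume <- n_per_hemisphere / density
  # semi-axes a*r1, a*r2, a*r3 with (4/3) pi a^3 r1 r2 r3 = volume
  a <- (volume * 3 / (4 * pi * prod(axis_ratio)))^(1 / 3)
  semi <- a * axis_ratio
  # infeasible if requested separation packs tighter than the volume allows
  if (n_per_hemisphere * (4 / 3) * pi * (min_separation / 2)^3 > 0.5 * volume) {
    abort("requested density infeasible at this `min_separation`")
  }
  hemis <- list(L = -1, R = +1)
  parts <- with_seed(seed, {
    lapply(names(hemis), function(h) {
      side <- hemis[[h]]
      centre <- c(side * (gap / 2 + semi[1]), 0, 0)
      pts <- sample_ellipsoid(n_per_hemisphere, centre, semi, min_separation)
      tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3], hemisphere = h)
    })
  })
  nt <- bind_rows(parts)
  nt <- mutate(nt, id = seq_len(nrow(nt)), .before = 1L)
  curves <- lapply(names(hemis), function(h) {
    side <- hemis[[h]]
    cx <- side * (gap / 2 + semi[1])
    s <- seq(-semi[2], semi[2], length.out = 41L)
    # gentle lateral bow so the axis is genuinely curved
    cbind(x = cx + side * 0.25 * semi[1] * cos(pi * s / (2 * semi[2])),
          y = s, z = rep(0, length(s)))
  })
  names(curves) <- names(hemis)
  proj <- lapply(names(hemis), function(h) {
    idx <- nt$hemisphere == h
    project_coordinates(nt[idx, ], curves[[h]])
  })
  nt$ap <- NA_real_
  nt$ml <- NA_real_
  for (i in seq_along(hemis)) {
    idx <- nt$hemisphere == names(hemis)[i]
    nt$ap[idx] <- proj[[i]]$ap
    nt$ml[idx] <- proj[[i]]$ml
  }
  attr(nt, "ap_curves") <- curves
  class(nt) <- c("tectal_neurons", class(nt))
  nt
}

# Uniform samples inside an ellipsoid with a minimum pairwise separation,
# by dart throwing in batches.
sample_ellipsoid <- function(n, centre, semi, min_sep) {
  kept <- matrix(numeric(0), ncol = 3L)
  max_rounds <- 200L
  for (round in seq_len(max_rounds)) {
    need <- n - nrow(kept)
    if (need <= 0L) break
    m <- max(need * 3L, 32L)
    u <- matrix(rnorm(3L * m), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    r <- runif(m)^(1 / 3)
    cand <- sweep(u * r, 2L, semi, `*`)
    cand <- sweep(cand, 2L, centre, `+`)
    for (k in seq_len(nrow(cand))) {
      p <- cand[k, ]
      if (nrow(kept) > 0L) {
        d2 <- (kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2 + (kept[, 3] - p[3])^2
        if (min(d2) < min_sep^2) next
      }
      kept <- rbind(kept, p)
      if (nrow(kept) == n) break
    }
  }
  if (nrow(kept) < n) abort("could not place all neurons; reduce density")
  dimnames(kept) <- NULL
  kept
}

#' Project neurons onto a curved anterior-posterior axis
#'
#' Computes, for each neuron, its arclength position along a traced
#' anterior-posterior polyline (`ap`) and its minimal distance to that curve
#' (`ml`), both in micrometres — the 2D coordinate system used for
#' correlation-map fitting.
#'
#' @param neurons Data frame with `x`, `y`, `z` columns (um).
#' @param ap_curve Numeric matrix with 3 columns: polyline vertices, at least
#'   two and of positive total length.
#' @return A tibble with columns `id` (if present in `neurons`), `ap`, `ml`.
#' @examples
#' curve <- cbind(seq(0, 100, 10), 0, 0)
#' project_coordinates(data.frame(x = 10, y = 5, z = 0), curve)
#' @export
project_coordinates <- function(neurons, ap_curve) {
  ap_curve <- as.matrix(ap_curve)
  if (nrow(ap_curve) < 2L) abort("`ap_curve` needs at least 2 vertices")
  seg <- diff(ap_curve)
  seg_len <- sqrt(rowSums(seg^2))
  if (sum(seg_len) <= 0) abort("`ap_curve` has zero length")
  arc0 <- c(0, cumsum(seg_len))
  pts <- as.matrix(neurons[, c("x", "y", "z")])
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_arc <- rep(0, n)
  for (s in seq_len(nrow(seg))) {
    if (seg_len[s] == 0) next
    a <- ap_curve[s, ]
    v <- seg[s, ] / seg_len[s]
    rel <- sweep(pts, 2L, a, `-`)
    t_par <- pmin(pmax(rel %*% v, 0), seg_len[s])
    foot <- outer(as.numeric(t_par), v) # n x 3 offset along segment
    d2 <- rowSums((rel - foot)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- arc0[s] + t_par[upd]
  }
  out <- tibble(ap = best_arc, ml = sqrt(best_d2))
  if ("id" %in% names(neurons)) out <- tibble(id = neurons$id, ap = out$ap, ml = out$ml)
  out
}
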