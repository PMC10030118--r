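# Evolutionary multi-objective calibration of the seven model parameters
# against burst-statistics objectives, with elbow selection and pattern
# search refinement.

#' Objective losses for one parameter set
#'
#' Simulates the network at the given parameters, detects bursts, computes
#' the three objective curves ([objective_curves()]) and returns the sum of
#' squared errors against the targets, per objective: (1) log-binned
#' log-rates of burst sizes, (2) of burst durations, (3) the scaled
#' burst-triggered activity timecourse. Size/duration SSEs are computed over
#' bins where the target is defined; bins empty in the simulation but
#' populated in the target enter with a half-count floor rate. A parameter
#' set that produces no bursts receives `NA` losses, which [evolve()]
#' penalises relative to the current generation.
#'
#' @param params [model_params()].
#' @param neurons Neuron table (typically one hemisphere, mirroring the
#'   reduced evaluation used during calibration).
#' @param eval_config [sim_config()] describing evaluation length, discard
#'   and seed.
#' @param targets An `objective_set` from [objective_curves()].
#' @return Numeric length-3 vector of losses (`NA` if no bursts), with the
#'   burst count as attribute `n_bursts`.
#' @export
objective_losses <- function(params, neurons, eval_config, targets) {
  sim <- tryCatch(
    simulate_network(neurons, params, eval_config),
    error = function(e) NULL)
  if (is.null(sim)) {
    out <- rep(Inf, 3)
    attr(out, "n_bursts") <- 0L
    return(out)
  }
  r <- binned_raster(sim)
  bursts <- detect_bursts(r, neurons)
  curves <- objective_curves(bursts, r)
  losses <- curve_sse(curves, targets, raster_duration(r) / 60)
  attr(losses, "n_bursts") <- nrow(bursts)
  losses
}

# SSE between simulated and target objective curves.
curve_sse <- function(curves, targets, duration_min) {
  if (is.null(curves$size)) return(rep(NA_real_, 3))
  floor_rate <- log10(0.5 / duration_min)
  sse_hist <- function(sim_tab, tgt_tab) {
    ok <- is.finite(tgt_tab$log10_rate)
    sim_v <- sim_tab$log10_rate[ok]
    sim_v[!is.finite(sim_v)] <- floor_rate
    sum((sim_v - tgt_tab$log10_rate[ok])^2)
  }
  l1 <- sse_hist(curves$size, targets$size)
  l2 <- sse_hist(curves$duration, targets$duration)
  m <- min(nrow(curves$suppression), nrow(targets$suppression))
  l3 <- sum((curves$suppression$value[seq_len(m)] -
               targets$suppression$value[seq_len(m)])^2)
  c(size = l1, duration = l2, suppression = l3)
}

# Fast non-dominated sorting: returns front index per individual
# (1 = non-dominated). Minimisation in all objectives.
pareto_rank <- function(losses) {
  n <- nrow(losses)
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  front <- 0L
  while (length(remaining)) {
    front <- front + 1L
    sub <- losses[remaining, , drop = FALSE]
    nd <- vapply(seq_along(remaining), function(i) {
      !any(vapply(seq_along(remaining), function(j) {
        if (i == j) return(FALSE)
        all(sub[j, ] <= sub[i, ]) && any(sub[j, ] < sub[i, ])
      }, logical(1)))
    }, logical(1))
    rank[remaining[nd]] <- front
    remaining <- remaining[!nd]
  }
  rank
}

# Genotype-space crowding distance within a front (NSGA-II style but on
# normalised parameter vectors): per dimension, boundary individuals get
# Inf, interior ones the normalised gap between neighbours; summed over
# dimensions. Larger = less crowded.
crowding_distance <- function(genotypes) {
  n <- nrow(genotypes)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(genotypes))) {
    v <- genotypes[, k]
    rng <- diff(range(v))
    ord <- order(v)
    d[ord[1L]] <- Inf
    d[ord[n]] <- Inf
    if (rng > 0) {
      d[ord[2:(n - 1L)]] <- d[ord[2:(n - 1L)]] +
        (v[ord[3:n]] - v[ord[1:(n - 2L)]]) / rng
    }
  }
  d
}

param_order <- c("g_e", "g_i", "sigma_e", "sigma_i", "tau_e", "tau_i", "mu")
log_scaled <- c("g_e", "g_i", "sigma_e", "sigma_i", "tau_e", "tau_i")

# Map between natural parameters and the (partially log) search space.
to_search <- function(theta) {
  out <- theta
  out[log_scaled] <- log(pmax(theta[log_scaled], 1e-12))
  out
}
from_search <- function(z) {
  out <- z
  out[log_scaled] <- exp(z[log_scaled])
  out
}

params_from_vector <- function(theta, template) {
  template$g_e <- unname(theta["g_e"]); template$g_i <- unname(theta["g_i"])
  template$sigma_e <- unname(theta["sigma_e"])
  template$sigma_i <- unname(theta["sigma_i"])
  template$tau_e <- unname(theta["tau_e"]); template$tau_i <- unname(theta["tau_i"])
  template$mu <- unname(theta["mu"])
  template
}

#' Evolve a population of models against burst-statistics objectives
#'
#' Controlled elitist evolutionary multi-objective optimisation with a
#' genotype-based crowding measure. Each generation: parents are selected
#' by tournament on the previous ranking; 80% of children are produced by
#' intermediate crossover (each parameter drawn uniformly between the two
#' parents' values) and 20% by adaptive mutation (log-normal steps whose
#' sign vector is kept while mean population fitness improves and
#' re-randomised otherwise); the extended population (parents + children)
#' is ranked by Pareto front order and, within fronts, by genotype crowding
#' distance (less crowded ranked higher), then trimmed back to `pop_size`.
#' Individuals producing zero bursts receive, per objective, ten times the
#' worst finite loss of the current generation. Evaluation uses one fixed
#' simulation seed per generation, shared across individuals so dominance
#' comparisons are fair.
#'
#' Gains, space constants and time constants are searched in log space;
#' `free` restricts the search to a subset of the seven parameters, the
#' rest staying at `start` values.
#'
#' @param targets [objective_curves()] target set.
#' @param neurons Neuron table for evaluations (single hemisphere
#'   recommended).
#' @param eval_config [sim_config()] for evaluations (its seed is re-derived
#'   each generation).
#' @param bounds Named list of length-2 numeric ranges for free parameters
#'   (natural units).
#' @param start A [model_params()] giving fixed values for non-free
#'   parameters.
#' @param free Character vector of parameter names being calibrated.
#' @param pop_size Population size (default 200; reduce for desk-scale
#'   runs).
#' @param generations Number of generations.
#' @param tournament Tournament size (default 2).
#' @param p_crossover Fraction of children from crossover (default 0.8).
#' @param mutation_scale Log-normal mutation SD as a fraction of the bound
#'   range in search space (default 0.1).
#' @param seed Master seed.
#' @param verbose Print per-generation progress.
#' @param loss_fn Optional `function(params, gen_seed) -> 3 losses`
#'   replacing the simulation-based [objective_losses()] (used for cheap
#'   algorithmic tests).
#' @return An object of class `emoo_population`: tibble with one row per
#'   individual of the final population (parameters, three losses, `rank`,
#'   `crowding`, `n_bursts`) plus attributes `history` (per-generation best
#'   scalarised loss), `initial_losses` (loss matrix of the random initial
#'   population) and `free`.
#' @export
evolve <- function(targets, neurons, eval_config, bounds, start,
                   free = c("g_e", "g_i", "mu"), pop_size = 200L,
                   generations = 10L, tournament = 2L, p_crossover = 0.8,
                   mutation_scale = 0.1, seed = 1L, verbose = FALSE,
                   loss_fn = NULL) {
  if (generations < 1L) abort("`generations` must be >= 1")
  stopifnot(all(free %in% param_order), all(free %in% names(bounds)))
  lo <- vapply(bounds[free], `[`, numeric(1), 1L)
  hi <- vapply(bounds[free], `[`, numeric(1), 2L)
  if (!all(is.finite(lo)) || !all(is.finite(hi))) abort("bounds must be finite")
  base_theta <- c(g_e = start$g_e, g_i = start$g_i, sigma_e = start$sigma_e,
                  sigma_i = start$sigma_i, tau_e = start$tau_e,
                  tau_i = start$tau_i, mu = start$mu)
  z_lo <- to_search(replace(base_theta, free, lo))[free]
  z_hi <- to_search(replace(base_theta, free, hi))[free]

  eval_ind <- function(z, gen_seed) {
    theta <- base_theta
    theta[free] <- from_search(setNames(z, free))[free]
    p <- params_from_vector(theta, start)
    if (!is.null(loss_fn)) return(loss_fn(p, gen_seed))
    cfg <- eval_config
    cfg$seed <- gen_seed
    objective_losses(p, neurons, cfg, targets)
  }
  evaluate_pop <- function(Z, gen_seed) {
    res <- lapply(seq_len(nrow(Z)), function(i) eval_ind(Z[i, ], gen_seed))
    L <- do.call(rbind, res)
    nb <- vapply(res, function(r) attr(r, "n_bursts") %||% 0L, integer(1))
    # zero-burst penalty: 10x worst finite loss per objective
    for (k in seq_len(ncol(L))) {
      bad <- !is.finite(L[, k])
      if (any(bad)) {
        worst <- if (any(!bad)) max(L[!bad, k]) else 1
        L[bad, k] <- 10 * max(worst, 1e-6)
      }
    }
    list(L = L, n_bursts = nb)
  }

  set.seed(child_seed(seed, 100L))
  Z <- matrix(runif(pop_size * length(free), rep(z_lo, each = pop_size),
                    rep(z_hi, each = pop_size)), nrow = pop_size)
  colnames(Z) <- free
  gen_seed <- child_seed(seed, 200L)
  ev <- evaluate_pop(Z, gen_seed)
  L <- ev$L
  initial_losses <- L
  nb <- ev$n_bursts
  rank <- pareto_rank(L)
  crowd <- rank_crowding(Z, rank, z_lo, z_hi)
  mut_sign <- sample(c(-1, 1), length(free), replace = TRUE)
  prev_mean <- mean(scalarise(L))
  history <- numeric(generations)

  for (gen in seq_len(generations)) {
    ord_key <- order(rank, -crowd)
    pos <- integer(pop_size)
    pos[ord_key] <- seq_len(pop_size) # 1 = best
    pick_parent <- function() {
      cand <- sample.int(pop_size, tournament, replace = TRUE)
      cand[which.min(pos[cand])]
    }
    n_child <- pop_size
    n_cross <- round(p_crossover * n_child)
    children <- matrix(NA_real_, n_child, length(free))
    for (c_i in seq_len(n_cross)) {
      p1 <- Z[pick_parent(), ]; p2 <- Z[pick_parent(), ]
      u <- runif(length(free))
      children[c_i, ] <- p1 + u * (p2 - p1)
    }
    step_sd <- mutation_scale * (z_hi - z_lo)
    for (c_i in seq(n_cross + 1L, n_child)) {
      p1 <- Z[pick_parent(), ]
      children[c_i, ] <- p1 + mut_sign * abs(rnorm(length(free), 0, step_sd))
    }
    children <- pmin(pmax(children, rep(z_lo, each = n_child)),
                     rep(z_hi, each = n_child))
    colnames(children) <- free
    gen_seed <- child_seed(seed, 200L + gen)
    ev_c <- evaluate_pop(children, gen_seed)
    Z_ext <- rbind(Z, children)
    L_ext <- rbind(L, ev_c$L)
    nb_ext <- c(nb, ev_c$n_bursts)
    rank_ext <- pareto_rank(L_ext)
    crowd_ext <- rank_crowding(Z_ext, rank_ext, z_lo, z_hi)
    keep <- order(rank_ext, -crowd_ext)[seq_len(pop_size)]
    Z <- Z_ext[keep, , drop = FALSE]
    L <- L_ext[keep, , drop = FALSE]
    nb <- nb_ext[keep]
    rank <- pareto_rank(L)
    crowd <- rank_crowding(Z, rank, z_lo, z_hi)
    new_mean <- mean(scalarise(L))
    if (new_mean >= prev_mean) {
      mut_sign <- sample(c(-1, 1), length(free), replace = TRUE)
    }
    prev_mean <- new_mean
    history[gen] <- min(rowSums(L))
    if (verbose) {
      message(sprintf("generation %d: best summed loss %.4g (front size %d)",
                      gen, history[gen], sum(rank == 1L)))
    }
  }

  thetas <- t(apply(Z, 1L, function(z) {
    th <- base_theta
    th[free] <- from_search(setNames(z, free))[free]
    th
  }))
  out <- as_tibble(as.data.frame(thetas))
  out$loss_size <- L[, 1]; out$loss_duration <- L[, 2]
  out$loss_suppression <- L[, 3]
  out$rank <- rank; out$crowding <- crowd; out$n_bursts <- nb
  attr(out, "history") <- history
  attr(out, "initial_losses") <- initial_losses
  attr(out, "free") <- free
  attr(out, "start") <- start
  class(out) <- c("emoo_population", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scalarise <- function(L) rowSums(scale_cols(L))

scale_cols <- function(L) {
  apply(L, 2L, function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) v - mean(v) else (v - mean(v)) / s
  })
}

# Crowding computed within each front on normalised genotypes.
rank_crowding <- function(Z, rank, z_lo, z_hi) {
  Zn <- sweep(sweep(Z, 2L, z_lo, `-`), 2L, pmax(z_hi - z_lo, 1e-12), `/`)
  crowd <- numeric(nrow(Z))
  for (f in unique(rank)) {
    idx <- which(rank == f)
    crowd[idx] <- crowding_distance(Zn[idx, , drop = FALSE])
  }
  crowd
}

#' Select the elbow individual of the Pareto front
#'
#' Restricts the population to its first (non-dominated) front, z-scores
#' each loss dimension across the front and returns the individual closest
#' to the origin of the z-scored loss space. A loss dimension with zero
#' variance across the front is centred only, with a warning.
#'
#' @param population An `emoo_population` (or any tibble with the three
#'   loss columns and `rank`).
#' @return A single-row tibble: the selected individual.
#' @export
select_elbow <- function(population) {
  if (nrow(population) == 0L) abort("population is empty")
  front <- population[population$rank == min(population$rank), ]
  L <- as.matrix(front[, c("loss_size", "loss_duration", "loss_suppression")])
  if (!all(is.finite(L))) abort("front contains non-finite losses")
  Zs <- apply(L, 2L, function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      warn("zero variance in a loss dimension; centred only")
      v - mean(v)
    } else {
      (v - mean(v)) / s
    }
  })
  if (is.null(dim(Zs))) Zs <- matrix(Zs, nrow = 1L)
  front[which.min(rowSums(Zs^2)), ]
}

#' Pattern-search refinement of a parameter set
#'
#' Coordinate pattern search on a scalarised loss (equal-weight sum of
#' z-scored objective losses, with the z statistics frozen at the supplied
#' values, typically from the final front of [evolve()]). Each iteration
#' polls every free parameter at +/- the current step (in search space,
#' respecting the bounds); if no poll improves, the step is halved. Stops
#' when the evaluation budget is exhausted or the step falls below
#' `step_tol`.
#'
#' @param start Named 7-vector (or [model_params()]) starting point.
#' @param targets Objective targets.
#' @param neurons,eval_config As in [objective_losses()]; pass
#'   `loss_fn` to optimise an arbitrary function instead (used in tests).
#' @param bounds Named list of ranges for free parameters.
#' @param free Parameters to refine.
#' @param budget Maximum number of loss evaluations (0 returns `start`).
#' @param z_center,z_scale Numeric length-3 freeze of the scalarisation
#'   (defaults: centre 0, scale 1).
#' @param step0 Initial step as fraction of bound range (default 0.25).
#' @param step_tol Stop when the step fraction falls below this (default
#'   1e-3).
#' @param loss_fn Optional `function(params) -> 3 losses` overriding the
#'   simulation-based loss.
#' @return List with `params` (a `tectal_params`), `loss` (scalarised),
#'   `trace` (tibble of accepted moves), `evals`.
#' @export
pattern_search_refine <- function(start, targets = NULL, neurons = NULL,
                                  eval_config = NULL, bounds,
                                  free = c("g_e", "g_i", "mu"),
                                  budget = 60L, z_center = rep(0, 3),
                                  z_scale = rep(1, 3), step0 = 0.25,
                                  step_tol = 1e-3, loss_fn = NULL) {
  if (inherits(start, "tectal_params")) {
    template <- start
    theta <- c(g_e = start$g_e, g_i = start$g_i, sigma_e = start$sigma_e,
               sigma_i = start$sigma_i, tau_e = start$tau_e,
               tau_i = start$tau_i, mu = start$mu)
  } else {
    theta <- start[param_order]
    template <- do.call(model_params, as.list(theta))
  }
  lo <- vapply(bounds[free], `[`, numeric(1), 1L)
  hi <- vapply(bounds[free], `[`, numeric(1), 2L)
  z_lo <- to_search(replace(theta, free, lo))[free]
  z_hi <- to_search(replace(theta, free, hi))[free]
  if (is.null(loss_fn)) {
    loss_fn <- function(p) objective_losses(p, neurons, eval_config, targets)
  }
  scalar <- function(l3) {
    if (!all(is.finite(l3))) return(Inf)
    sum((l3 - z_center) / z_scale)
  }
  eval_at <- function(z) {
    th <- theta
    th[free] <- from_search(setNames(z, free))[free]
    scalar(loss_fn(params_from_vector(th, template)))
  }
  z <- to_search(theta)[free]
  evals <- 0L
  if (budget <= 0L) {
    return(list(params = params_from_vector(theta, template), loss = NA_real_,
                trace = tibble(), evals = 0L))
  }
  best <- eval_at(z); evals <- evals + 1L
  step <- step0
  trace <- list(tibble(eval = evals, loss = best, step = step))
  while (evals < budget && step > step_tol) {
    improved <- FALSE
    for (k in seq_along(free)) {
      for (sgn in c(1, -1)) {
        if (evals >= budget) break
        z_try <- z
        z_try[k] <- min(max(z[k] + sgn * step * (z_hi[k] - z_lo[k]), z_lo[k]),
                        z_hi[k])
        if (z_try[k] == z[k]) next
        val <- eval_at(z_try); evals <- evals + 1L
        if (val < best) {
          best <- val
          z <- z_try
          improved <- TRUE
          trace[[length(trace) + 1L]] <-
            tibble(eval = evals, loss = best, step = step)
          break
        }
      }
      if (improved) break
    }
    if (!improved) step <- step / 2
  }
  th <- theta
  th[free] <- from_search(setNames(z, free))[free]
  list(params = params_from_vector(th, template), loss = best,
       trace = bind_rows(trace), evals = evals)
}
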