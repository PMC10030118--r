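# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Tiny two-hemisphere network (200 cells per side).
tiny_neurons <- function() {
  fixture("tiny_neurons", function() generate_positions(200, seed = 101))
}

# One hemisphere of a small standard-style network.
small_hemisphere <- function() {
  fixture("small_hemisphere", function() {
    nt <- generate_positions(600, seed = 202)
    ntL <- nt[nt$hemisphere == "L", ]
    ntL$id <- seq_len(nrow(ntL))
    ntL
  })
}

# A short ongoing-activity simulation of the small hemisphere at the
# shipped parameters, with the imaging-equivalent raster.
small_sim <- function() {
  fixture("small_sim", function() {
    nt <- small_hemisphere()
    sim <- simulate_network(nt, optimized_params(),
                            sim_config(duration = 480, discard = 120,
                                       seed = 303, log_drive = "none"))
    list(neurons = nt, sim = sim, raster = binned_raster(sim))
  })
}

# Brute-force DBSCAN: exhaustive density-connectivity by transitive
# closure over core-point neighbourhoods. Independent of the package's
# implementation.
brute_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  nbr <- d <= eps
  core <- rowSums(nbr) >= min_pts
  # adjacency between core points within eps; transitive closure
  reach <- nbr & outer(core, core, `&`)
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach > 0)
  }
  labs <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (labs[i] == 0L) {
      cl <- cl + 1L
      comp <- which(reach[i, ] | seq_len(n) == i)
      labs[intersect(comp, which(core))] <- cl
    }
  }
  # border points: attach to any core cluster within eps
  for (i in which(!core)) {
    near_core <- which(nbr[i, ] & core)
    if (length(near_core)) labs[i] <- labs[near_core[1L]]
  }
  labs
}

# Canonical form of a clustering: list of sorted member sets, sorted by
# first member (label-invariant comparison).
cluster_sets <- function(labs) {
  s <- lapply(split(seq_along(labs), labs), sort)
  s <- s[names(s) != "0"]
  unname(s[order(vapply(s, `[`, integer(1), 1L))])
}

# Brute-force Pareto helpers shared by emoo and acceptance tests.
brute_dominates <- function(a, b) all(a <= b) && any(a < b)

brute_fronts <- function(L) {
  n <- nrow(L)
  rank <- rep(NA_integer_, n)
  left <- seq_len(n)
  f <- 0L
  while (length(left)) {
    f <- f + 1L
    nd <- vapply(left, function(i) {
      !any(vapply(left, function(j) j != i && brute_dominates(L[j, ], L[i, ]),
                  logical(1)))
    }, logical(1))
    rank[left[nd]] <- f
    left <- left[!nd]
  }
  rank
}

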