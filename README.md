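# tectalnp

Ongoing activity in the larval zebrafish optic tectum is intermittently
*bursty*: spatially compact groups of neurons fire together for a couple of
seconds, and these avalanche-like events both reflect and reshape the
excitability of the surrounding network. `tectalnp` implements a minimal
recurrent spiking-network account of these dynamics and the analyses built
on top of it, for computational neuroscientists who want a tested,
self-contained reimplementation that runs end-to-end on synthetic data.

## The model

Every neuron follows the same linear-nonlinear-Poisson (LNP) rule. The
firing rate of neuron *j* is the exponential of its linear drive

φ_j(t) = x_j(t) + Σ_i (I^E_ij − I^I_ij) ∗ y_i + μ,  λ_j(t) = exp(φ_j(t)),

with spatially Gaussian, temporally exponential coupling filters

I^X_ij(t) = g_X · exp(−d²_ij / 2σ²_X − t/τ_X),  X ∈ {E, I}.

Excitation is strong, short-range (σ_E = 4.5 µm) and fast (τ_E = 0.05 s);
suppression is long-range (σ_I = 40 µm) and slow (τ_I = 24.1 s). Seven
global parameters plus the soma positions fully determine the network.
This motif — fast local excitation balanced by slow activity-dependent
suppression — is sufficient to produce localized intermittent bursting,
post-burst suppression lasting tens of seconds, trial-to-trial response
variability explained by recent activity history, spatially selective
post-stimulus suppression, and stimulus-specific adaptation.

The package provides, as composable functions returning tibbles:

* `generate_positions()`, `generate_dataset()` — synthetic two-hemisphere
  anatomy, rasters with logged ground-truth drive, events, implanted
  receptive fields (simulator-driven or surrogate-Poisson control);
* `simulate_network()` — the stochastic two-timescale LNP simulator;
* `detect_bursts()`, `burst_statistics()` — density-clustering burst
  detection (DBSCAN, ε = 15 µm, MinPts = 12) with Poisson-filtered burst
  extents, log-binned size/duration statistics and burst-triggered
  suppression/participation profiles;
* `correlation_map()`, `fit_correlation_map()` — seed-based correlation
  maps and bounded bivariate-Gaussian/exponential fits in projected
  tectal coordinates;
* `evolve()`, `select_elbow()`, `pattern_search_refine()` — elitist
  evolutionary multi-objective calibration with genotype crowding, elbow
  selection and pattern-search refinement;
* `estimate_drive()`, `baseline_correct()`, `fit_threshold_linear()`,
  `drive_recovery()` — excitability estimation from spiking history and
  threshold-linear response models;
* `build_protocol()`, `make_external_input()`, `identify_responsive()`,
  `post_stimulus_suppression()`, `response_modulation()`,
  `population_adaptation()` — receptive-field, suppression and
  oddball-adaptation experiments.

Fitted objects have broom-style `tidy()`/`glance()` methods and
`autoplot()` views.

## Worked example

Simulate ten minutes of ongoing activity in a 750-cell hemisphere at the
shipped calibrated parameters, then detect and summarise bursts:

```r
library(tectalnp)

nt   <- generate_positions(750, seed = 1)
ntL  <- dplyr::filter(nt, hemisphere == "L")
sim  <- simulate_network(ntL, optimized_params(),
                         sim_config(duration = 720, discard = 120, seed = 1))
rast <- binned_raster(sim)          # 200 ms imaging-equivalent frames
bursts <- detect_bursts(rast, ntL)
bursts
#> # A tibble: 20 x 10
#>   burst_id peak_frame t_init t_term  size duration centroid_x centroid_y
#>      <int>      <int>  <int>  <int> <int>    <dbl>      <dbl>      <dbl>
#> 1        1         73     66     79    51      2.8      -46.2      -71.4
#> 2        2        212    206    217   219      2.4      -42.6       29.7
#> 3        3        296    288    302    81      3        -45.9      -65.5
#> # ... with 17 more rows, 2 more variables: centroid_z <dbl>, members <list>

burst_statistics(bursts, rast, seed = 1)
#> Burst statistics: 20 bursts, 2 per minute
```

Each row is one detected burst: a density-connected set of ≥ 12 cells
active around a population-activity peak, with initiation/termination
times from the Poisson-filtered activity of its members. At this reduced
scale the burst rate, scaled by cell count to the full ~1.47·10⁴-cell
network, the burst sizes (tens to hundreds of neurons) and durations
(~1–5 s) sit in the ranges reported for the biological tectum; the
suppression profile in `burst_statistics()` shows participants quieter
than baseline for tens of seconds after a burst.

Estimating each cell's excitability (linear drive) before an event from
the spike raster alone, and checking it against the simulator's logged
ground truth:

```r
ds  <- generate_dataset(synthetic_config(n_per_hemisphere = 1500, seed = 42),
                        duration = 1500, discard = 120, n_events = 16,
                        hemisphere = "L")
rec <- drive_recovery(ds$raster, ds$drive, ds$neurons, ds$params,
                      ds$events$time)
rec$median_r
#> [1] 0.947
```

The median per-neuron correlation between estimated and true pre-event
drive is ≈ 0.95; on a history-free surrogate raster it collapses towards
zero — recent spiking history, filtered through the model, genuinely
carries the network's excitability state.

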