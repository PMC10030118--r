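---
title: "A recurrent LNP network model of tectal dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A recurrent LNP network model of tectal dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tectalnp)
```

## The model

`tectalnp` implements a minimal stochastic spiking network account of
ongoing and visually evoked population activity in the larval zebrafish
optic tectum. Every neuron follows the same linear-nonlinear-Poisson (LNP)
rule: its instantaneous firing rate is the exponential of a *linear drive*

$$\varphi_j(t) = x_j(t) + \sum_i \big(I^E_{ij} - I^I_{ij}\big) * y_i + \mu,
\qquad \lambda_j(t) = e^{\varphi_j(t)},$$

where $x_j$ is an instantaneous external (visual) input, $y_i$ are the
spike trains of all neurons (self-coupling included), $\mu$ a global bias,
and the coupling filters are separable in space and time:

$$I^X_{ij}(t) = g_X \exp\!\Big(-\frac{d_{ij}^2}{2\sigma_X^2}
 - \frac{t}{\tau_X}\Big), \qquad X \in \{E, I\}.$$

$d_{ij}$ is the 3D Euclidean somatic distance in micrometres. An
exponential spatial variant, random connection pruning with gain
compensation, and a 0.01 scaling of cross-hemisphere coupling are
supported. Seven global parameters — $g_E, g_I, \sigma_E, \sigma_I,
\tau_E, \tau_I, \mu$ — fully describe the network given the cell
positions. Excitation is strong, short-range ($\sigma_E = 4.5\,\mu m$) and
fast ($\tau_E = 0.05$ s); suppression is long-range ($\sigma_I = 40\,\mu
m$) and slow ($\tau_I = 24.1$ s), so it integrates activity over tens of
seconds. The linear drive doubles as an interpretable *excitability state*:
most analyses in the package are statements about $\varphi$.

### Units and rate convention

$\lambda = e^{\varphi}$ is the expected spike count per fast simulation
step (50 ms). The bias $\mu$ is therefore a log spike count per 50 ms; a
tonic rate of 0.05 spikes/s corresponds to $\mu \approx -6$ in the absence
of recurrent input.

### Integration scheme

The simulator advances in 50 ms steps; spike counts are Poisson draws with
mean $e^{\varphi}$, clamped at `phi_max`, and emitted spikes feed back into
the filters (a spike at step $t$ contributes $w\,e^{-(t'-t)\,dt/\tau}$ at
later steps $t'$). The excitatory filter state is updated every fast step.
The slow inhibitory pathway — whose coupling matrix is effectively dense —
is advanced only once per 5 s window: spikes are accumulated within the
window and enter the knot state at the boundary, discounted by half a
window of decay (their mean latency). Within a window the inhibitory drive
used at each fast step is the linear interpolation between the current
knot and the *running estimate* of the next knot (decayed knot plus the
inhibition of spikes accumulated so far). This keeps the slow pathway
causal and cheap (one sparse product per spiking step) while letting
suppression ramp in *within* a window. The alternative — decay-only
inhibition inside each window — leaves every nascent burst inhibition-blind
for up to 5 s, and in that case the exponential nonlinearity reliably
escalates local events into hemisphere-wide waves; with the ramped
interpolation the measured deviation from an exact 50 ms computation of
the slow pathway is below 15% in time-averaged drive for
$\tau_I \ge 10\,dt_{slow}$ (tested on a 200-neuron network).

### The saturation ceiling

`sim_config(phi_max = log(0.5))` caps the drive at 0.5 expected spikes per
step (10 spikes/s). This is a deliberate model choice, not only an
overflow guard. The exponential nonlinearity with strong local recurrence
is bistable per site: once any patch reaches a high-rate state, the drive
it exerts on its neighbours exceeds any plausible standing inhibition and
a self-sustaining wave recruits the entire hemisphere. A ceiling at a
physiological rate — comparable to the peak rates of burst participants in
calcium-imaging data — bounds the drive a bursting patch can export,
so bursts stay local, terminate within seconds, and leave behind the
long-lasting suppression footprint that the slow pathway encodes. With a
high ceiling (for example 10 spikes per step) we found no parameter regime
with localized intermittent bursting: networks either fell silent or
produced rare, clamp-rate global waves.

### Initialisation

By default the slow inhibitory state starts at its spatial steady state
for the baseline rate $e^{\mu}$ (`init_inhibition = "warm"`). A cold start
produces a network-wide burst in the first seconds (no standing
suppression) followed by minutes of over-suppression — the transient the
published procedure discards 15 minutes for. Warm initialisation shrinks
that transient to roughly one $\tau_I$; simulations here discard 120–150 s.

## Synthetic study conditions

The generator (`generate_positions()`, `generate_dataset()`) emulates the
anatomy the analyses need, not optical realism:

* **Positions.** Uniform samples with a 4 µm exclusion radius inside two
  mirrored, sheet-like ellipsoids (axis ratio 0.8 : 3 : 0.5, midline gap
  40 µm) at one soma per 180 µm³ (≈5.7 µm spacing, tightly packed
  periventricular somata). Density is held fixed across scales, so a
  hemisphere's extent grows with cell count; at 1,500 cells per hemisphere
  the anterior-posterior extent (~220 µm) spans several $\sigma_I$, which
  is what allows spatially localized burst statistics. A curved
  anterior-posterior reference line is generated per hemisphere and used
  for the 2D (arclength, distance-to-curve) projection.
* **Scale tiers.** Tiny (200/hemisphere) for unit tests, standard
  (1,500/hemisphere) for the acceptance analyses, full (7,366/hemisphere,
  ≈1.47·10⁴ cells) for the network size of the modelled recordings. Tests
  and the acceptance script run the tiny and standard tiers; the full tier
  is API-compatible but takes tens of minutes per half hour simulated.
* **Receptive fields.** Gaussian azimuth tuning with population width
  (2.5σ) of 38° ± 24°, log-normal gains, and elevation preference in bands
  along the anterior-posterior axis with azimuth mapped within each band.
  In fish, elevation maps mediolaterally; the generator deliberately uses
  the long axis so that, at reduced scale, the anatomical separation of
  the two elevation sets exceeds $\sigma_I$ — the property the suppression
  and adaptation analyses depend on. Input drive follows
  $x_j(t) = 2.5\cdot 10^3 \, A_j \exp(-(\alpha(t)-\mu_j)^2 /
  (2\,(0.8\sigma_j)^2))$ during sweeps of the matching elevation; mean
  implanted gains put peak drive near 3 log-units.
* **Events.** Saccade-like event lists are sampled preferentially at
  times of high mean anterior drive (softmax with inverse temperature 2),
  at least 75 s apart so that 60 s estimation windows do not overlap —
  overlapping windows make consecutive drive estimates strongly
  autocorrelated and reduce the effective number of trials.
* **Surrogate mode.** Homogeneous Poisson spiking at the population mean
  rate: history-independent and spatially structureless. It is the
  negative control for every history-dependent effect. Note that a
  memoryless surrogate still produces occasional chance density-clusters;
  what it cannot produce is post-event suppression or drive recovery.
* **Fluorescence.** An optional forward calcium model (exponential kernel,
  baseline, noise, optional slow drift) exists purely to exercise the
  ΔF/F₀ preprocessing (sliding 10th percentile of 20 volumes; ROIs whose
  mean-normalised baseline has SD > 0.45 are discarded).

What passing tests on these data do *not* show: robustness to optical
artifacts, spike-inference errors (simulated spikes stand in for
deconvolved events), anatomical anisotropies beyond two shells, or
cell-type heterogeneity.

## Parameter provenance

$\sigma_E, \tau_E, \sigma_I, \tau_I$ are fixed at the published optimised
values (4.5 µm, 0.05 s, 40 µm, 24.1 s); the baseline comparison variant
uses $\sigma_I = 20\,\mu m$, $\tau_I = 180$ s. The gains and bias are not
legible from the source material and were recovered by reduced-scale
calibration of the default synthetic network against the published
bursting statistics, under four simultaneous constraints fixed before
calibration:

1. burst rate, scaled by cell count to the full network, near 46/min;
2. burst size and duration distributions broad and centred near 95 cells
   and 2.5 s;
3. sparse tonic firing (a few hundredths of a spike per second per cell);
4. the MinPts-selection condition: per-neuron circular permutations of the
   raster must yield zero density-clusters at MinPts = 12, ε = 15 µm —
   the criterion by which MinPts was chosen for the recorded data, and
   therefore part of the study conditions the fixture must satisfy.

The shipped values are $g_E = 11$, $g_I = 0.009$, $\mu = -4.5$
(`optimized_params()`). At the standard tier they give a tonic rate of
≈0.046 spikes/s, 2.6 bursts/min (≈25/min scaled to 1.47·10⁴ cells), mean
burst size ≈126 cells and mean duration ≈2.8 s, with clean permutation
nulls. The package also ships the full evolutionary multi-objective
calibration machinery (`evolve()`, `select_elbow()`,
`pattern_search_refine()`, with `reference_objectives()` building
power-law targets from the published statistics). It is exercised at
reduced scale in the tests and improves markedly on random
initialisation; however, with desk-scale evaluation budgets (minutes per
individual rather than hours) its sum-of-squared-error objectives are
dominated by the smallest size bins of the power-law targets and it
drifts toward regimes of many borderline-detectability bursts (median
size ≈ MinPts). The shipped values therefore come from the constrained
exploration above rather than from the automated loop's end point.

## Burst detection choices

The pipeline follows the published procedure: population peaks on the
3-frame-smoothed mean trace (strictly greater than the previous smoothed
frame, at least equal to the next; plateaus take their first frame);
exclusion of bilateral-activation peaks (>10% of neurons active and <70%
of them in one hemisphere); DBSCAN over the 3D positions of cells active
(≥1 spike) within the 5-frame window centred on the peak, with ε = 15 µm
and MinPts = 12 (a core point's neighbourhood includes itself); and a
6-frame sliding Poisson filter in which per-cell window counts above the
smallest $k$ with $\mathrm{CDF}_{Pois(\bar\lambda)}(k) \ge 0.6$ are
discarded. The filtered-activity vector's contiguous non-zero run
containing the peak defines the burst extent (the filter output is
evaluated within ±15 s of the peak; in quiescent windows the threshold is
0, so the vector vanishes away from genuine activity). Bursts from
consecutive peaks are *not* merged by default (per-peak counting);
`merge_duplicates = TRUE` merges clusters sharing >50% membership with
overlapping extents. Log-binned statistics use a fixed decade grid with 8
bins per decade.

## Excitability estimation choices

Pre-event drive is estimated by applying the model's coupling filters to
the observed raster at frame resolution (5 Hz): spikes from −60 s to −5 s
before the event, with the final 5 s zeroed (spike-inference uncertainty),
bias and external input excluded. Cell-specific biases (edge effects) are
removed by subtracting the mean drive vector over 60 ongoing epochs
(uniformly sampled at least 90 s from any event, without replacement; the
exclusion relaxes by halves, with a warning, when a session is too short),
and the point estimate is the mean of the final 10 s of the corrected
vector. The threshold-linear fit
$y = (a(x - x_0) + |a(x - x_0)|)/2 + c$, $a \ge 0$ profiles $x_0$ over
data-derived candidates with $(a, c)$ solved by constrained linear least
squares, then refines locally. The recovery score used in the tests is
the median across neurons of the per-neuron correlation, across events,
between the estimated pre-event drive and the simulator's logged true
recurrent drive averaged over the same 10 s window.

## Correlation-map fitting choices

Traces are smoothed with a Gaussian window (σ = 1.4 frames, truncated at
±4σ, unit sum). The bivariate-Gaussian and exponential models are fitted
by bounded Levenberg-Marquardt least squares with the published bounds
($b \in [0, 0.8]$, $A \ge 0$ unbounded above, $\mu_x \in [-100, 1200]$,
$\mu_y \in [-100, 250]$, $\sigma \in (0, 500]$, $\rho \in [-1, 1]$); the
initial peak is drawn within 100 µm of the seed (clamped to the data
bounding box), with five random restarts plus one start at the observed
maximum, keeping the best $r^2$.

## Visual-protocol choices

Sweeps move at 20°/s over 110° (−55° to +55°, 5.5 s). The oddball design
presents a common stimulus every 30 s and a deviant every 5 min inside
30-min stimulation blocks separated by 30-min rests, each deviant followed
by a 90 s break in common presentations; an optional baseline block
presents every stimulus sparsely beforehand (used to define per-cell
baseline responses). Responsive cells must exceed the population's 90th
percentile of mean response rates (strictly) and five times their own
baseline rate (floored at one spike per session). Post-stimulus windows
default to 0–10 s and 10–30 s after sweep offset, normalised by each
set's ongoing rate. The per-presentation response scalar is the spike
count during the sweep. The synthetic retinal-input adaptation gain
multiplies common presentations only: towards a plateau of 0.5 with
per-event factor 0.8 and recovery $\tau = 300$ s, settling near 0.7 under
30 s ISIs with partial recovery during 90 s breaks (the measured input
profile it emulates is not available numerically; these values were
chosen once to reproduce the reported ≈70% steady-state response with
partial recovery).

## Numerical and degenerate-input policy

Spatial weights below $10^{-6} g$ are truncated and matrices stored
sparse. Coupling construction is blockwise to bound memory. Pruning
divides survivors by $1 - p$, preserving expected totals. Fits flag
non-convergence rather than erroring (`r2 = NA`); zero-variance traces are
excluded and counted; silent burst clusters are flagged degenerate and
dropped; a raster with no active cells yields empty peak and cluster
sets. One master seed drives independent child streams (positions,
pruning, spike emission, event placement, permutations), so identical
seeds give bit-identical spike output.

## Problem sizes used by the tests and acceptance script

Unit tests run the tiny tier (200–600 cells, 1–8 min of activity).
Acceptance analyses use: a 30-minute standard-tier (1,500-cell
single-hemisphere) simulation for burst statistics; a 25-minute session
with ~14 events for drive recovery plus a surrogate arm; ten ~33-minute
alternating-stimulation sessions (600 cells) for suppression and ten
~34-minute oddball protocols (500 cells) for adaptation; 10–20 raster
permutations for the null check; and a pop-8 × 2-generation evolutionary
run on a 400-cell hemisphere for the calibration-machinery check. These sizes are the package's chosen
reduced-scale study conditions; the full published scale (200 models ×
2¼-hour evaluations × 30 generations on a cluster) is out of scope.

## Known limitations

* The saturation ceiling is a modelling commitment; burst peak rates are
  pinned near it.
* Scaled-down hemispheres hold only a handful of independent
  $\sigma_I$-sized regions, so burst statistics are coarser and the
  burst-rate-per-volume mapping to the full network is approximate
  (linear cell-count scaling is used).
* The slow-pathway scheme trades ≤15% drive accuracy for a ~50× cost
  reduction of the inhibitory coupling.
* The evolutionary calibration is validated as machinery, not as the
  provenance of the shipped gains (see above).
* Correlation-map $r^2$ values on simulated rasters are not comparable to
  recorded-data values: simulated ongoing activity lacks several noise
  sources that depress (and spatial artifacts that inflate) empirical
  correlations.
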