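---
title: "Modelling conduction through spheroid-bearing axons and analysing the imaging readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling conduction through spheroid-bearing axons and analysing the imaging readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidax)
```

## The scientific problem

Plaque-associated axonal spheroids (PAASs) are large membrane-bound swellings
that form on axons passing near amyloid plaques. Electrically, a spheroid is a
patch of extra membrane — up to thousands of square micrometres — hanging off
an axon whose own diameter is a fraction of a micrometre. Charging that extra
membrane steals axial current from a passing action potential, so spheroids
are expected to delay or block conduction in a size-dependent way, degrading
the timing of every circuit the axon participates in. `spheroidax` provides
(i) a biophysical simulator to map where in (axon diameter, bulb area, channel
density) space conduction survives, slows, or fails, (ii) the trace-analysis
estimators used to measure conduction delays and AP-induction thresholds from
calcium and voltage imaging, (iii) population-activity statistics for
networks, and (iv) seeded synthetic-data generators so all of the above is
testable end to end without any recording.

## The cable model

The axon is a uniform unmyelinated cylinder, 566 µm long with diameter swept
over 0.1–0.9 µm, discretised into compartments obeying the Hodgkin–Huxley
cable equation with sodium, potassium and leak currents. The spheroid is a
"cylinder and stick": a neck (stick) 5 µm long, diameter 0.3–8.3 µm, joins
the axon midpoint to a bulb head whose *membrane surface area* (0–7,100 µm²)
is the controlled variable. Because the bulb's electrical role — a
capacitive/conductive current sink — depends on its area rather than its
shape, it is modelled as a single iso-potential compartment parameterised
directly by area. A bulb area of zero means "no spheroid" and such runs serve
as references. Bulb sizes are reported as the equivalent spherical diameter
`d = sqrt(A / pi)`; note the printed endpoints of the source ranges
(7,100 µm² and 150 µm) are mutually inconsistent under any spherical-area
convention, so the package treats them purely as sweep bounds.

### Channel kinetics and defaults

The underlying experimental work cites previously validated modelling
methodology without printing kinetics, so the package adopts the canonical
squid-axon Hodgkin–Huxley rate functions with standard densities
(`gNa = 0.12`, `gK = 0.036`, `gLeak = 0.0003` S/cm², `ENa = +50` mV,
`EK = −77` mV, `Cm = 1` µF/cm², `Ra = 100` Ω·cm), all overridable through
`channel_params()`. One deliberate choice: the default leak reversal is
`ELeak = −64.4 mV` rather than the textbook −54.4 mV. The density sweep
multiplies `gNa` and `gK` jointly by `density_scale` from 0 up to 1.1 × the
regenerative threshold, and with the textbook value the resting potential
would drift from −65 mV at full density to −54 mV at zero density, passing
through regions where the reduced-density membrane is unstable near rest.
With −64.4 mV the rest stays between −64.4 and −68.5 mV across the whole
sweep and a zero-stimulus simulation holds rest to < 0.01 mV at every
density. Spheroid compartments always carry the same (scaled) channel
densities as the axon; `channel_params()` enforces this contract.

`resting_potential()` solves the steady-state current balance exactly and the
solver is initialised there with all gates at steady state, so "rest" is a
true fixed point of the discrete scheme.

### Numerical scheme

Membrane voltages advance by a linearised backward-Euler step: gates are
updated first by exponential (Rush–Larsen) integration at the pre-step
voltage, then the voltage system — tridiagonal plus one branch point — is
solved exactly by a Hines sweep over the compartment tree. Rate functions are
tabulated on a 0.05 mV grid with linear interpolation, with `exp(−dt/τ)`
baked into the tables (they are rebuilt whenever `dt` changes). The default
step is `dt = 0.025 ms`; the default spatial resolution targets ~3 µm
segments (189 for the default axon), and `build_morphology()` refuses
discretisations whose segment length exceeds a configurable fraction
(default 0.1) of the passive length constant
`λ = sqrt(d Rm / (4 Ra))` (158 µm for a 0.3 µm axon). Under these defaults
the passive steady-state profile matches the analytic sealed-end cable
solution to ~3 × 10⁻⁴ % and halving `dt` or doubling the spatial resolution
moves detected AP times by ≤ 0.05 ms. Solver failure (non-finite voltage) is
raised as an error carrying `dt`, compartment count and density.

### Protocols, probes and outcome classification

Current pulses (0.2 ms, 2 nA by default — strong enough to reliably evoke a
single input AP) are injected at one axon end; the proximal probe sits just
distal to the injection site (5% of axon length) and the distal probe at the
far end, "the other side" of the midpoint spheroid. APs are detected as
upward crossings of +10 mV separated by a 2 ms refractory window (wider than
a spike, far below the 50 ms inter-pulse interval of a 20 Hz train). Each
output AP is matched to the nearest preceding input AP within one inter-pulse
interval; unmatched inputs are blocked APs.

One windowing convention matters for train protocols: a 20 Hz train starting
at 100 ms in a 10,000 ms window has pulse onsets at 100, 150, …, 10,000 ms —
199 pulses counting both ends — and the response to the last pulse peaks just
after the nominal window. `stimulus_protocol()` therefore integrates a short
tail (`tail_ms`, default 15 ms) past `sim_duration` so edge responses are
counted; pulse onsets themselves must stay inside `[0, sim_duration]`.

`classify_conduction()` compares an outcome with its spheroid-free reference:
`blocked` (no output APs), `partial_block` (some lost), `delayed` (all
conducted, median delay more than `delay_tolerance` above the reference), else
`normal`. The default `delay_tolerance = 0.25 ms` is roughly three times the
measured dt-convergence error of reference delays; there is no experimental
cutoff to inherit, so it is exposed as a parameter.

In `run_conduction_sweep()` the neck diameter by default co-varies with the
bulb: linear in the bulb's equivalent spherical diameter from 0.3 µm (area 0)
to 8.3 µm (7,100 µm²), matching the endpoints of both swept ranges; a fixed
neck diameter can be forced. Density grids are interpreted as multiples of
the per-diameter regenerative threshold `g*` found by bisection
(`find_regenerative_density()`), mirroring the convention of sweeping 0 to
1.1 × g*. Per-row failures are recorded in an `error` column and the sweep
continues.

```{r sweep, eval = FALSE}
sw <- run_conduction_sweep(diameter_grid = 0.3,
                           area_grid = c(0, 100, 250, 500, 7100),
                           density_grid = 1.1, protocol = "single",
                           sim_duration_ms = 300)
```

At 0.3 µm diameter and 1.1 × g*, growing the bulb area traverses all three
regimes — normal (≤ 100 µm²), delayed (≈ 100–250 µm²), blocked (≥ 500 µm²) —
with the output count non-increasing and the delay non-decreasing in area.

## Calcium-trace analysis

Raw traces are normalised to ΔF/F against the mean pre-stimulation baseline;
image stacks can be smoothed with a 3 × 3 mean filter (reflect padding at the
edges — a documented choice, the source is silent). The rising phase of an
event runs from the first data point exceeding the baseline (scanning back
from the event peak) through the peak, and is fitted with
`Y = 1 − exp(−k (x − t0))`; the x-intercept `t0` is the spike-time
surrogate. Choices the source leaves open:

* **Amplitude normalisation.** The model saturates at 1 but real events have
  arbitrary amplitude. Default: rescale the segment by its peak value. A free
  amplitude `Y = A (1 − exp(−k (x − t0)))` is available
  (`normalize = "free_amplitude"`) and is the right choice when the segment
  has not saturated — it recovers noiseless parameters to < 10⁻⁶ relative
  error, while peak-rescaling an unsaturated segment biases `k` upward.
* **Initialisation.** A log-linear regression of `log(1 − Y/A)` on time seeds
  `(k, t0)`, making the nonlinear fit robust to bad basins.
* **Bounds.** `k ∈ (0, 10 × rate]`; `t0` is bounded above by the peak time
  only. Clamping `t0` at the onset sample would truncate the estimator's
  sampling distribution and bias it low under noise; the type-level
  expectation that `t0` precedes the first supra-baseline sample emerges from
  well-formed data rather than being forced.
* **Minimum segment length** 3 samples; shorter events are rejected.
* **Spontaneous event detection** (`detect_calcium_events()`): local maxima
  above baseline + 3 MAD, configurable.

ROI-pair delays are `t0(distal) − t0(proximal)`. On synthetic pairs the
estimate tracks a planted delay to well under one frame, and grows with a
planted per-pulse block probability — but single-axon estimates are
heavy-tailed when many pulses are blocked, so population comparisons should
use medians across axons (the tests do). Axons qualify for spontaneous
analysis at ≥ 1 transient per minute, boundary inclusive.

## Voltage-imaging analysis

Kymographs (lines × pixels at 1 kHz) are reduced to a per-line mean over the
soma pixels. ASAP3-type indicators dim on depolarisation, so APs are *dips*;
the package keeps raw polarity throughout. A dip is accepted within a 30 ms
post-pulse search window if its depth below the pre-stimulus baseline median
exceeds 3 × the baseline MAD (both configurable; no published criterion
exists). Missing dips are conduction failures — data, not errors — and are
excluded from latency statistics.

Response strength per current is the 10 Hz discrete-spectrum power of the
soma trace — the stimulation frequency — after removing the mean and a linear
trend (photobleaching drift). Power is normalised as `|X_f|² / N²` so values
are comparable across trace lengths; the whole 1 s sweep is transformed (the
source does not state its windowing, this is the fixed documented
convention). The threshold is the half-height abscissa `b` of a logistic fit
`a / (1 + exp(−k (x − b)))` to power versus current, fitted by
Levenberg–Marquardt from a ladder of starting slopes (near-step data defeat a
single shallow start). Because power scales roughly as the squared per-pulse
success probability, the fitted `b` sits where success ≈ 0.7 rather than 0.5
— about +3 µA at the planted slopes used here, well inside one 10 µA current
step, which is the recovery tolerance the tests enforce (median over 50
seeds).

## Network metrics

All metrics consume a cells × bins spike raster (40 ms bins at 25 Hz; 30 min
sessions) plus cell centroids.

* **Spike inference** is a deliberately simple stand-in for dedicated
  deconvolution tools: per cell, FISTA iterations solve the non-negative
  LASSO `min ½‖y − K s‖² + λ‖s‖₁`, `K` the AR(1) calcium kernel, with both
  convolutions implemented as recursive filters (linear per iteration).
  Externally inferred rasters pass straight through `spike_raster()`.
* **Pairwise mutual information** is the plug-in estimator on binarised bins
  (count > 0) at the native bin width, in bits, one value per unordered pair,
  grouped into 25 µm distance bins. No bias correction is applied; the
  analytic plug-in bias bound `(K−1)²/(2N ln 2)` (K = 4 joint states) is
  attached to the result, and with N = 45,000 bins it is ~1.4 × 10⁻⁴ bits.
  Constant cells give MI 0 and are flagged degenerate.
* **Community detection** builds a graph from positive pairwise activity
  correlations above `r = 0.2` (configurable) and maximises modularity with
  Louvain under a fixed internal seed and cell-id vertex order, so the
  partition is bit-reproducible — the "forced deterministic behaviour"
  needed for reproducible cluster-size distributions. On planted two-group
  rasters it recovers the groups exactly, and for n ≤ 8 its modularity equals
  the exhaustive-search maximum in the test suite.
* **Population entropy** is the Shannon entropy of the empirical distribution
  of the per-bin population state, averaged over 100 random subsamples of 100
  neurons (both configurable) to compare sessions with different cell counts.
  The state definition is not pinned down by the source; the default is the
  per-bin count of active cells (a discretised population rate), with a
  binary-word mode (`state = "word"`) that needs coarse binning to avoid
  undersampling. The two variants are both documented and no equivalence is
  claimed. Lower entropy means more repetitive population dynamics.

## Synthetic data: what it emulates, and what it does not

Every generator is deterministic under (configuration, seed) and stores a
truth record sufficient to score the downstream estimator.

* `gen_gcamp_trace()`: spikes convolved with a difference-of-exponentials
  kernel (rise 50 ms, decay 400 ms — GCaMP6f-like defaults; the indicators
  themselves are not modelled biophysically) plus i.i.d. Gaussian noise.
* `gen_axon_roi_pair()`: a 50 Hz × 500 ms pulse train; the proximal ROI
  integrates every pulse, the distal ROI receives each pulse independently
  with probability `1 − block_prob`, shifted by the planted delay —
  per-pulse Bernoulli blocking, consistent with reading delays as partial
  conduction block of individual spikes.
* `gen_voltage_kymograph()`: per current, 10 pulses at 10 Hz over 1 s; each
  pulse elicits a Gaussian dip on the soma pixels with logistic success
  probability in the current.
* `gen_population_raster()`: cells uniform in a 400 µm field; activity mixes
  independent background spiking, a shared latent Gaussian factor with a
  squared-exponential spatial kernel (distance-decaying correlation), and
  stereotyped ensemble reactivations — in a fraction `pattern_rep` of bins
  the population state is replaced by one spatially contiguous cluster firing
  as a whole. The `"ad"` scenario plants frequent reactivation of few, large
  ensembles over a sparse background; `"wt"` plants a moderate independent
  background with weak spatial correlation and rare, small reactivations.
  These settings produce the qualitative disease pattern — higher spike
  counts, higher short-distance MI, larger clusters, lower population
  entropy — by construction; passing the end-to-end tests demonstrates that
  the *estimators order the scenarios correctly*, not that real cortical
  data behave this way. The generators likewise omit motion artefacts,
  segmentation errors, non-Gaussian noise and indicator nonlinearity, so
  absolute error levels in real recordings will be larger than the synthetic
  recoveries suggest.

A note on entropy and repetitiveness: the entropy of a mixture of background
states and stereotyped patterns contains a mixing term that can *raise*
entropy when patterns are rare novel states. Entropy decreases monotonically
in `pattern_rep` when the background state distribution is rich relative to
the pattern set (the regime the tests probe and the `"ad"` scenario lives
in); with a near-silent background and rare patterns the relationship is
non-monotone at small `pattern_rep`.

## Problem sizes and runtime

Defaults were chosen so a full check is quick on one core: the test suite
(~220 assertions) runs in ~20 s and `scripts/acceptance.R` in ~30 s. The
acceptance script uses the full 30 min / 150-cell population comparison and a
complete 10 s / 20 Hz train simulation; sweep-based checks use a single
diameter and a six-point area grid with 300 ms single-AP windows, which is
sufficient to exhibit all three regimes. Wider grids (e.g. 5 × 5 × 3 with
the 10 s train protocol) run in minutes via `run_conduction_sweep()`.

## Known limitations

* No myelination, branching arbors beyond the single spheroid, stochastic
  channel gating, temperature dependence, or synaptic input.
* Squid-axon kinetics at default parameters; mammalian axons differ
  quantitatively, so regime *boundaries* (critical areas) should be read as
  model-relative, not physiological predictions.
* The spike-inference stand-in is not a calibrated replacement for published
  deconvolution methods; use pass-through rasters for quantitative work.
* Plug-in MI is biased upward at finite N; the bound is reported, not
  subtracted.
* The population-entropy state definition follows a documented convention;
  other conventions (word entropy, bias-corrected estimators) can give
  different absolute values.
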