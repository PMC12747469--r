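---
title: "Clusterless state-space decoding: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clusterless state-space decoding: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterless)
```

This vignette is the package's own account of the science it implements: the
decoding model and its assumptions, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the design was genuinely open.

## The decoding model

The package estimates an animal's linearized position from *unsorted*
threshold-crossing spikes. Instead of spike-sorted units, every spike carries a
*mark* $\vec m$ — a low-dimensional waveform feature vector, by default the
per-channel peak amplitudes of a tetrode ($D = 4$). Decoding is a recursive
Bayesian filter over a 1D grid of position bins $x$:

$$ p(x_k \mid \Delta N_k, \{\vec m_k\}) \propto p(x_k)\, p(\Delta N_k, \{\vec m_k\} \mid x_k), $$

where $\Delta N_k$ is the spike count in time bin $k$ and $p(x_k)$ is the
one-step prediction of the previous posterior through a movement model
$p(x_k \mid x_{k-1})$ (`transition_model()`; Markovian, and by default the
*uniform non-informative* transition, under which the posterior reduces to the
normalised likelihood at every step).

The clusterless likelihood factors over electrode groups $i = 1,\dots,E$ and
over the spikes $j$ each group contributed to the bin:

$$ p(\Delta N_k, \{\vec m_k\} \mid x_k) \propto \prod_{i=1}^{E}
   \prod_{j=1}^{\Delta N_k^i} \big[\lambda_i(\vec m_{k,j} \mid x_k)\,\Delta\big]
   \; e^{-\Lambda_i(x_k)\,\Delta}, $$

with $e^{-\Lambda_i(x_k)\Delta}$ alone when group $i$ was silent. Here
$\Delta$ is the bin size in seconds, so $\lambda\Delta$ is unitless. The two
intensity functions come from a kernel encoding model per group
(`encoding_model()`):

$$ \lambda_i(\vec m \mid x) = \mu_i\,\frac{p_i(x, \vec m)}{\pi(x)}, \qquad
   \Lambda_i(x) = \mu_i\,\frac{p_i(x)}{\pi(x)}, $$

where $\pi(x)$ is the occupancy (distribution of positions visited while
running during the learning phase), $p_i(x)$ the distribution of positions at
which group $i$'s stored spikes occurred, and $\mu_i$ the group's mean rate.
During learning *no computation happens*: each spike's $(\vec m_o, x_o)$ pair
is simply stored. At query time, $p_i(x, \vec m)$ is estimated on the fly as a
Gaussian-kernel weighted histogram of the stored positions:

$$ a_o^2 = \sum_{d=1}^{D} (m_{o,d} - m_d)^2, \qquad
   w_o = \frac{1}{\sigma\sqrt{2\pi}}\, e^{-a_o^2 / 2\sigma^2}, $$

with the weighted histogram divided by the number of stored spikes. The
normaliser is a design choice (the kernel estimate must carry *some*
convention); dividing by the stored count keeps $p_i(x,\vec m)$ a density-like
quantity so that $\mu_i$ alone carries the rate scale.

### Assumptions

* Spiking is conditionally Poisson given position; spikes contribute
  independently within and across groups.
* Marks are informative about identity: similar waveforms come from similar
  generators with similar spatial tuning. The kernel bandwidth $\sigma$
  expresses how similar is "similar" in amplitude units.
* Position is well represented by a 1D linearized coordinate; the movement
  model is Markovian.

## Parameters, units, defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| bin size | 5 | cm | one posterior bin = 5 cm of track; 205 cm track gives 41 bins |
| $\Delta t$ (`dt_ms`) | 6 | ms | posterior update interval; must exceed per-step compute time in a live deployment |
| $\Delta t_{\text{delay}}$ (`dt_delay_ms`) | 30 | ms | shifts the spike window behind current time so spikes can be turned into intensity estimates; spike incorporation latency is the sum, 36 ms |
| $\sigma$ (`sigma`) | 20 | mark (ADC amplitude) units | kernel bandwidth in amplitude space |
| `vel_thresh` | 4 | cm/s | movement filter: only running-period spikes and positions train the model (no value is standard; 4 cm/s is a common rodent-running cutoff) |
| occupancy smoothing | 1 | bins (Gaussian sd) | regularises the dwell-time histogram before it divides the intensities |
| occupancy floor | 1e-12 | — | additive, before division; keeps unvisited bins from producing infinities |
| $\Delta t_{\text{event}}$ (`dt_event_ms`) | 36 | ms | trailing window averaged for event detection (6 posteriors at 6 ms) |
| event thresholds | 0.40 / 0.20 | fraction | strict (`>`, `<`) target / off-target mass gates |
| spatial gate | 17 | cm | animal must be within this distance of the central box |
| `min_active_groups` | 2 | groups | population-level requirement |
| refractory | 3 | s | one trigger per reward-collection window |

The window for an update at $t_{\text{curr}}$ is the half-open interval
$(t_{\text{curr}} - \Delta t_{\text{delay}} - \Delta t,\;
t_{\text{curr}} - \Delta t_{\text{delay}}]$; consecutive updates tile time
with no gaps or double counting. The decoder clock is driven by LFP
timestamps: a step fires each time LFP time crosses the next $\Delta t$
boundary.

The spike-incorporation latency is deliberately *free* configuration: both the
delay and the bin size are experiment choices, and published deployments of
this architecture quote values from 12 to 36 ms depending on how much of the
pipeline the number includes. Nothing in the package depends on a particular
sum.

## Encoding-model conventions

* $\mu_i$ = stored spikes ÷ accumulated movement-period encoding time.
* "Spatially specific activity" of a group (the 2-group event gate) is
  operationalised as: the group emitted at least one spike in the event window
  whose joint-mark-intensity places more than 50% of its mass in the target
  plus off-target arms. The threshold is configuration
  (`specificity_frac`); the definition is ours, since the population-level
  requirement is stated in the field without a formal definition.
* Frozen models answer queries from the fixed stored set; queries before and
  after freezing agree on identical stored data (tested).

## Ripple detection

The LFP path band-passes to 150–250 Hz (Butterworth, order 2), squares,
low-passes (order 1 at 25 Hz) to form a power envelope, and z-scores the
envelope against a baseline mean/sd estimated over the first 10 s and then
frozen. An event opens at $z \ge$ `z_threshold` (default 3) and closes when
$z <$ `z_end_threshold` (default 0, return to baseline); it is emitted on
close. The z-scored quantity is the smoothed *square* (a power proxy), not its
square root.

Two facts from the design analysis worth recording:

1. **A mean+3sd threshold cannot give zero noise detections over minutes.**
   For any realistic envelope smoothing, the z-scored envelope of stationary
   1/f background crosses 3 several times per minute (the expected maximum of
   a few hundred effectively independent envelope samples sits near 3).
   Threshold 3 is an *onset sensitivity* setting, appropriate when marginal
   physiological events matter; it necessarily admits noise events. The
   detector therefore offers a sustain requirement (`min_duration_ms`,
   default 0 = off): an event is only emitted if z spent at least that long at
   or above the onset threshold. Real ripples last 50–100 ms or more, so a
   15–30 ms sustain discards single-sample excursions without touching
   physiological events. The default is off so the plain
   open-at-threshold/close-at-end contract holds exactly.
2. **Detection latency is bounded by filter physics.** A 100 Hz-wide band
   filter cannot respond faster than roughly 1/bandwidth (about 10 ms), plus
   envelope smoothing lag. For strong bursts the threshold crossing happens
   early on the rising envelope, giving 10–20 ms onset latency at this
   sampling rate; no causal detector at these bandwidths does much better.

For validation fixtures with *strong* injected bursts (peak amplitude 6 times
the background's ripple-band RMS, i.e. envelope z in the tens to hundreds),
the detector is operated at `z_threshold = 5`, `z_end_threshold = 1`,
`min_duration_ms = 30`: halfway (in order of magnitude) between the noise
envelope ceiling (max z about 4–6 over a minute) and the burst response, with
the sustain well below the 80 ms burst length. That operating point was fixed
from this analysis, before the validation suite was written, and gives full
recall with onsets within 20 ms and no detections on matched burst-free noise.

## The synthetic session generator

`sim_config()` / `simulate_session()` produce the study conditions the
validation suite runs under:

* **Track and behaviour.** A 205 cm two-arm track (two central-box segments,
  25 + 20 cm, and two 80 cm arms), traversed at 20 cm/s with 2 s central-box
  pauses, alternating arms; camera samples at 30 Hz; 10 min sessions split
  half encoding, half feedback.
* **Spiking.** Each electrode group carries 3 *multiunit amplitude clusters*
  — not isolated single units, because a clusterless decoder consumes every
  threshold crossing. Each cluster has Gaussian spatial tuning (peak 100 Hz,
  sd 10 cm, baseline 0.5 Hz), which works out to roughly 35–40 Hz mean
  multiunit rate per tetrode during behaviour, matching what CA1 tetrodes
  actually deliver. Spike times come from Lewis–Shedler thinning of the
  inhomogeneous rate; marks are the cluster center plus isotropic Gaussian
  noise (sd 20, matching $\sigma$), with in-group centers separated by
  $150\sqrt{2} \approx 212$ units, i.e. clearly separable clusters.
* **LFP.** 1/f-shaped Gaussian background at 1,500 Hz with 200 Hz bursts of
  80 ms under a fast-rise Tukey envelope (5 ms ramps). The fast rise is a
  deliberate generator choice: an onset time is only a meaningful ground
  truth if the burst actually carries energy near its nominal onset; a slow
  cosine ramp would make "onset error" unmeasurable for any causal detector.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: theta rhythmicity and phase precession, overlapping or
drifting mark clusters, non-Poisson spike-history effects (bursting,
refractoriness), behaviourally inhomogeneous occupancy, real LFP
non-stationarities and artifacts, and replay-like sequential structure inside
events. The suite demonstrates that the estimator is implemented correctly
and recovers the generative state under its own assumptions, not that those
assumptions hold in any particular recording.

## Numerical choices

* The likelihood is accumulated in log space and exponentiated after
  subtracting the per-bin maximum; raw products across many groups underflow.
  Posterior-forming operations are invariant to this rescaling (tested).
* All-zero posterior products (degenerate evidence) fall back to the prior
  with a warning rather than producing NaNs.
* Bins are 0-based half-open intervals; `norm_pos = 1` clamps to the
  segment's last bin; MAP ties break to the lowest bin index and are flagged.
* Ties in nearest-segment projection go to the lowest segment index.
* The replay runtime evaluates each stage vectorised (batched kernel queries
  via BLAS, per-bin aggregation by window index) with semantics identical to
  a sample-by-sample event loop: half-open windows assign each spike to
  exactly one bin, late spikes are counted as dropped, and record files are
  bit-reproducible for identical inputs and configuration. The streaming
  sample contract (`next_sample()`) and the stateful chunk-wise ripple path
  are sample-exact against whole-trace processing for any chunking (tested).
* 64-bit integer record fields are carried as R doubles, exact to $2^{53}$ —
  ample for acquisition-clock ticks (30 kHz for two millennia).

## Validation problem sizes

The shipped validation suite uses: a 10 min default session (8 groups × 3
clusters, about 10⁵ decoded 6 ms bins) for position recovery; 1,000 stored
marks × 100 queries for the kernel-density oracle; 50 bins × 50 steps for the
forward-filter oracle; 75 s LFP traces with 20 injected bursts for ripple
recall; and 60–90 s sessions for determinism and runtime invariants. These
sizes were chosen so the whole suite runs in a couple of minutes on one core
while keeping every estimate's Monte-Carlo error far from its acceptance
margin.

## Known limitations

* One decoder instance, one behavioural state: no multi-state state-space
  variants (e.g. movement-dynamics mixtures), and no dual-decoder reward
  logic.
* File replay only; no live acquisition transport. The `next_sample()`
  contract is the seam where one would attach a network source.
* The two-arm trajectory generator is specific to the 4-segment topology;
  geometry, rates and mark layout are configurable but the visit schedule is
  not general.
* HDF5 I/O is not provided; sources are CSV and model persistence is JSON.
* Kernel queries are exact (no tree or GPU approximations); cost grows with
  the stored-spike count, which is why the encoding model freezes.
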