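---
title: "Methods: burst detection, delayed-synchrony connectivity and calcium event analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst detection, delayed-synchrony connectivity and calcium event analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(culturenet)
```

This vignette documents the models behind `culturenet`, the parameters that
matter, the numerical conventions, and — because the package validates itself
against synthetic recordings — exactly what the generator emulates and what
it does not.

## Network-burst detection

The total spiking rate (TSR) is the spike count across all electrodes in
fixed, non-sliding 50-ms bins anchored at *t* = 0. A bin qualifies as burst
activity when it holds at least `min_spikes` (default 4) spikes from at
least `min_electrodes` (default 4) distinct electrodes — the classical
network-burst criterion for dissociated cultures. Maximal runs of contiguous
qualifying bins form one burst.

Two details deserve emphasis:

* **Class versus extent.** A burst is classed *small* (peak bin 4–100
  spikes) or *large* (peak bin ≥ 101) by its single strongest 50-ms bin,
  because the class definition is explicitly per-bin. The *spikes per burst*
  statistic, by contrast, counts the whole extent: population bursts
  routinely carry a few hundred spikes spread over several bins, which a
  single sub-100-spike bin could never hold. Whether that statistic should
  average over all bursts or small bursts only is genuinely ambiguous in the
  field's reporting; `summarize_bursts()` averages over all bursts by
  default and exposes `spikes_per_burst_scope = "small"`.
* **Gap tolerance.** By default a single sub-threshold bin splits a burst
  (`max_gap_bins = 0`) — the simplest rule consistent with a contiguity
  criterion. Recordings with ragged burst tails can set `max_gap_bins = 1`.

Numerical conventions: bins are half-open `[kw, (k+1)w)`; a spike exactly at
the recording end is placed in the last bin so `sum(tsr)` always equals the
raster's spike count; the number of bins is `ceiling(duration / width)`
(last partial bin included). Burst counts are normalised to the reporting
windows (small per 5 min, large per 10 min) by linear scaling of the
recording duration.

## Delayed-synchrony connectivity

For an ordered pair (i presynaptic, j postsynaptic) the connection
coefficient is the proportion of transmitted spikes,
`C_ij = n_synchr / n_j`: the fraction of j's spikes that follow a spike of i
at an axonal delay. "At an axonal delay" is operationalised as a scan: for
each candidate delay τ on a grid (default 1–20 ms, 1-ms steps, matching the
few-millisecond conduction delays expected at a 200-µm electrode pitch) the
coincidence window is `τ ± δ/2` with δ = 2 ms, and the maximum of C over
the grid is kept along with its maximising delay. Each postsynaptic spike is
matched at most once per delay, which is what guarantees `C_ij ≤ 1`: the
numerator is a count of *received-and-matched* spikes, never of pre/post
pairs.

Conventions and degenerate cases:

* The coincidence window is half-open, `[τ − δ/2, τ + δ/2)`, so that
  adjacent windows partition the lag axis and a lag exactly on a boundary
  belongs to one window only; with the closed convention a boundary lag
  would tie across three neighbouring delays and the reported best delay
  would be an artifact of the tie-break. Boundaries are evaluated with a
  1-ns tolerance so lags formed by float subtraction resolve as their
  real-number values; 1 ns is six orders of magnitude below the delay grid
  and far below any physiological time scale.
* Ties in the maximisation resolve to the smallest delay.
* A silent postsynaptic electrode has `n_j = 0`; `C_ij` is defined as 0
  there (flagged through the stored `n_post`) so silent electrodes cannot
  poison downstream matrix operations. They remain in every matrix, table
  and graph — they simply can never be hubs.
* `spike_scope = "burst"` optionally restricts both trains to detected
  burst extents; the default uses all spikes, the conservative reading when
  the restriction is not stated.
* No surrogate-based chance correction is applied by default; the edge
  selection rule is a fixed top fraction, not a significance test.

**Edge selection and hubs.** The strongest `fraction = 0.05` of the
`M = n(n−1)` ordered off-diagonal coefficients are kept,
`k = max(1, floor(0.05 M))` (for 59 electrodes, 171 of 3422). Ties at the
cutoff break deterministically by higher `n_synchr`, then lexicographic
pair label; zero coefficients are never selected even if that leaves fewer
than `k` edges. An electrode's connection count is its in-degree plus
out-degree over the selected set; electrodes with ≥ 10 connections are
hubs. The mean-connections-per-hub statistic averages over hubs when any
exist; when none do, it falls back to the five highest-degree connected
electrodes (and to 0 for an empty selection) — this keeps the statistic
defined for degraded networks, whose published values are far below the hub
threshold.

## Calcium transient detection

Raw fluorescence is converted to dF/F with a running-percentile baseline:
`F0(t)` is the 8th percentile of the trace in a centred 60-s window, long
relative to a transient (seconds) and short relative to drift (minutes), so
transients are excluded from their own baseline while drift is tracked. For
speed the percentile is evaluated every 5 frames and linearly interpolated —
the stride is 2.5 s at the 2-Hz imaging rate, far below the 60-s baseline
time scale. `F0` is floored at a small positive constant (10⁻⁶ of the trace
maximum) so near-zero baselines cannot blow up the ratio.

Events are maximal runs of frames above a threshold of
`threshold_sd = 2.5` noise SDs lasting at least `min_duration_s = 1` s
(2 frames at 2 Hz). Three detector details matter:

* **Noise estimation.** The per-cell noise SD is
  `1.4826 · mad(diff(x)) / sqrt(2)`. First-differencing removes the slow
  transients before the robust scale estimate; the plain MAD of the trace
  is badly inflated once a quarter of the frames sit inside events.
* **Threshold reference.** A *p*-th-percentile baseline sits `qnorm(p)`
  noise SDs below the noise centre, so the dF/F noise floor rests *above*
  zero by `−qnorm(p)·σ` (about 1.4σ for p = 8%). `detect_events()` reads
  the percentile from the attribute `compute_dff()` leaves on its result
  and raises the threshold by exactly that analytic offset. Estimating the
  centre empirically (e.g. the trace median) is biased upward on
  event-rich cells and was rejected for that reason.
* **Prefilter.** A 3-frame running median removes single-frame noise
  excursions, which otherwise split one transient into several events near
  threshold; events separated by at least one (filtered) sub-threshold
  frame remain distinct. `smooth_frames = 1` disables it.

The reported duration is the time above threshold. At 2 Hz this is
quantised to 0.5 s, which is why all duration tolerances in the tests are
stated as a relative band plus one frame. Whether the published "duration
of an oscillation" means width at threshold, at half maximum, or something
else is not stated anywhere we could find; width at threshold is the
default and the definition the generator is built around.

Summaries report the percentage of cells with at least one event, the event
rate averaged over *active* cells (the convention consistent with nonzero
published rates coexisting with large inactive fractions; `rate_scope =
"all"` switches to population averaging) and the mean event duration.

## What the synthetic generator emulates

`generate_mea_recording()` produces rasters from a planted hub network:
Poisson burst initiations at each hub (default 8.7 /min/hub for the sham
DIV21 preset) emit a regular packet (10 spikes, 5-ms spacing); each packet
spike propagates along planted edges with transmission probability `w`,
per-edge delay (uniform 2–10 ms) and 1-ms Gaussian jitter; every electrode
adds 0.2-Hz Poisson background. Design choices that shape what recovery
tests can show:

* **Single-hop propagation** by default: followers do not re-propagate, so
  the planted `C` structure stays interpretable; `multi_hop = TRUE` enables
  cascades.
* **Background does not recruit the network.** Only packet spikes (and,
  under `multi_hop`, their descendants) transmit. If isolated background
  spikes at a hub recruited its followers, every such spike would create a
  mini-burst — roughly one per hub per five seconds at the default rates —
  which would both double the burst count the presets are calibrated to and
  blur the distinction between burst-driven and background activity.
  `background_transmits = TRUE` restores the fully literal every-spike rule.
* **Disjoint follower sets.** Hubs are wired to disjoint followers. A
  follower listening to two hubs splits its received spikes between them,
  halving both planted `C_ij` values and pushing those edges into the range
  of sibling-correlation noise (followers of a common hub correlate with
  each other through the shared packet drive). Disjoint wiring keeps
  "planted edge" a meaningful recovery target.
* **Determinism.** All randomness derives from one integer seed through
  fixed per-component sub-streams (wiring, per-hub initiations, per-edge
  transmission, per-electrode background), so outputs are reproducible and
  independent of iteration order.

`generate_calcium_traces()` plants transients with an instant rise and
exponential decay. The decay constant is solved from the planted duration
*at the detector's threshold level* (`duration = τ_decay · ln(amplitude/θ)`
with `θ = 2.5 · noise_sd`), because time-above-threshold is the only
duration a threshold detector can observe; with zero noise the threshold
level is taken at 1% of the amplitude. Event times form a
Poisson-with-dead-time renewal process — consecutive events are separated by
at least the event duration plus one frame, with exponential gaps rescaled
so the mean rate equals the preset exactly. A pure Poisson stream would
overlap a substantial fraction of consecutive transients at sham-like rates
(the next event arriving before the previous decays), making the planted
rate unrecoverable by any threshold detector; the dead time is also the
biophysically sensible refractory reading. Amplitude defaults to 1.0 dF/F
with 0.05 additive noise (a 20:1 ratio typical of healthy somatic OGB-1
signals) and 1%/min linear drift.

What the generator does **not** emulate: biophysical membrane or indicator
dynamics, multi-compartment waveforms, correlated network-wide calcium
events, photobleaching beyond linear drift, electrode noise or spike-sorting
errors, and any pharmacology — experimental conditions differ *only* through
planted statistics. Passing recovery tests therefore shows the analysis
correctly inverts this generative family at realistic signal-to-noise, not
that it is robust to every artefact of real recordings.

## Condition presets

`condition_preset()` plants published group statistics: e.g. sham DIV28
calcium (68.7% active, 2.49 events/min, 6.2 s), chronic amyloid DIV28
(17.18%, 0.35/min, 13.24 s), 5xFAD DIV21 (44.3%, 1.16/min). Where a group's
duration is published only as a fold change (5xFAD at 1.55× / 1.75× control)
it is applied to the control value; where a value is not published at all
(sham DIV21 rate; control durations) a single value was fixed from the
neighbouring published values (2.3 events/min; 8.0 s and 7.0 s) and is not
revisited. MEA presets are calibrated so `n_hubs × burst_rate × 5 min`
equals the group's small-burst count (sham DIV21: 5 × 8.7 × 5 = 217.5) and
hub out-degrees echo the published hub connection counts. Presets plant
group *means*; dispersion across replicate recordings comes only from
sampling noise, with no claim of matching published between-culture
variance.

## Problem sizes and limitations

The test suite validates burst detection against brute-force enumeration on
200 random rasters (≤ 10 electrodes, ≤ 60 s), the connectivity matrix
against a triple-loop oracle on 100 small rasters (≤ 5 electrodes), planted
network recovery on 20 full-size recordings (59 electrodes, 300 s, 5 hubs,
w = 0.8) against 20 independent-Poisson nulls, and calcium parameter
recovery on 10 seeds × 100 cells × 300 s per condition. These sizes were
chosen as the smallest at which the Monte-Carlo properties are stable.

Known limitations: recovered event durations run ~15% short of the planted
value at high duty cycles (the noise estimate inflates slightly with event
density, and transients that re-fire mid-decay merge); single isolated
transients near the detection threshold fragment — an intrinsic property of
threshold crossing at 2 Hz, since crossing-time jitter is noise SD divided
by signal slope; and the connectivity statistic is correlational — followers
of a common hub show elevated `C` between each other, which is why hub
identification uses degree rather than individual edge identity.
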