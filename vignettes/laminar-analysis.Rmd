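---
title: "Analyzing laminar sensory-evoked responses with lamep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing laminar sensory-evoked responses with lamep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(lamep)
```

## The analysis problem

A linear ("laminar") silicon probe inserted perpendicular to the cortical
surface records extracellular voltage simultaneously at 16 sites spaced
100 µm apart. Around a brief sensory stimulus (here: a whisker deflection
in rodent barrel cortex), those recordings contain two signals with very
different analyses:

* the **local field potential (LFP)**, a slow voltage reflecting summed
  synaptic currents, whose stimulus-locked trial average is the
  **sensory-evoked potential (SEP)** — a negative deflection whose onset
  latency, peak latency, peak amplitude and maximal slope characterize the
  response;
* **multi-unit activity (MUA)**, the unsorted spikes of nearby neurons,
  detected as negative threshold crossings of the 300–5000 Hz band and
  summarized as a peristimulus spike-density function.

Because the probe samples a line through the cortical depth, the second
spatial derivative of the averaged LFP — the **current-source density
(CSD)** — localizes the transmembrane current sinks that generate the
response, and the earliest deep sink near ~600 µm identifies the granular
layer (L4), with the supragranular layers (L2/3) above it.

When an NMDA-receptor antagonist is applied to the cortical surface, the
evoked response splits into a fast drug-resistant component and a slower
drug-sensitive component. Subtracting the drug-condition average from the
control average isolates the sensitive component; its 20–80% rise time,
time to peak, second (polysynaptic) peak, and exponential decay constant
are the quantities of pharmacological interest. Drug effects on firing are
staged in the classic post-stimulus epochs 5–8, 8–10, 10–20, 20–50 and
50–100 ms, with the normalized decrement (control − drug)/control and a
two-sided Wilcoxon signed-rank test across animals.

`lamep` implements this pipeline end to end, together with a synthetic
laminar-recording generator whose ground truth makes every stage testable
by parameter recovery.

## The synthetic generator

`simulate_pair()` produces a matched control/drug pair of wideband
recordings. Its design:

* **Evoked components.** Each LFP component is a difference of two
  exponentials, re-parameterized by root finding so that the requested
  20–80% rise time and decay constant hold exactly on the returned trace.
  The defaults are calibrated to the field-typical values the analysis
  should recover: a fast component (onset 7.5 ms, rise 2.0 ms, decay
  τ = 11.1 ms, 469 µV at the L2/3 reference site) and a slow component
  (onset 8.0 ms, rise 3.9 ms, τ = 88.3 ms, 183 µV) with a second lobe
  placed — again by root finding on the composite derivative — so the
  realized second peak falls at 46 ms. Together they give a control SEP of
  ≈621 µV peaking near 14 ms.
* **Spatial structure.** The true CSD of each component is a Gaussian
  depth profile (fast sink centered at 620 µm, i.e. the granular sink
  sits between the 600 and 700 µm sites; slow sink at 360 µm). The
  noiseless LFP is obtained by solving the tridiagonal second-difference
  system with zero boundary potentials, so applying `compute_csd()` to the
  generated LFP reproduces the planted CSD exactly — an operator-inversion
  identity the tests exploit. The fast sink is deliberately not centered
  exactly on a recording site: a site-centered sink would make the two
  bracketing channel pairs exactly equidistant and the ground-truth layer
  assignment ambiguous by construction.
* **Spikes.** The L2/3 burst is a sum of Gaussian bumps (σ = 0.5 ms)
  spaced at 1/398 Hz starting at 9.3 ms with densities 0.32, 0.56, 0.28
  and 0.14 spikes/ms (summed over the L2/3 sites); L4 gets an earlier
  burst. The late, drug-sensitive tail follows the slow component's
  magnitude, gated on after 11 ms so the early epochs are drug-free by
  construction — this emulates the observed dissociation in which the
  early burst is NMDA-independent. Spike times are drawn from
  inhomogeneous Poisson processes; each spike injects a biphasic 1 ms
  waveform whose amplitude is `spike_snr` (default 8) times the
  300–5000 Hz noise SD.
* **Noise.** Wideband Gaussian white noise (30 µV SD) sets the detection
  floor. The LFP-band noise (20 µV SD, AR(1) at 1 kHz) is mostly spatially
  smooth — a common mode plus a linear-in-depth mode, both annihilated by
  the CSD operator — plus a smaller independent per-channel part, which is
  what real volume conduction looks like from a laminar probe.
* **Shared randomness.** All noise and all early-burst/spontaneous spike
  draws are shared between the two conditions; the drug condition differs
  only by scaling the slow LFP component by `1 - drug_suppression` and
  thinning the late spike tail by the same factor. `drug_suppression = 0`
  therefore yields bit-identical recordings — the exact null the
  statistical tests are validated against.
* **Protocol scale.** Stimulus triggers are quantized to a 1 ms clock (as
  acquisition systems do) and the default inter-stimulus interval is
  0.9–1.1 s. The simulated response returns to baseline well inside
  600 ms, so the ISI does not affect any measured quantity; experimental
  protocols use much longer intervals for drug-application stability, not
  for response independence.

What the generator does **not** emulate: trial-to-trial amplitude
variability of the evoked response, electrode drift, movement artifacts,
single-unit waveform diversity, or multi-whisker receptive-field
structure. Passing recovery tests therefore demonstrate the correctness of
the analysis chain under controlled conditions, not robustness to every
pathology of real recordings.

## Numerical and algorithmic choices

* **Downsampling** (32 kHz → 1 kHz) uses an exact boxcar pre-decimation
  (whose spectral nulls sit on every frequency that would fold into the
  band) followed by a zero-phase 4th-order Butterworth low-pass at 80% of
  the output Nyquist. The boxcar's half-sample group delay is folded into
  the recording's time base, so latencies are unaffected.
* **Zero-phase filtering** pads by odd reflection about the trace
  endpoints before forward–backward filtering; without this, edge
  transients of the size of the signal's DC level leak into the first and
  last few hundred samples.
* **SEP onset** is the intersection of the front with the baseline level,
  computed by extrapolating the tangent at the front's steepest point. A
  naive "last sample at/above baseline walking back from the trough" rule
  is unusable under temporally correlated baseline noise: before the true
  onset the trace is pure noise around the baseline level, so the last
  crossing tracks the last noise excursion (measured mean error 4–10 ms,
  independent of the noise amplitude). The tangent rule is exact on
  piecewise-linear fronts and recovers simulated onsets to ~0.3 ms.
* **Trough qualification** requires both a depth of 4 baseline SDs and at
  least 25% of the window's deepest excursion; the second clause guards
  near-noiseless traces (e.g. a decomposed component), where 4 SDs of an
  almost-silent baseline would qualify meaningless micro-troughs.
* **MUA onset** keeps the back-tracked baseline-crossing rule (the
  density has a zero floor, which makes the rule stable), debounced so an
  isolated single-spike bin does not stop the backward walk.
* **MUA peaks**: local maxima above baseline mean + 3 SD; tops closer
  than one bin width are merged (count noise splits one burst peak into
  twins whose mutual topographic prominence is ~0); the surviving peaks
  must have prominence ≥ 0.15 of the tallest. Prominence is computed
  against strictly higher peaks so equal-height twins cannot mask each
  other.
* **Oscillation frequency** is 1000 / mean inter-peak interval of density
  peaks inside [onset, onset + 8 ms], with parabolic sub-bin refinement of
  each peak time, a 1.8 ms minimum peak separation (the ~600 Hz
  physiological ceiling of cortical high-frequency oscillations), and a
  prominence criterion of 0.20. The 8 ms window stops before the
  drug-sensitive tail grows large enough for its count noise to inject
  spurious peaks; with a 15 ms window the estimator's SD across simulated
  animals quadruples.
* **Layer assignment** ranks only channels whose sink amplitude reaches
  25% of the map maximum (noise-only channels cannot contaminate the
  choice), scores adjacent pairs by mean sink onset (optionally averaged
  with per-channel MUA onsets), and breaks ties — earliest within
  0.5 ms — toward the expected 600 µm depth and then toward the strongest
  sink.
* **Exponential decay fits** use a log-linear initialization refined by
  Levenberg–Marquardt least squares on the magnitude trace, with the fit
  window running from the last detected peak to the point where the
  magnitude first falls below 5% of that peak.
* **The signed-rank test** drops zero differences, assigns average ranks
  to ties, and computes the exact two-sided p-value for n ≤ 25 by
  convolution over doubled ranks (average ranks are multiples of ½, so
  doubling makes them integers); above that it uses the normal
  approximation with tie and continuity corrections. The exact path is
  validated against exhaustive enumeration of all 2^n sign assignments.

## Problem sizes used by the test-suite studies

Parameter-recovery studies run 10 simulated animals at 100 trials each;
the drug-dissociation study runs 10 animals at 30 trials; the null
calibration of the paired test runs 40 replicate groups at the
spike-train level. These sizes give recovery noise comfortably inside the
assertion bands while keeping a full check of the package quick enough to
run routinely.

## A worked run

```{r, eval = FALSE}
sim <- simulate_pair(simulation_config(n_trials = 100, seed = 1))
man <- run_pipeline(analysis_config(), sim$control, sim$stim, sim$drug,
                    out_dir = "run1")
cat(make_report(man), sep = "\n")
```

The seven result tables (`sep.tsv`, `csd.tsv`, `layers.tsv`, `mua.tsv`,
`epochs.tsv`, `stats.tsv`, `decomp.tsv`) and `manifest.json` land in
`run1/`. With the defaults above, the control SEP onset comes out near
7.4 ms with a peak of ~620 µV at 14 ms, the drug-condition peak near
470 µV, the L2/3 MUA first peak ~0.3 spikes/ms at 9.4 ms oscillating near
400 Hz, and the decomposed sensitive component rises in ~3.9 ms, peaks
twice (the second time near 46 ms) and decays with τ ≈ 89 ms — the same
numbers the acceptance script reports.

## Known limitations

* The CSD is the plain second spatial difference in units of µV/mm²
  (no conductivity scaling, no Vaknin padding of the edge sites, no
  spline/inverse methods); maps are relative, which suffices for sink
  localization and component comparison.
* MUA density undercounts during the burst peak: two spikes within the
  1 ms dead time on one site are genuinely indistinguishable by threshold
  detection. At the default burst rates this costs ~10% of the first-peak
  density, a ceiling shared with any real MUA recording at these rates.
* Decomposition operates on averaged traces only; subtracting noisy
  single trials would be meaningless without trial pairing.
* The epoch decrement is undefined when the baseline-corrected control
  rate is ~0 (early epochs); group inference there rests on the paired
  test, not on the decrement's mean.
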