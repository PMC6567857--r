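# lamep — laminar evoked-response analysis

`lamep` analyzes sensory-evoked responses recorded with linear multi-site
("laminar") probes in cortex, the standard preparation for studying how a
brief stimulus — e.g. a whisker deflection over rodent barrel cortex —
propagates through the cortical layers, and how a pharmacological agent
applied to the cortical surface reshapes that response. It is written for
electrophysiologists who have a wideband multichannel recording, a list of
stimulus times, and a control/drug condition pair, and who want the
field's standard quantities computed reproducibly:

* **SEP parameterization** — the trial-averaged LFP's first trough:
  onset latency (intersection of the front's steepest tangent with the
  baseline), peak latency, peak amplitude, maximal slope, and
  fixed-latency readouts;
* **CSD mapping** — the negated second spatial difference
  `-(V[i-1] - 2V[i] + V[i+1]) / h²` of the averaged laminar LFP after
  1 s-baseline subtraction, with automatic layer assignment from the
  earliest deep sink (expected granular depth ~600 µm) and short-latency
  spiking;
* **MUA analysis** — spike detection at −5 SD of the quietest-second
  noise floor of the 300–5000 Hz band, sliding-window spike density
  (1 ms window, 0.2 ms steps), onset/first-peak/slope/maximal-peak
  metrics and the high-frequency oscillation rate of the early burst;
* **epoch statistics** — baseline-corrected firing rates in the classic
  5–8, 8–10, 10–20, 20–50, 50–100 ms post-stimulus epochs, the
  normalized drug decrement `(control − drug)/control`, and an exact
  two-sided Wilcoxon signed-rank test for matched samples;
* **component decomposition** — drug-resistant (drug-condition average)
  and drug-sensitive (control − drug) components with 20–80% rise times,
  second-peak latency and exponential decay constants.

A synthetic laminar-recording generator (`simulate_pair()`) with complete
ground truth — spike times, noiseless component traces, true CSD maps —
backs the test suite: every stage is validated by closed-form identities
and parameter recovery. See `vignettes/laminar-analysis.Rmd` for the
model, the estimator choices and their rationale.

## Worked example

```r
library(lamep)

sim <- simulate_pair(simulation_config(n_trials = 100, seed = 1))
man <- run_pipeline(analysis_config(), sim$control, sim$stim, sim$drug,
                    out_dir = "run1")
read_table_tsv("run1/sep.tsv")
#>   condition onset_ms peak_latency_ms peak_amplitude_uV max_slope_uV_per_ms amplitude_at_50ms_uV
#> 1   control 7.222654              14          618.3882            213.3807           -200.18400
#> 2      drug 7.150810              13          462.0273            171.0622            -20.73088
```

The control SEP starts ~7.2 ms after the whisker deflection and reaches
−618 µV at 14 ms; under the NMDA-receptor antagonist the peak shrinks to
−462 µV and arrives earlier because the slow component is gone, while the
late response (−200 µV at 50 ms in control) collapses to baseline. The
manifest carries the decomposed component kinetics:

```r
str(man$kinetics$sensitive)
#> List of 5
#>  $ onset_ms       : num 7.75
#>  $ time_to_peak_ms: num 19
#>  $ rise_2080_ms   : num 3.88
#>  $ second_peak_ms : num 45
#>  $ decay_tau_ms   : num 89.1
```

— the drug-sensitive component rises in ~3.9 ms, peaks twice (the second
time near 46 ms, the polysynaptic lobe) and decays with τ ≈ 89 ms, the
slow-receptor time course the decomposition is designed to isolate.
`run1/` also holds `mua.tsv` (L2/3 burst 0.25 spikes/ms at 9.6 ms,
oscillating near 400 Hz), the epoch decrement table (`stats.tsv`: early
epochs unchanged, late epochs suppressed by >95%), the CSD map, the layer
table and a human-readable `report.md` via `make_report(man)`.

A thin command-line wrapper is installed as `exec/lamep`
(`lamep simulate|run|report`).

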