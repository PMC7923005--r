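# evgate

Fluorescently conjugated antibodies and protein labels self-associate into
aggregates that scatter light and fluoresce in the same window as
extracellular vesicles (EVs, 50–1000 nm). On a high-resolution flow
cytometer (hFCM) these aggregates trigger as events and masquerade as rare
EV populations. `evgate` is an R implementation of the analysis used to
quantify such aggregates in labelled buffer and to compare label
pre-treatments (centrifugation at 17,000 g for 5/10/30 min — `C5`, `C10`,
`C30`; 0.45 µm filtration — `F`; washed-filter filtration — `WF`) against
untreated labels (`U`), together with a synthetic acquisition generator
that stands in for the instrument and wet lab so the whole pipeline can be
exercised and validated at desk scale.

## What the package computes

For each sample the pipeline applies three gates in fixed order and turns
the surviving event count into a volumetric concentration:

1. **Time-stability QC.** Events are binned into 1 s bins; bins whose count
   deviates from the median by more than *k*·MAD (σ-scaled, floored at one
   count; *k* = 5) are excluded as erratic-rate episodes. The retained time
   enters the analyzed volume.
2. **Bead-calibrated EV-size gate.** Thresholds sit at the 1st percentile
   of the 1300 nm silica-bead reference population in SALS and LALS
   (small/large-angle light scatter); an event is inside the gate when
   SALS < sals_max **and** LALS < lals_max (strict).
3. **Fluorescence positivity.** Per channel, the threshold is the 99th
   percentile (linear interpolation) of a compensated control inside the
   size gate — a triton lysis control for the lactadherin-FITC channel,
   isotype-stained controls for PE/APC/AF700/BV510. Positivity is strict
   `value > threshold`.

Concentration is `count / (flow_rate × retained_time / 60)` in events/µL at
0.75 µL/min over 120 s. The statistical layer normalizes concentrations to
the untreated group mean per panel × arm × label, computes fold changes
against unlabelled buffer (`FC = mean labelled / mean buffer`), percent
reductions `(1 − c/mean U) × 100` with their CV%, and compares treatments
with unadjusted two-sided pairwise Wilcoxon rank-sum tests at three
aggregation levels (pooled n = 70 per treatment; per panel × arm n = 15/20;
per label n = 5).

Spillover compensation is `observed %*% solve(S)` with S[i, j] the fraction
of fluorophore i detected in channel j; negative compensated values are
kept so the percentile gates see the full distribution.

The generator draws, per population, Poisson(concentration × acquired
volume) events with log-normal scatter/fluorescence coupled by a latent
size factor, applies spillover and a trigger threshold, and models
pre-treatment as removal of a replicate-specific fraction of aggregate
particles, preferentially the highest-scatter ones for filtration.

## Worked example

```r
library(evgate)
ex  <- simulate_experiment(
  config = acquisition_config(spillover = default_spillover(), seed = 1))
res <- analyze_experiment(ex)
res$gates$P2
#> <gate_set>
#> <time_gate> 0/120 bins excluded, retained 120 s
#> <size_gate> SALS < 2.499e+04, LALS < 6686 (from 1524 bead events)
#> <fluor_gate> FITC > 201.7 (99th pct of triton control, n=5878)
#> <fluor_gate> PE > 66.11 (99th pct of isotype control, n=5996)
#> <fluor_gate> APC > 66.59 (99th pct of isotype control, n=5996)
#> <fluor_gate> AF700 > 68.1 (99th pct of isotype control, n=5996)

subset(res$reductions, group == "total",
       c(treatment, n, reduction_mean, reduction_sd, reduction_cv))
#>  treatment  n reduction_mean reduction_sd reduction_cv
#>        C10 70          20.94         30.9        147.5
#>        C30 70          20.54         37.9        184.5
#>         C5 70           6.48         31.2        482.1
#>          F 70          48.79         31.5         64.6
#>         WF 70          61.14         21.9         35.9

subset(res$comparisons$all, group_a == "F" | group_b == "F")
#>  stratum group_a group_b    W        p n_a n_b
#>      all     C10       F 3681 2.93e-07  70  70
#>      all     C30       F 3556 4.12e-06  70  70
#>      all      C5       F 4158 1.11e-12  70  70
#>      all       F       U  520 8.89e-16  70  70
#>      all       F      WF 3046 1.30e-02  70  70
```

Read: the size gate retains everything below the bead reference; filtration
removes about half the aggregate signal (48.8% ± 31.5 here, against a
simulated truth near 47%), the washed filter slightly more, centrifugation
little and with huge spread — and filtration beats untreated and every
centrifugation arm at p < 0.001 on the pooled stratum.

A full run with provenance, gate JSON, manifest and tidy CSV outputs:

```r
run_pipeline(default_run_config(seed = 1, out_dir = "out"))
```

or from a shell via the thin wrapper
`Rscript inst/cli/evgate.R run --seed 1 --out out`.

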