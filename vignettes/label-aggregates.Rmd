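---
title: "Quantifying label aggregates in the EV window: models, gates and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying label aggregates in the EV window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evgate)
```

## The problem

High-resolution flow cytometers trigger on particles far below the reach of
conventional instruments, which makes them attractive for extracellular
vesicle (EV) phenotyping — and simultaneously exposes a confounder:
fluorescent antibody and protein labels aggregate, and the aggregates
scatter and fluoresce in the same window as EVs. Quantifying aggregates in
labelled buffer, and measuring how much of them centrifugation or
filtration of the label removes, requires a reproducible chain of gating,
volumetric quantification and non-parametric comparison. `evgate`
implements that chain, plus a synthetic acquisition generator: no raw event
data accompanies the study this analysis re-implements, so validation rests
on simulated acquisitions with known ground truth.

## The synthetic acquisition model

Each sample is a mixture of particle populations. For population $p$ with
concentration $c_p$ (particles/µL of measured sample), the number of
candidate events in an acquisition at flow rate $\phi$ µL/min over $T$
seconds is

$$N_p \sim \mathrm{Poisson}(c_p \,\phi\, T / 60).$$

Channel intensities are log-normal. Within an event, all channels share a
latent standard-normal size factor $Z$:

$$\log X_{c} = \mu_c + \sigma_c\left(\ell_c Z +
\sqrt{1 - |\rho|}\,\varepsilon_c\right),
\qquad \ell_c = \mathrm{sign}_c \sqrt{|\rho|},$$

with $\mathrm{sign}_c$ positive for scatter channels and carrying the sign
of $\rho$ for fluorescence channels. Every marginal stays exactly
log-normal (the Kolmogorov–Smirnov property test relies on this), the
implied correlation matrix is positive semi-definite by construction, and
the scatter–fluorescence correlation equals $\rho$. Aggregate populations
use $\rho = 0.6$: larger aggregates both scatter and fluoresce more, the
structure that makes size-selective filtration visible downstream.

Fluorescence channels are then mixed through the spillover matrix $S$
(row convention, $\text{observed} = \text{true}\,S$), an event is recorded
only if its trigger-channel (MALS) intensity exceeds the trigger threshold,
and timestamps are uniform on $[0, T]$ — a homogeneous Poisson process,
except inside injected erratic-rate segments, which add events from a broad
nuisance population at a specified rate multiplier.

### Acquisition defaults

The acquisition settings are the study conditions: 120 s at 0.75 µL/min
(1.5 µL analyzed), MALS trigger. The trigger threshold (80 intensity
units) and the unstained-buffer noise population (40,000 particles/µL,
MALS meanlog $\log 20$, sdlog 0.9) are calibrated jointly so that an
unstained-buffer acquisition triggers at roughly 30 events/s — comfortably
inside the instrument contract of fewer than 100 events/s used to set the
trigger "above background". The buffer's fluorescence channels are dim
with a heavy tail (meanlog $\log 5$, sdlog 1.6): real unstained buffer
yields a small but non-zero positive-event concentration above the
control-derived gates, and that concentration is the denominator of every
fold change, so it must not degenerate to zero.

### Populations and concentrations

Default untreated aggregate concentrations per panel, arm and fluorophore
are the published untreated means scaled down 20-fold (e.g. FITC in the
P1-specific panel: 66,234 events/µL becomes ~3,300/µL). The scaling is a
deliberate desk-scale choice — a full 120-sample experiment simulates in a
few seconds — and preserves the relative structure between labels, which is
what the normalization-based statistics consume. These values are
calibration, not data: the source study deposits no event distributions, no
bead coordinates and no spillover matrix, so every simulator default is the
package's own choice of a realistic magnitude.

The bead reference mimics a 1300 nm silica-bead calibrant: a tight
(sdlog 0.08) population two orders of magnitude above the EV-scale noise
floor in SALS and LALS. Plasma gating controls are emulated as EV/debris
populations with dim fluorescence (triton control: moderately elevated
FITC from lysis debris); they emulate the fluorescence background that
defines the positivity thresholds, not the full aggregate content real
stained controls would carry.

### Treatment models

A pre-treatment removes a replicate-specific fraction of each aggregate
population, drawn as $\mathrm{clip}(\mathcal{N}(\mu, s), 0, 1)$
independently per sample × label (each label vial is treated separately in
each replicate). Clipping a wide Normal shifts its mean — a Normal centred
at 0.02 with SD 0.45 clips to a mean near 0.19 — so $\mu$ is solved
numerically (`clipped_normal_location()`) such that the **realized** mean
removal equals the published per-treatment mean: F 47%, WF 57%, C5 2%,
C10 13%, C30 19%, with the published between-replicate SDs (24, 18, 45,
37, 42 percentage points). Size selectivity is 0.9 for the filtration arms
(removal taken from the top of the SALS ranking first) and 0.3 for
centrifugation, reflecting the observation that filtration removes the
large, bright aggregates while small dim ones pass through.

Between-replicate label-preparation variability is a mean-preserving
log-normal jitter on each aggregate concentration (CV 0.3 by default) —
day-to-day panel preparation was the dominant variance source in the
original design, and without it the untreated CV would be implausibly
small.

## Gating

**Time QC.** The published analysis removed erratic-rate time windows by
hand in FlowJo; a manual gate is not reproducible, so the package uses a
robust rule: 1 s bins, exclude bins deviating from the median count by more
than $k \cdot \mathrm{MAD}$ ($k = 5$; MAD scaled by 1.4826 to a σ
equivalent and floored at one count so a quiet acquisition cannot divide by
zero). Under a homogeneous Poisson null the false-exclusion rate is well
below 5% (a 5σ-equivalent cut), and a 10× burst is excluded bin-exactly.
Both are asserted in the tests. The gate is refit per acquisition — time
stability is a property of each run, unlike the transferred size and
fluorescence gates.

**Size gate.** Thresholds at the 1st percentile of the bead population's
SALS and LALS; an event is inside when strictly below both. The published
description ("below the first percentile … in a scatterplot") is ambiguous
between a rectangle and a freehand region; the axis-aligned rectangle with
strict inequalities is chosen for determinism and testability. Bead
selection is likewise deterministic: events above a scatter floor (the
99.5th percentile of the unstained background's SALS), trimmed to within a
factor 5 of the selection's median SALS to shed stray noise events; if the
trim leaves fewer than 100 events the untrimmed selection is used, and
fewer than 100 events above the floor is an error rather than an unstable
percentile.

**Fluorescence gates.** 99th percentile of the compensated control inside
the size gate, one control mapping hard-wired per channel (triton lysis
control for lactadherin-FITC, isotype controls elsewhere) and overridable.
Whether the original percentiles were computed inside or outside the size
gate is not stated; inside is chosen, since the gate is applied to
size-gated data and a threshold should be calibrated on the population it
will cut. All percentiles use linear interpolation between order statistics
(R type 7), pinned against a brute-force oracle in the tests; with $n =
10^4$ control events the gate marks 0.9–1.1% of the control's own events
positive.

Gates are fitted once per analysis session and transferred to every sample
of that session. `apply_gates()` enforces the fixed order time → size →
fluorescence, so per-channel counts are non-increasing along the pipeline.

## Quantification and statistics

Concentration is count over analyzed volume, $\phi \cdot
t_\mathrm{retained} / 60$ µL. Concentrations are reported as-measured
(events/µL of the diluted sample); whether the published tables corrected
for the 17-fold staining dilution is not stated, and the printed magnitudes
are consistent with as-measured counts, so dilution correction is opt-in
and logged.

Normalization divides by the mean untreated concentration of the same
panel × arm × label group, making the untreated group mean exactly 1.
Fold change is the ratio of the labelled group mean to the unlabelled
buffer mean; its SD is computed on per-replicate ratios against the overall
buffer mean (the only way a ± SD on a ratio of means is definable), which
makes the per-replicate mean coincide with the ratio of means. Percent
reduction is $(1 - c/\bar c_U) \times 100$, negative values (increases)
retained, summarized as mean ± SD and CV%.

Treatments are compared with unadjusted two-sided Wilcoxon rank-sum tests
— exact when both groups are tie-free with fewer than 50 values, otherwise
the normal approximation with tie and continuity correction (the default
of the R environment the original analysis used) — at three aggregation
levels: all labels pooled (n = 70 per treatment on the default grid),
per panel × arm (n = 15 for the 3-label panel, 20 for the 4-label panel),
and per label (n = 5). The absence of multiplicity adjustment is
deliberate and inherited from the analysis being re-implemented.

## Numerical choices and degenerate inputs

* Percentiles: type-7 linear interpolation throughout; a flat 1…100 bead
  sample yields a 1st-percentile threshold of 1.99.
* Compensation: negative compensated values are retained; clipping would
  bias every 99th-percentile threshold upward.
* Spillover matrices must have unit diagonal, off-diagonals in $[0, 1)$
  and be invertible; compensation refuses singular matrices.
* Zero-concentration populations, empty acquisitions and zero-event
  samples propagate as zeros, not errors; a zero untreated or buffer mean
  is an error naming the group, since the normalization and fold change
  are undefined there.
* Reproducibility: one global seed; each sample of an experiment draws
  from a deterministic substream derived from (seed, sample index), so any
  subset can be regenerated in isolation. Identical seeds give
  byte-identical event tables and pipeline CSVs.

## Problem sizes

The shipped defaults simulate the full 2-panel × 2-arm × 6-treatment ×
5-replicate grid (120 samples plus controls, ~1.3 million events) in a few
seconds; the end-to-end recovery test repeats this over 50 seeds. The
validation suite uses 200 seeds for the Poisson count law, $10^4$ events
for distributional (KS) and gate-calibration checks, and 2000 null
replicates for the type-I-error check of the rank-sum comparison. These
sizes were chosen so the full suite runs on a laptop in a few minutes while
keeping Monte-Carlo error well inside the asserted tolerances.

## What passing tests do and do not show

The generator reproduces the statistical structure the analysis assumes:
Poisson event counts, log-normal intensities with positive
scatter–fluorescence coupling in aggregates, spillover, trigger
thinning, erratic-rate bursts, and treatment effects of the published
magnitudes. It does not model optics (no Mie scattering), fluorophore
photophysics, swarm/coincidence detection of multiple particles in the
laser spot, or matrix effects of plasma versus buffer. Passing the
end-to-end tests therefore shows that the pipeline recovers known effects
from data with this structure — it does not certify instrument-specific
behaviour on real acquisitions, where coincidence and background drift can
violate the generator's assumptions.

## Limitations

* The fluorescence thresholds inherit the synthetic controls' composition;
  real triton controls contain surviving aggregates, which would raise the
  FITC threshold and lower measured positive concentrations.
* The per-label independence of treatment draws is an assumption; if a
  whole master mix fails at once, effective sample sizes on the pooled
  stratum shrink.
* Reduction summaries divide by a noisy untreated mean (n = 5), which
  biases normalized values upward by roughly $\mathrm{CV}^2/5$ — about 2
  percentage points at the default jitter; visible as a small systematic
  underestimate of reductions.
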