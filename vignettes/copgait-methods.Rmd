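---
title: "Methods: COP cyclogram gait analysis for perturbation-based balance training trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COP cyclogram gait analysis for PBT trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copgait)
```

## Scope and model

`copgait` analyses instrumented-walkway gait recordings from
perturbation-based balance training (PBT) studies in which older adults walk
overground while a walker-mounted pelvic cable robot delivers brief,
unpredictable force pulses. The canonical protocol the package encodes has
five trials — Gait Baseline, Test Pre, Training, Test Post, Gait Post — with
5 minutes of walking per trial except Training (10 minutes). Pulses are
square waves: 0 N between pulses, a high value of roughly 10% of the
subject's body weight during the pulse, 100 ms wide, with lateral
(left/right) directions in the Test trials and diagonal (lateral + vertical)
directions during Training for the experimental group (EG) only; the control
group (CG) trains with cables attached but no pulses. Inter-pulse timing is
random so subjects cannot anticipate.

From footfall-segmented center-of-pressure (COP) recordings the package
computes, per gait cycle or stride:

* **stride length** — Euclidean distance between two successive ipsilateral
  heel strikes (cm);
* **stride velocity** — stride length over stride duration (cm/s);
* **single support time** — time within the stride during which exactly one
  foot is in ground contact (s);
* **integrated pressure** — trapezoidal area under a footfall's
  pressure–time curve (instrument units · s);
* **COP cyclogram** metrics: the self-intersection point (CISP) of the
  butterfly-shaped cyclogram, expressed as percentages of the cyclogram's
  anterior–posterior (AP) and medial–lateral (ML) extents, and the
  **single-stance COP path efficiency** — 100 × chord length / path length
  of each foot's single-stance COP trajectory.

Per-unit metrics are reduced to subject × trial means and (n − 1) SDs, and
those summaries feed a two-group × two-condition statistical procedure:
assumption checks with a natural-log transform rule, a two-factor
mixed-design ANOVA (group between subjects, trial/session within), an
independent t or Mann–Whitney U comparison of the Training trials, and a
baseline descriptive table.

## The synthetic generator

Real walkway exports are rarely shareable, so the package carries a
generator that emulates the protocol end to end; every pipeline stage is
exercised and validated against the generator's logged ground truth.

**Gait model.** Heel strikes alternate L/R along a 500 cm walkway in
back-and-forth passes. Step lengths are i.i.d. normal with SD
`stride_length_sd`/√2, so successive-ipsilateral-heel-strike distances have
the subject's stride SD; mean stride length is 110 ± 10 cm between subjects
and stride velocity 110 ± 12 cm/s, typical of healthy older adults. Step
timing is step length over mean velocity plus a 10 ms jitter. Toe-off is
scheduled so that each single-stance phase averages half the subject's
single support time (default 0.78 ± 0.06 s per stride). Within stance the
COP advances 18 cm heel-to-toe with a smooth two-harmonic lateral meander of
amplitude `cop_waviness` (default ≈ 0.15 cm, which yields single-stance
efficiencies near 99%, the range reported for healthy gait). Pressure
follows a half-sine per stance scaled by body weight.

**Perturbation coupling.** The protocol literature specifies the stimulus,
not the biomechanical response, so the coupling is a deliberate modelling
choice: a pulse overlapping a stance adds a lateral COP offset equal to
pulse force × `perturbation_susceptibility` (default 0.02 cm/N), held for
the pulse width and decaying exponentially with a 0.3 s time constant —
the simplest first-order response that is testable and monotone in the
force. Vertical (up/down) pulse components scale the pressure curve during
the pulse and leave COP position unchanged; this is a synthetic-only
convention. Inter-pulse gaps are uniform on [3 s, 8 s], chosen to give a
plausible pulse count in a 5-minute trial; both bounds are configurable.

**Randomness.** A single master seed expands into fixed per-subject,
per-trial substreams, so any subset of a cohort is reproducible in
isolation and reruns are byte-identical.

**Two fidelities.** `simulate_cohort(fidelity = "recordings")` produces
full COP sample streams. `fidelity = "summary"` draws the per-subject trial
summaries directly from the same cohort model (a between-subject random
effect plus within-subject noise; for efficiency, 98.9 with between/within
SDs 0.65/0.45, consistent with the 98.7–99.2 range of healthy training
trials). Monte-Carlo calibration and power studies use the summary
fidelity — thousands of recording-level cohorts would be pointlessly
expensive — and the two levels are tied together by the parameter-recovery
tests, which push recordings through the full pipeline and compare against
the generator log. Injected effects (`effect_spec`) are expressed as
Cohen's d on the subject-summary scale; with the default 50/50
between/within variance split, an interaction of d = 1.5 at n = 20 per
group is detected essentially always, and null cohorts reject at the
nominal 5%.

**What the generator does not emulate.** No musculoskeletal dynamics, no
fatigue or learning trends within a trial, no turns (passes are clean), no
missing-sensor dropout, Gaussian rather than heavy-tailed variability.
Passing tests validate the pipeline's arithmetic and the statistical
procedure's operating characteristics under these idealized conditions;
they say nothing about, e.g., footfall segmentation quality in real
exports.

## Cyclogram construction and the CISP

A cycle spans two successive ipsilateral heel strikes. The net COP is the
pressure-weighted average of the feet in contact (a tiny ε weight keeps the
average defined at zero-load instants). Because the raw AP coordinate
advances monotonically overground, a butterfly (and hence a
self-intersection) only exists after removing forward progression; the
package removes the OLS linear trend of AP on time over the cycle, anchors
the frame at the leading heel strike, and centres ML on the cycle midline.
The two double-support transfer strokes then cross near mid-extent, as on a
treadmill force-plate butterfly. Reports of CISP percentages rarely state
the normalizing denominator; here **AP% = 100 (CISP − min AP)/(AP
extent)** and **ML% is a signed percentage of half the ML extent about the
midline**. These choices only rescale the coordinates, so group or
condition comparisons (the quantities analysed) are unaffected.

The self-intersection is computed by pairwise segment intersection over
non-adjacent segments with a bounding-box prefilter; when several crossings
exist, the one nearest the AP midpoint wins, ties broken by the earliest
position along the path — butterflies cross centrally, and the rule is
deterministic. Cycles with no crossing (typically the first cycle of a
pass, which lacks its leading double support) are flagged and excluded from
summaries with counts retained. A brute-force all-pairs search is kept in
the test suite as an oracle; the two agree to 10⁻⁹ on hundreds of random
cyclograms.

Efficiency is computed in the horizontal plane only, per foot per cycle,
and per-cycle metrics are averaged per subject — never the CISP of a
time-averaged cyclogram — because the per-person SDs are themselves
analysis variables.

## Numerical and procedural choices

* Heel-strike position is defined as the first COP sample of a footfall;
  walkway exports carry no anatomical landmarks.
* Strides never span passes; the pass boundary comes from the file.
* Sampling is taken as-is (trapezoid on the recorded grid, no resampling);
  non-monotone sample times are a hard validation error, never reordered.
* Single support for a stride requires a contralateral contact already on
  the ground at stride start; otherwise the leading double support is
  unobservable and the stride is flagged `missing_contra` and excluded.
* Pass normalization rotates each pass so the displacement from the first
  heel strike to the last *ipsilateral* heel strike points along +y; using
  the same foot avoids a lateral bias in the direction estimate, and the
  map is idempotent.
* Mixed-ANOVA sums of squares use the subject mean/difference
  decomposition. With two within-levels this reproduces `aov`'s error
  strata exactly (asserted in tests) and makes the interaction F equal the
  squared pooled t on difference scores. Effects with zero sum of squares
  report F = 0, p = 1 (constant data would otherwise yield 0/0). Degrees
  of freedom follow the data actually supplied after listwise exclusion;
  they are not forced to any published value.
* The transform rule: natural log on the raw (positive) metric values only
  when homoscedasticity and sphericity hold but normality fails
  (Shapiro–Wilk on cell residuals, Levene across groups, both at α = 0.05;
  sphericity is automatic with two within-levels). Already-normal data are
  never transformed, so the procedure is idempotent.
* Mann–Whitney U is reported as min(U₁, U₂) with midranks for ties and a
  two-sided p from the normal approximation with continuity correction.
* Baseline "paired t-test" between independent groups is a mismatch; the
  default is an independent two-sample t, with `as_printed = TRUE`
  providing a row-order-paired mode for comparability with reports that
  used one.
* No multiplicity correction is applied across the battery, matching the
  analysis style the package mirrors.

## Problem sizes used in validation

The shipped suite runs the full pipeline at deliberately modest sizes
chosen to probe every code path while keeping the suite quick: single-trial
recordings of 25–90 s (60+ strides for recovery checks at 2 SE), cohorts
of 2–20 subjects per group, 1000-replicate null calibration and
200-replicate power runs at n = 20 per group on the summary fidelity, and
oracle sweeps of 200–1000 random segments/cyclograms. Full five-trial,
40-subject recording cohorts at protocol durations are supported and run in
minutes through the CLI.

## Limitations

The CISP percentage basis and the walkway software's exact stride
conventions are proprietary/unstated; our definitions are documented above
and internally consistent, but absolute CISP values are not comparable
across implementations with different normalizations. The
perturbation–COP coupling is an assumption, adequate for validating the
pipeline, not a biomechanical model. Euclidean heel-to-heel stride length
slightly exceeds progression-axis stride length when lateral placement
varies; the difference is second order at realistic step widths.
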