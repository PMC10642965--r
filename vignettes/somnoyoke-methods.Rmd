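---
title: "somnoyoke: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnoyoke: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

somnoyoke implements, as one tested pipeline, the analysis chain of a
yoked-control sleep-deprivation experiment in *Drosophila*: a generative
model of fly locomotor activity, two virtual deprivation engines,
velocity- and beam-count-based sleep scoring under a parameterizable
inactivity criterion, homeostatic rebound quantification normalized to
unperturbed controls, and a three-condition MALDI-TOF peak-pattern screen.
This vignette is the package's own account of the underlying models, the
parameters that matter, and the design choices that were genuinely open.

## The scoring conventions

Activity is a per-fly series of maximal velocities (mm/s) in 10-s epochs,
8640 epochs per day, anchored to Zeitgeber time (ZT0 = lights-on, ZT12 =
lights-off, 12:12 LD). The conventions are deliberately strict:

* an epoch is **immobile** iff its maximal velocity is strictly below
  1 mm/s;
* a **sleep bout** is a maximal run of immobile epochs whose duration is at
  least the inactivity criterion *k* (closed inequality). Standard sleep
  uses *k* = 300 s; long-bout ("deep") sleep uses *k* = 1500 s (25 min);
  short ("active") sleep is the band [60 s, 300 s);
* bouts spanning an analysis-window boundary are **split at the boundary**
  and each fragment is re-tested against *k* inside its window. The split
  rule was an open choice; we adopt it because it makes per-day totals
  additive, and the concatenation-invariance property test pins it down.

P(doze) — the probability that an active time bin is followed by an
inactive one — and its converse P(wake) are computed on 60-s activity bins
(a bin is active iff any of its epochs is active). The bin size is a config
knob; 60 s is our choice, since the metric is defined on coarse activity
bins rather than raw epochs, and the source material for this experiment
does not state the bin width it used.

DAM (infrared beam-crossing) series are scored with the field convention:
a bin is immobile iff its count is zero, with no debouncing.

## The generative model

No generative model exists in the experimental literature this pipeline
serves; we adopt the minimal structure that reproduces every qualitative
pattern the downstream analyses test — a discrete-time, two-process-style
state machine per fly:

* **Circadian propensity** `w(ZT)`: a baseline plus two Gaussian
  components, a daytime siesta peak (ZT7) and a larger night peak (ZT18).
* **Homeostatic pressure** `P`: rises by `pressure_gain` every awake
  epoch, falls by `pressure_decay` every asleep epoch (floored at 0).
* **Sleep onset**: while awake, the per-epoch onset probability is
  `onset_base * w(ZT) * (1 + pressure_onset_coef * P) / (1 + h)`, capped
  at 0.5, where `h` is the hyperactivity elevation (below).
* **Bout duration**: at onset the fly draws a lognormal bout length (in
  epochs) with day/night location parameters, scaled by
  `1 + pressure_bout_coef * P`. Pressure therefore discharges
  preferentially into *long* bouts — the mechanism that plants the
  homeostatic rebound in the >= 25-min sleep state.
* **Speeds**: resting epochs draw uniformly from (0, `rest_max`] with
  `rest_max` = 0.8 mm/s; active epochs draw `1 + lognormal * m(ZT) *
  (1 + h)`, where `m(ZT)` carries crepuscular morning/evening activity
  peaks. Rest mass lies strictly below and active mass strictly above the
  1 mm/s immobility boundary, so scoring never sits on the knife edge.
* **Stimulus coupling**: with probability `arousal_prob` (default 1) a
  stimulus forces the next epoch active and increments `h` by
  `hyperactivity_gain`, saturating at `hyperactivity_max`; `h` decays
  exponentially with half-life `hyperactivity_halflife_h`. `h` both
  elevates active speed and divides the onset probability, so mechanical
  stimulation leaves a decaying, sleep-suppressing locomotor elevation —
  the sleep-independent masking effect that makes yoked controls
  necessary. The magnitude of this effect has no published quantitative
  anchor; `hyperactivity_gain` = 0.05 per stimulus (cap 1.5, half-life
  16 h) is a calibration knob, chosen so the post-deprivation elevation is
  clearly measurable while focal-vs-yoked rebound survives it.

Every fly runs on an RNG substream derived deterministically from the
master seed and its id, so cohort membership, ordering, or the presence of
other flies never perturbs an individual trace, and a stimulated fly has an
exactly comparable unperturbed "twin" under the same substream.

### The frozen reference calibration

The defaults of `fly_params()` (also shipped as
`inst/extdata/reference_params.conf`) were calibrated once, against the
study conditions the analyses assume, and then frozen:

* a bimodal standard-sleep profile (siesta + night peak) with total sleep
  ~680 min/day;
* night/day long-bout (>= 25 min) sleep ratio ~2 (checked over 50
  simulated flies x 5 days);
* a mean of 12-14 tube rotations per focal fly per 24 h under the 1320-s
  inactivity trigger (checked over 50 focal flies);
* a post-deprivation sleep surplus concentrated in long bouts and
  discharged over multiple cycles (`pressure_decay` is set so a 24-h debt
  takes roughly three days to drain).

What the generator does **not** emulate: positional micro-movement,
grooming, feeding bouts, death, between-fly parameter heterogeneity, or
any biomechanics of the rotation stimulus. Passing tests therefore show
that the *analysis chain* behaves correctly on data with the assumed
statistical structure — not that real flies obey this model.

## The deprivation engines

Two regimes, both coupled to the simulator (stimuli alter subsequent
behaviour; they are never a post-hoc edit):

* **Fixed-interval** ("vortexer"): one 2-s shake at a uniformly random
  offset within every complete interval (20, 120 or 220 s), delivered
  monitor-wide; a 24-h window at 220 s yields exactly floor(86400/220) =
  392 shakes. A shake marks the whole 10-s epoch it lands in.
* **Inactivity-triggered** (closed loop): a per-fly timer counts
  consecutive immobile epochs inside the deprivation window; the trigger
  fires in the epoch where accumulated immobility first reaches the
  threshold (220 s forbids standard sleep; 1320 s = 22 min forbids only
  >= 25-min bouts, the 22-min setting deliberately undercutting the 25-min
  criterion), then re-arms — regardless of whether arousal succeeds. The
  re-arm rule is left implicit by the protocol wording; firing-then-reset
  is the only reading that makes "every time a fly was inactive for T"
  well defined, and the timer is property-tested against a brute-force
  run-length rescanning oracle.
* **Yoking**: the yoked partner's stimulator is bound to the focal fly's
  tracker — it receives rotations at exactly the focal trigger epochs,
  regardless of its own state. `verify_yoking()` is a standing regression
  guard on that contract.

Whether real rotations ever fail to arouse a fly is unreported;
`arousal_prob` exposes the assumption rather than hard-coding it (default
1, matching the reported completeness of deprivation).

## Rebound quantification

Per fly: debt = baseline-day sleep − deprivation-window sleep; gain on
post day *d* = (focal post-*d* − focal baseline) − (unperturbed cohort
mean post-*d* − unperturbed cohort mean baseline); cumulative recovery =
cumulative gain / debt, in percent, with overshoot past 100% retained.
Two open points were settled as follows: the unperturbed terms are
*cohort means day-matched to each focal fly* (the design pairs focal with
yoked flies, not with unperturbed ones, so no per-fly unperturbed pairing
exists), and flies with non-positive debt at a given criterion are
excluded from surface means and counted in a QC attribute rather than
contributing undefined fractions.

`criterion_sweep()` recomputes the recovery surface while sweeping the
inactivity criterion from 1 to 30 min over up to three post days. With the
reference generator, day-3 recovery is maximized at criteria of 25-30 min
and clearly exceeds recovery under the 5-min standard definition — the
long-bout-specific rebound structure the sweep exists to reveal.

Group comparisons use Wilcoxon rank-sum (two groups) or Kruskal-Wallis
with Bonferroni-adjusted pairwise rank-sum tests (three or more); the
reported W is the Mann-Whitney statistic of the first-named group,
printed alongside group medians to remove orientation ambiguity. Exact
small-sample behaviour below 50 per group and midrank/normal-approximation
handling of ties follow `stats::wilcox.test`. The vortex-grid design
feeds a two-way fixed-factor ANOVA (treatment x trigger frequency) whose
interaction term carries the inference.

## The MALDI peak screen

Input is an m/z-peak x brain-section intensity table with sections
labelled focal / yoked / unperturbed. The test cascade is
omnibus-then-posthoc: per peak, a Kruskal-Wallis omnibus test (or, in
no-yoking mode, a focal-vs-unperturbed rank-sum test), Benjamini-Hochberg
correction *across the peak family*, a q >= alpha gate to "NS", then
Bonferroni-adjusted pairwise rank-sum tests *within* the peak, with effect
direction taken from group medians. The named statistical ingredients
(KW, Bonferroni pairwise, BH across peaks) do not uniquely determine their
combination; the gate-then-posthoc cascade is the most conservative
faithful composition, and both alphas are exposed as knobs. Categories:

| category | pattern |
|---|---|
| mechanical | F > U and Y > U significant, F-Y NS |
| sleep_pressure | U < Y < F, all three pairs significant |
| sleep_absence | F > Y and F > U significant, Y-U NS |
| NS | omnibus q >= alpha |
| other | anything else (including focal significantly *lower*) |

"Similar/indistinguishable" is operationalized as pairwise
non-significance after correction — an accept-the-null convention and a
known limitation, documented rather than hidden. At realistic section
counts (6/3/4 per condition) the exact rank-sum p-value floors
(2 / choose(n1+n2, n1)) can exceed the Bonferroni-corrected alpha, making
some patterns formally unattainable; the screen still runs and reports
these floors in its QC output. The adduct annotator uses M+H (+1.007 Da)
with a ±0.2 Da tolerance, which places serotonin (average mass 176.2) at
~177.2 m/z.

The fixture generator plants categories as multiplicative effects on a
lognormal baseline (sleep-pressure peaks get the square-root of the effect
in yoked sections, giving the graded U < Y < F ordering). Planted-category
recovery exceeds 90% at a 4x effect with 10 sections per condition, and on
all-null fixtures the BH gate keeps the fraction of screens with any false
category call within its nominal bound.

## Numerical and degenerate-input choices

* All probabilities are clipped into [0, 1] (onset at 0.5); pressure is
  floored at 0; bout draws are at least one epoch.
* P(doze)/P(wake) return `NA` (flagged undefined) when the conditioning
  set is empty; recovery fractions with non-positive debt warn and return
  `NA`.
* Velocity thresholding is strict (`< 1`), criterion thresholding closed
  (`>= k`); both are pinned by boundary tests (0.99 vs 1.0 mm/s; 290-s vs
  300-s bouts).
* The DAM emitter guarantees at least one count in any bin containing
  activity; the Poisson-mean property then holds up to a zero-truncation
  bias that is negligible at the default rate.

## Problem sizes used by the shipped checks

The test-suite and acceptance computations use cohorts of 20-100 pairs
simulated for 1-5 days (a 50-pair, 5-day design runs in a few seconds),
1000-case property sweeps for the oracle equivalences, 100-draw null
ensembles for the FDR and type-I-error checks, and 100-300 simulated
tables for the ANOVA calibration checks. These sizes give comfortable
Monte-Carlo margins for every asserted bound.

## Known limitations

* The generator's homeostat is linear and memoryless beyond `P`; it does
  not model circadian gating of *arousal*, state inertia, or
  ultradian structure.
* Masking, pressure, and bout-lengthening interact multiplicatively; real
  mechanical stress physiology is undoubtedly richer.
* The screen's accept-the-null reading of "indistinguishable" inherits the
  power limits of exact rank-sum tests at small n.
* DAM emulation reduces a velocity trace to beam crossings with a single
  rate parameter; positional beam geometry is not modelled.
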