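# somnoyoke

Yoked-control sleep-deprivation analysis for *Drosophila* activity data.

Mechanical sleep deprivation — the workhorse of fly sleep research — does
two things at once: it removes sleep, and it shakes the animal. Responses
measured afterwards therefore mix genuine homeostatic sleep pressure with
sleep-independent effects of the mechanical insult, which can mask rebound
entirely. The yoked-control paradigm separates the two: for every *focal*
fly whose inactivity closes the loop on a rotation stimulus, a paired
*yoked* fly receives the identical, time-locked stimuli regardless of its
own state. Focal and yoked flies then share the same mechanical history but
differ in sleep lost, so focal-vs-yoked contrasts isolate sleep pressure,
while focal-vs-unperturbed contrasts confound it with the stimulus.

somnoyoke packages that whole experimental logic as testable software, for
sleep/circadian researchers who want the analysis chain without hardware:

* **Generative model** of fly activity (maximal velocity in 10-s epochs):
  a two-process-style state machine with bimodal circadian propensity
  `w(ZT)`, homeostatic pressure `P` (onset probability ∝
  `w(ZT)·(1 + aP)`; bout duration lognormal, scaled by `1 + bP`, so debt
  discharges into long bouts), and a decaying post-stimulus hyperactivity
  elevation `h` that both raises active speed and suppresses onset — the
  masking effect.
* **Virtual deprivation engines**: fixed-interval monitor-wide shaking
  (2 s every 20/120/220 s) and closed-loop inactivity-triggered rotation
  (trigger at 220 s of immobility to forbid standard sleep, or 1320 s =
  22 min to forbid only ≥ 25-min "deep" sleep), with yoked stimulus
  binding and a yoking verifier.
* **Sleep scoring**: strict `< 1 mm/s` immobility, bouts ≥ criterion *k*
  (standard *k* = 5 min, swept 1–30 min), short-sleep band [1, 5) min,
  P(doze)/P(wake) transition metrics, TriKinetics DAM monitor file
  reader/writer and zero-count bin scoring.
* **Rebound analysis**: debt = baseline − deprivation-window sleep;
  gain normalized to unperturbed controls,
  `(F_post − F_pre) − (U_post − U_pre)`; cumulative recovery fraction
  (gain/debt, overshoot retained); the criterion × post-day recovery
  surface; rank-sum / Kruskal-Wallis + Bonferroni comparisons and the
  treatment × frequency interaction ANOVA.
* **MALDI-TOF peak screen**: Kruskal-Wallis omnibus per m/z peak, BH
  correction across the peak family, Bonferroni pairwise rank-sum tests
  within peaks, and category calls — `mechanical` (focal = yoked >
  unperturbed), `sleep_pressure` (unperturbed < yoked < focal),
  `sleep_absence` (focal alone elevated), `NS`, `other` — plus
  M+H adduct annotation (serotonin 176.2 → ~177.2 m/z).

## Worked example

```r
library(somnoyoke)

ex <- run_experiment("yoked-220", seed = 42, n_pairs = 10,
                     n_unperturbed = 8, n_post = 3)
ex$yoking
#> <yoking_report> PASS: all pairs matched, controls clean

rb <- ex$rebound_long   # 25-min (long-bout) criterion
aggregate(cum_recovery_pct ~ condition + post_day,
          rb[rb$debt_min > 0, ], mean)
#>  condition post_day cum_recovery_pct
#>      focal        1         62.90050
#>      yoked        1         97.89087
#>      focal        2        100.34066
#>      yoked        2        189.88096
#>      focal        3        124.46099
#>      yoked        3        272.45528
```

Every focal fly's rotation log matched its yoked partner's exactly, and no
unperturbed fly was stimulated. Focal flies — fully deprived of long-bout
sleep during the 24-h window — recover their long-bout sleep debt
cumulatively across the three recovery days (63% → 100% → 124% of debt,
normalized to unperturbed controls); the yoked fractions run high because
yoked debt at the 25-min criterion is small. A planted-fixture screen shows
the category logic at work:

```r
fx <- generate_peak_table(maldi_params(
  n_sections = c(focal = 10, yoked = 10, unperturbed = 10), seed = 42))
maldi_screen(fx$table, "yoked")
#> <maldi_screen> mode yoked, alpha 0.05: 188 peaks
#>   NS               81 (43.1%)
#>   mechanical       73 (38.8%)
#>   sleep_pressure    9 (4.8%)
#>   sleep_absence     8 (4.3%)
#>   other            17 (9.0%)
```

A command-line front end over the same functions ships at
`inst/cli/somnoyoke.R` (subcommands `run`, `simulate`, `score`, `rebound`,
`maldi`).

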