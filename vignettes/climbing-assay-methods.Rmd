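---
title: "Methods: multibeam climbing-assay analysis with flyclimb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multibeam climbing-assay analysis with flyclimb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyclimb)
```

## The assay and its measurement model

Negative geotaxis — the innate drive of a disturbed fly to climb against
gravity — is the work-horse behavioural readout for *Drosophila* motor
phenotypes, including parkin (`park25`) models of Parkinson's disease and
their pharmacological rescue. flyclimb analyses the instrumented version of
the assay: a single fly in a vertical tube monitored by an array of infrared
beams that reports the fly's position once per second, in 3 mm bins, along a
51 mm detection zone. That geometry yields 17 unique positions; flyclimb
adopts the convention `h = 3 p` mm for position index `p`, so the top
position maps to the 51 mm tube top and the lowest observable state is 3 mm.
Under this convention the three equal 17 mm dwell sections (lower 1–17 mm,
middle 18–34 mm, top 35–51 mm) split the positions cleanly 5/6/6, with no
position straddling a boundary. Whether the hardware reports bin centers or
edges is not documented for the device; the convention is explicit in
`assay_geometry()` and configurable.

The standard recording is 20 minutes at 1 Hz (1200 samples). Everything
downstream is computed from the per-second height series; there is no
sub-second interpolation, because 1 Hz / 3 mm *is* the native resolution of
the instrument and all derived quantities inherit it.

## Per-fly climbing metrics

A **movement** is any height change between consecutive seconds. A
**climbing event** opens at the local minimum preceding an upward movement,
peaks at the maximum height reached before the next downward movement, and
closes at that up-to-down reversal; pauses between upward movements do not
close an event. A **complete ascent** is a maximal non-descending run that
starts at the lowest observable height and reaches the tube top. "Bottom of
the tube" is taken as position 1: the physical tube floor lies below the
detection zone (a yarn plug occupies the bottom of the tube), so 3 mm is the
lowest observable state.

Per fly, `compute_metrics()` reports: number of climbing events and of
climbs reaching the top, mean height gained per event and mean event peak
height, total height climbed (the sum of all positive per-second deltas),
complete ascents, the three dwell times, total movements, and ascending /
descending velocities.

Three definitional choices were genuinely open and are resolved as follows:

* **Height gained per event** is measured from the event's own local minimum
  (not from the tube bottom), matching the reading "height climbed in each
  climbing event". The alternative is a one-line change but is not exposed.
* **Velocities** are means of the per-second deltas over seconds with
  movement in that direction, rather than per-event means: at 1 Hz with 3 mm
  bins the per-second delta is the native velocity estimate, and no formula
  is prescribed by the assay description.
* **Terminal ascents**: a fly that climbs to the top in the final seconds
  and stays there would register zero events under a strict
  reversal-counting rule. By default an ascent still open at the end of the
  recording is counted (`count_terminal_ascent = TRUE`); the strict reading
  is available by flag.

Mean-of-empty-set metrics (event averages and velocities for motionless
flies) are `NA`, never 0, so that group means are not dragged toward zero by
flies that never moved; group-level code drops them listwise per metric with
a logged count.

## Descents: drops versus descending climbs

Descents are segmented analogously (opening at a downward movement, closing
at an upward movement, a long pause, or the end of the recording) and then
classified by the video-validated thresholds: both descent types must cover
**more than 3 mm** (the minimum distance the monitor can record); a **drop**
is a descent faster than **8.97 mm/s**; a **descending climb** is slower
than **6 mm/s**. All inequalities are strict; descents whose mean velocity
falls in `[6, 8.97]` mm/s are `unclassified` and excluded from both
behavioural counts, exactly as non-differentiable descents were excluded
from the original video validation.

Two numerical choices deserve note:

* **Internal pauses up to 2 s are absorbed** into an ongoing descent. A
  genuine descending climb below 6 mm/s necessarily crosses a 3 mm bin less
  than once per second, so its trace is `-3, 0, 0, -3, ...`; pause-free
  segmentation would shatter every slow descent into 3 mm fragments below
  the distance floor. Because a true descent faster than 1 mm/s crosses
  bins at most 3 s apart, the 2 s tolerance keeps slow descents intact
  while a longer pause (a genuine stop) closes the descent.
* **Velocity is total distance over total duration** including absorbed
  pauses, the simplest mean-velocity definition; a fall completed within a
  single inter-sample gap is attributed 1 s (the resolution floor), so any
  fall of 12 mm or more within one sample is a drop by construction.

## The behavioural simulator and what a green test establishes

`simulate_fly()` runs a continuous-time semi-Markov cycle — rest, ascent to
a sampled target peak, a pause at the peak, then a descent (drop or
descending climb) — with event durations on a 0.05 s grid, position clamped
to the detection zone, and the resulting piecewise-linear path sampled at
1 Hz and quantized to the nearest 3 mm bin (so sampled heights are always
within 3 mm of the continuous truth). Every episode is logged with its true
type, times, heights and velocity, giving ground truth for recovery tests.

The three bundled presets (`control`, `park25`, `park25_nicotine`) are
calibrated **only to directional orderings** — controls initiate climbs at
similar rates but climb higher, reach the top more often, dwell less at the
bottom, and perform more descending climbs; the nicotine preset is
intermediate — never to published group means, which were measured on live
flies and are not reproducible at desk scale. Drops are modelled at
20–40 mm/s and descending climbs at 1–5 mm/s so that true labels avoid the
classifier's excluded band by construction. Rest durations are exponential
(mean 8–12 s away from the bottom; at the bottom, the climb-initiation rate
of 2/min sets the mean), and per-fly RNG substreams are derived as
`master seed + fly index`, so cohorts are reproducible independent of
iteration order.

What the simulator does **not** emulate: grooming and lateral motion,
beam-detection noise and dropouts (gap handling is tested with constructed
fixtures instead), correlated behaviour within a monitor, and any
pharmacokinetics — "nicotine" presets simply shift behavioural parameters.
A green recovery test therefore establishes that the pipeline's segmentation
and classification recover the stated event structure at the instrument's
resolution — not that the presets reproduce real fly biology.

One resolution artifact matters when reading recovery numbers: a short drop
that straddles a sample boundary is observed at half its distance per
second (a 12 mm drop seen across two samples is always 6 mm/s), landing in
the excluded band *regardless of its true speed*. The recovery metric
therefore follows the validation convention of the original video study:
accuracy is computed over classifiable descents (those receiving a definite
label), with the classifiable fraction reported separately as coverage (and
asserted to stay above 80% in the acceptance suite). On default presets the
classifiable accuracy is ~99% with ~95% coverage, comfortably above the 95%
bar that echoes the published 94.9% (298/314) video validation.

## Group statistics

* `two_way_anova_tukey()` — least-squares factorial ANOVA with Tukey HSD.
  Unbalanced cohorts (the rule in real experiments) use **Type II sums of
  squares** by default, the conventional choice when inference focuses on
  main effects; Type III (sum-to-zero contrasts) is available. Tukey
  comparisons run on genotype-by-dose cells by default, or on marginal
  means. Empty cells and zero residual degrees of freedom are hard errors
  naming the offending cell.
* `fisher_exact()` — two-sided exact p by summing hypergeometric
  probabilities no larger than the observed table's (with the customary
  `1 + 1e-7` relative tolerance for ties). The test suite checks it against
  an independent binomial-coefficient enumeration over every 2x2 table with
  total at most 30.
* `marascuilo()` — omnibus chi-square plus the Marascuilo critical range
  per pair, with Bonferroni correction. The Bonferroni divisor defaults to
  the number of comparisons actually made: all pairs, or, when a control
  group is designated, control-versus-each-treatment only (matching how
  multi-dose flight percentages are compared to their control).
* `window_analysis()` — for each genotype and treatment start day, a Fisher
  exact test of treated versus matched untreated flies (same-day untreated
  when present, otherwise the genotype's pooled untreated). The empirical
  **window edge** is the last start day of the unbroken run of significant,
  direction-consistent effects beginning at the earliest day; a stratum
  with a zero column margin (nobody flew in either arm) is treated as
  p = 1. The therapeutic-window idea this operationalizes: treatment
  started early enough rescues flight; started too late, the effect
  vanishes.

### The window-recovery stated world

The window-recovery test simulates, per replicate, days 0–8 with 50 flies
per arm: `park25` untreated flight probability 0.06 versus 0.40 when
treatment starts on days 0–5 (the true edge), and controls harmed by
treatment through day 6 (0.88 versus 0.55). The untreated baseline of 6% and
the *existence* of a day-5 flight window follow the published phenotype;
the treated probability is deliberately larger than the published ~20%
maximum because at the prescribed n = 50 per group a 7%-versus-20% Fisher
test has ~50% power, and the recovery criterion is meant to measure the
edge-finding logic, not Fisher power (the original study pooled several
experiments per point). Even so the criterion is tight: with per-day power
0.982 over six window days and a 0.008 false-positive rate at day 6, the
expected recovery rate is about 0.89–0.90 against the ≥ 0.90 bar; the fixed
seeds of the acceptance suite recover the edge in 93/100 replicates, and
independent seeds fluctuate between roughly 88 and 93.

## Degenerate inputs and numerical conventions

Monitor gaps are imputed hold-last (back-filled at the head); a gap longer
than 5 s flags the fly, and flagged flies are excluded from metric tables by
default with a logged message — the imputation is the least-inventive choice
for a device that stops reporting when no beam fires, and flagging keeps
exclusions auditable. Flight outcomes parse strictly from
`0/1/yes/no/true/false`; anything else is an error rather than a guess.
Heights off the 3 mm grid, positions outside 1–17, and non-monotone
timestamps are validation errors naming the line. All randomness flows from
explicit integer seeds; derived seeds stay below 2^31.

## Known limitations

Single-fly tubes only (no multi-fly disambiguation); no sub-second
kinematics, posture, or wing-state inference — the 750 frames/s video work
behind the drop thresholds is *used* (as the 8.97 / 6 mm/s cutoffs), not
reproduced; the exact decision rule the original spreadsheet used beyond
those cutoffs and the 3 mm floor is not published, so only the stated
thresholds are implemented; and the statistics module intentionally stops at
the tests used in this assay family (no mixed models or survival analysis).
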