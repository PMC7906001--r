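---
title: "Methods: adaptive velocity-threshold classification and eye-hand coordination metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive velocity-threshold classification and eye-hand coordination metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyehand)
```

## The problem

In minimally invasive (endoscopic) surgery the operative field is seen only
on a monitor while the instruments are driven by hand, so eye-hand
coordination is a core trainable skill. Training simulators can log two
kinematic streams per trainee: the on-screen binocular gaze position from an
eye tracker (here nominally 60 Hz, 1920 x 1080 px, top-left origin) and the
3D position of the haptic stylus that drives the virtual tool (nominally
100 Hz, arbitrary device units). `eyehand` turns those two streams into a
small set of interpretable metrics and a statistical summary of how tightly
gaze behaviour and hand kinematics are coupled.

The pipeline is: align the two clocks, segment the session into its repeated
tasks, classify each signal into *stable* intervals (fixations for the eye,
stand-stills for the hand), *rapid* intervals (saccades, sudden sharp
movements) and *gaps* (blinks, dropouts), reduce each task to six metrics --
FD (mean fixation duration, ms), FN (fixation count), SN (saccade count),
SSD (mean stand-still duration, ms), SSN (stand-still count), SSM
(sudden-sharp-movement count) -- and correlate the three eye-hand pairs
FD--SSD, FN--SSN, SN--SSM per skill group.

## The event classifier

Classification is purely velocity-based and entirely data-driven, so it
needs no device calibration and no user-set threshold, and it behaves
identically across sampling rates and unit conventions.

**Velocity.** For positions $x_i$ at times $t_i$ (ms) the point-to-point
speed is $v_i = \lVert x_{i+1} - x_i \rVert / (t_{i+1} - t_i) \times 1000$,
in units/s. Speed $v_i$ is attributed to the half-open interval
$[t_i, t_{i+1})$; the $n$ samples of a stream yield $n-1$ intervals exactly
tiling $[t_1, t_n)$. No smoothing is applied by default (an optional
3-sample running median is available via `event_config(median_filter =)`).

**Adaptive threshold.** The stable/rapid cutoff $\theta$ for one signal is
the fixed point of a trimmed mean-plus-$k$-sigma iteration:
$\theta_0 = \mu + k\sigma$ over all finite speeds, then repeatedly
$\theta \leftarrow \mu_{<\theta} + k \sigma_{<\theta}$, the mean and sample
SD of the sub-threshold speeds, until the update falls below `tolerance`
(default 1 unit/s) or `max_iter` (50) is reached. Defaults use $k = 3$.
When the signal is noise plus a small fraction of much faster movement
samples, the iteration walks down from the movement-inflated initial value
and settles just above the noise mode; on pure Gaussian noise its limit has
a closed form through truncated-normal moments, which the test suite uses
as an oracle. Degenerate inputs are defined explicitly: fewer than 10 finite
speeds is an error; identical speeds return the configurable floor
(default $10^{-6}$ units/s) with `converged = TRUE`. The iteration relies
on rapid samples being a minority (roughly under a tenth of the signal);
when fast movement dominates a recording, $\mu + 3\sigma$ of the full
mixture can exceed every observed speed and the estimate degenerates to its
starting point -- a documented limitation of this family of estimators.

**Binocular rule.** For gaze, each eye gets its own threshold from its own
speed series, and an interval is labelled stable only when *both* eyes are
sub-threshold (`binocular_rule = "both"`; `"either"` is available). An
interval touching a sample flagged invalid on either eye is a gap.

**Grouping rules.** Interval labels become events by run-length grouping
with duration filters, applied in a fixed order:

1. maximal runs of equal labels become candidate intervals;
2. stable runs shorter than `min_stable_ms` (default 50 ms, i.e. at least
   3 gaze samples at 60 Hz and 5 hand samples at 100 Hz) are relabelled
   rapid, decided simultaneously on the pre-filter durations;
3. adjacent same-kind intervals merge;
4. rapid runs shorter than `min_rapid_ms` (default 10 ms) flanked by stable
   intervals on *both* sides are absorbed into the stable state;
5. same-kind merging again;
6. optionally, gaps up to `max_gap_merge_ms` flanked by stable intervals are
   absorbed; the default is 0 -- gaps never merge, so a fixation split by a
   blink deliberately counts as two fixations.

The output events exactly tile the classified window; the package checks
this invariant, and the test suite verifies the rules against a brute-force
reimplementation on every ternary label sequence up to length 12.

## Metrics and aggregation

Task boundaries come from a marker table (or a fixed 10-s grid); all
intervals are half-open, `[t_start, t_end)`, so segmentations are exact
partitions. Within a segment, an event is counted once, in the segment
containing its midpoint, and contributes the part of its duration inside
that segment -- a tie-break that keeps counts additive across segments. FD
(and SSD) is the mean *clipped* stable duration; a segment with no stable
event reports FD as missing rather than zero, because zeros would bias
duration means downward. Aggregation is per task, then the mean across a
participant's tasks (missing values excluded), then group mean and sample
SD ($n-1$) across participants; a single-participant group reports SD 0
with a flag. Whole-scenario aggregation is available by passing a single
segment.

## The statistical battery

For each group and metric pair the method is gated on normality: Pearson's
$r$ iff Shapiro-Wilk $p > .05$ for both vectors, Spearman's $\rho$ (mid-ranks)
otherwise; a constant vector falls back to Spearman with a warning and an
undefined coefficient. Coefficient strength uses Cohen's bands; the
published tables this package mirrors label a coefficient of .06 "Small+",
so the bands are implemented as the total partition $|r| < .3$ small,
$.3 \le |r| < .5$ moderate, $|r| \ge .5$ strong, with the sign reported
separately. Two-sided p-values throughout; no multiple-testing correction
and no automated outlier removal (an optional report flags $|z| > 3$ values
without excluding them), matching the analysis style the package
reproduces. The correlation unit is configurable: participant-task records
(default; 10 observations per participant) or participant means.

Group comparisons of ordinal observer scores use a Mann-Whitney U with
mid-ranks: $U = \min(U_1, U_2)$ from rank sums, group mean ranks, a
tie-corrected normal-approximation $z$ (no continuity correction), and an
exact permutation p-value whenever $n_1 + n_2 \le 12$ (configurable). With
complete separation of 3 scores above 8, this yields $U = 0$ and mean ranks
10.00 / 4.50 regardless of the raw values. The reported $z$ depends on the
tie structure of the pooled scores, so $z$ values from differently-tied data
are not comparable cell-for-cell.

## The synthetic cohort generator

No raw recordings ship with the package; instead `simulate_cohort()`
generates study-shaped cohorts with known ground truth so that every stage
is testable end to end. It emulates: two skill groups (default 5
intermediates, 10 novices), one scenario of 10 tasks x 10 s separated by
500 ms masked repositioning intervals, gaze at 60 Hz with a fixed 3 px
vergence disparity between the eyes, and a 3D tool trajectory at 100 Hz in
a +-80-unit workspace.

**Coupling.** Eye-hand coupling is planted at the per-task metric level
through a Gaussian copula: each task draws a latent 6-vector (one component
per metric) from a correlated normal whose only nonzero cross-correlations
are the group profile for FD--SSD, FN--SSN and SN--SSM
(`skill_profile()`: intermediate $-.8, -.8, +.8$; scenario-1-like novice
$+.45, +.45, +.55$; scenario-2-like novice $-.45, -.45, +.1$). Monotone
maps turn the latents into counts (discrete uniform ranges, FN and SSN in
8--15, SN and SSM in 3--8 capped at count $-$ 1) and mean durations
(uniform 350--550 ms). Discretising counts onto a handful of levels ties
and attenuates rank correlations, so a planted 0.8 is recovered around
0.65--0.8 -- still inside the "strong" band, which is what the recovery
tests assert.

**Why gap filler is structural.** Within one continuously classified task,
stable time + rapid time = task length, so $FN \cdot FD$ + rapid time is
pinned to the 10-s budget. If fixations and saccades had to tile the task,
FD would be an almost deterministic function of FN and every metric pair
would collapse onto a single degree of freedom; and if saccades absorbed
the slack, rapid samples would dominate the stream and break the adaptive
threshold's working regime. The generator therefore fills the remaining
budget with signal-loss gaps -- blinks on the gaze side, logger dropouts on
the hand side -- placed in the transitions between stable events: of the
$FN - 1$ transitions of a task, SN carry a short saccade (40--60 ms at
1000--2750 px/s along a straight line) and the rest are gaps of at least
60 ms. This makes all six metrics independently plantable, at the price of
synthetic sessions whose invalid fraction (roughly 40--50% of samples) is
far higher than real recordings; real data instead couples FD to
(window $-$ rapid time)/FN. Conclusions from the recovery tests therefore
concern the pipeline's correctness, not the attainable precision on real
eye-tracker output.

**Noise model.** Fixation and stand-still jitter is uniform in a disk (2D)
or ball (3D) of fixed radius (defaults 2 px, 0.1 units). Bounded jitter is
chosen deliberately: the inter-sample speed of disk noise is bounded by
$2a \times \text{rate}$, which sits *below* the $\mu + 3\sigma$ threshold
of the noise's own speed distribution, so a planted stable interval can
never emit a supra-threshold sample and recovery failures always indicate a
pipeline defect rather than a noise tail event. Real tracker noise is
heavier-tailed and produces occasional one-sample velocity spikes; with
Gaussian noise the adaptive threshold by construction leaves a small tail
above $\theta$, which practitioners counter with blink padding and
minimum-duration filters. The generator omits that feature of real data,
and recovery rates on real recordings will be correspondingly lower.

**Rapid-event rendering.** Saccades and transports are straight
constant-speed moves between successive centroids, so the threshold
crossing is sharp and recovered stable boundaries land within one sample
period of the plan. A cosine-ramp profile
(`cohort_spec(transport_profile = "cosine")`) is available; its soft onsets
smear the crossing over a few samples and are excluded from the
boundary-exactness checks. Sudden sharp movements *are* the rendered
transports -- no separate spike entities are superimposed, since a spike
inside a stand-still would simply split it into two stand-stills plus one
rapid event, which the planted counts already cover.

**Not emulated:** smooth pursuit, saccadic main-sequence kinematics,
pupil dynamics, clock drift between devices, force feedback and tissue
contact, camera-channel task structure (the camera is rendered as slow
drift and classified only on request), and realistic blink kinematics
(optional blink injection simply clears validity flags).

## Numerical and design choices

* Time is milliseconds from stream start; every interval is half-open, so
  partitions are exact and boundary samples are never double-counted.
* Alignment applies a user-supplied or auto (align-stream-starts) offset to
  the hand clock and intersects the covered ranges; streams are never
  resampled. Clock drift is assumed negligible over the ~2-minute sessions.
* Classification runs per whole aligned session; task windowing happens in
  the metrics layer, so thresholds are per signal and task segments see
  consistent labels.
* Determinism: `simulate_cohort()` seeds R's RNG from `spec$seed`;
  identical spec and seed give bit-identical streams, and the pipeline
  report embeds the seed, a config hash and package/R versions.
* Problem sizes in the shipped tests and acceptance script are chosen to
  make Monte-Carlo checks stable yet quick: 500-task plans for copula
  calibration, 5 sessions (50 tasks) for count recovery, 100 replicate
  cohorts of 10 participants x 10 tasks for coupling recovery in the test
  suite (25 in the acceptance script), 50 seeds of n = 600 for the
  threshold fixed point.
* CSV is the interchange format, written at full double precision so
  read-write round-trips are bit-exact; column names are remappable through
  a schema argument because logger exports differ.

## Known limitations

The adaptive threshold degenerates when rapid samples dominate a signal
(see above). The 60 Hz gaze rate bounds saccade-boundary precision to
~17 ms, and no attempt is made to correct saccadic position accuracy at
that rate. FD and FN are budget-coupled in real fixed-length windows, so
their correlations with hand metrics partially reflect that shared
constraint rather than coordination alone -- a property of the metric
definitions, not of this implementation. The Mann-Whitney $z$ is reported
for completeness but is only comparable across identical tie structures.
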