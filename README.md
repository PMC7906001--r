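# eyehand

Quantifying eye-hand coordination from gaze and haptic hand trajectories in
simulation-based endoscopic surgery training.

In minimally invasive surgery the operative field is watched on a monitor
while the instruments are steered by hand, so the coupling between gaze
behaviour and hand kinematics is a core trainable skill. Training
simulators log two kinematic streams per trainee: binocular on-screen gaze
from an eye tracker (nominally 60 Hz, 1920 x 1080 px, top-left origin) and
the 3D stylus position of a haptic interface (nominally 100 Hz). `eyehand`
is for researchers and instructional designers who want objective,
device-independent coordination metrics from such logs.

## What it computes

A single velocity-based classifier labels any d-dimensional kinematic
stream into **stable**, **rapid** and **gap** intervals. Speeds are raw
finite differences, `v_i = ||x_{i+1} - x_i|| / (t_{i+1} - t_i)`, and the
stable/rapid cutoff is estimated per signal by the adaptive iteration

```
theta_0 = mean(v) + k * sd(v)
theta   <- mean(v[v < theta]) + k * sd(v[v < theta])   (k = 3, to convergence)
```

so no threshold, unit convention or sampling rate has to be supplied. For
gaze, each eye gets its own threshold and an interval is stable only when
both eyes agree. Applied to the eye the stable/rapid events are fixations
and saccades; applied to the tool trajectory they are stand-stills and
sudden sharp movements. Each task segment then reduces to six metrics:

| signal | metric | meaning |
|---|---|---|
| eye  | FD  | mean fixation duration (ms) |
| eye  | FN  | fixation count |
| eye  | SN  | saccade count |
| hand | SSD | mean stand-still duration (ms) |
| hand | SSN | stand-still count |
| hand | SSM | sudden-sharp-movement count |

Coordination is summarized per skill group by correlating the pairs
FD–SSD, FN–SSN and SN–SSM: Pearson when both vectors pass Shapiro-Wilk
normality (p > .05), Spearman otherwise, with Cohen strength labels
(|r| < .3 small, .3–.5 moderate, ≥ .5 strong). Group differences in ordinal
observer scores use a mid-rank Mann-Whitney U with tie-corrected z and
exact permutation p for small samples. A synthetic cohort generator with
planted ground truth (Gaussian-copula metric couplings) makes the whole
pipeline testable without any recordings; see the methods vignette
(`vignettes/eyehand-methods.Rmd`) for the model and its assumptions.

## Worked example

Plant one 5-s task with 5 fixations of 600 ms (3 saccades) and 6
stand-stills of 500 ms (4 transports), render it, and push it through the
classifier and metrics:

```r
library(eyehand)
set.seed(7)
plan <- make_task_plan(fn = 5, fd_ms = 600, sn = 3,
                       ssn = 6, ssd_ms = 500, ssm = 4, task_ms = 5000)
g <- render_gaze_stream(plan)
eye_ev <- classify_events(g$stream)
eye_ev
#> <event_sequence> 'eye': 5 stable, 3 rapid, 4 gap over [0, 5000) ms
eye_ev$threshold$left
#> <threshold_estimate> theta = 247 units/s (noise 105.3 +- 47.22), 3 iter, converged
unlist(eye_metrics(eye_ev, plan$markers[1, ]))
#>       FD       FN       SN
#> 586.6667   5.0000   3.0000
```

All planted counts are recovered exactly; the measured FD sits within one
sample period (16.7 ms at 60 Hz) of the planted 600 ms because event
boundaries are quantized to the sampling grid. The left eye's threshold,
247 px/s, was found automatically between the fixation jitter (~105 px/s)
and the slowest saccade (~1000 px/s).

A full study-shaped run (5 intermediates, 10 novices, 10 tasks each):

```r
rep <- run_pipeline(run_config("simulate", spec = cohort_spec(seed = 11)))
rep
#> <run_report> scenario S1: 150 records, 15 participants
#>          group   pair   method coefficient strength sign            p
#> 1 intermediate FD-SSD spearman  -0.8453504   strong    - 1.145190e-14
#> 2 intermediate FN-SSN spearman  -0.7295723   strong    - 1.855290e-09
#> 3 intermediate SN-SSM spearman   0.7367856   strong    + 1.061731e-09
#> 4       novice FD-SSD spearman   0.4239226 moderate    + 1.107498e-05
#> 5       novice FN-SSN spearman   0.5166239   strong    + 3.748167e-08
#> 6       novice SN-SSM spearman   0.5111028   strong    + 5.523924e-08
```

The intermediate group's planted profile (strong negative duration/count
couplings, strong positive saccade coupling) and the novices' weaker
positive profile are both recovered in the right bands.

## The analysis workflow

`analysis/` holds the numbered drivers of the full study-shaped analysis —
simulate both scenario cohorts, classify from the stored CSVs, reduce to
metrics and descriptives, run the correlation battery and the observer-score
comparison, and render the reports:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_classify_events.R
Rscript analysis/03_compute_metrics.R
Rscript analysis/04_coordination_stats.R
Rscript analysis/05_report.R
```

Each stage reads only the previous stage's files under `results/` and
prints what it found.

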