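Package: eyehand
Title: Eye-Hand Coordination Metrics from Gaze and Haptic Hand Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying eye-hand coordination in simulation-based
    endoscopic surgery training. Classifies binocular gaze streams and 3D
    haptic tool trajectories into stable (fixation / stand-still), rapid
    (saccade / sudden sharp movement) and gap intervals with a fully
    automatic, adaptive velocity threshold estimated per signal; reduces the
    classified events to six per-task metrics (fixation duration and count,
    saccade count; stand-still duration and count, sudden-sharp-movement
    count); and runs normality-gated Pearson/Spearman correlations with Cohen
    strength labels plus tie-corrected Mann-Whitney group comparisons. A
    synthetic cohort generator plants ground-truth events and metric couplings
    via a Gaussian copula so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
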