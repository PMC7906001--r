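#!/usr/bin/env Rscript
# Simulate the two scenario cohorts (5 intermediates, 10 novices each) and
# write their raw streams to results/data/. Scenario 1 pairs the strong
# intermediate coupling profile with the mildly positive novice profile;
# scenario 2 uses the novice profile whose saccade coupling is near zero.
library(eyehand)

specs <- list(
  s1 = cohort_spec(seed = 1001L),
  s2 = cohort_spec(coupling = list(intermediate = skill_profile("intermediate"),
                                   novice = skill_profile("novice_s2")),
                   seed = 1002L))

for (scen in names(specs)) {
  cohort <- simulate_cohort(specs[[scen]])
  dir <- file.path("results", "data", scen)
  write_cohort(cohort, dir)
  gaps <- mean(vapply(cohort$participants, function(p)
    mean(!p$gaze$samples$valid_left), numeric(1)))
  cat(sprintf(
    "%s: %d participants, %d planted task records, %.0f%% of gaze samples in gaps -> %s\n",
    scen, length(cohort$participants), nrow(cohort$planted), 100 * gaps, dir))
}
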