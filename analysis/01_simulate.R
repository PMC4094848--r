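#!/usr/bin/env Rscript
# Step 1 — simulate the study inputs.
#
# Two kinds of synthetic data stand in for the (undeposited) clinical
# material: a suite of rendered H&E-like scenes with ground-truth masks,
# which exercises the image pipeline, and per-subject cohort feature tables
# drawn from the published group means/SDs (full cohort n = 40 PE vs 35
# control; gestation-matched subgroup n = 10 vs 8).

suppressPackageStartupMessages(library(villimorph))

out <- "results/analysis"
dir.create(file.path(out, "scenes"), recursive = TRUE, showWarnings = FALSE)

# scene suite: reduced-scale frames (320 x 240, 6 villi of ~30 px radius)
# keep the run light; geometry is proportional to the full 1388 x 1040 frame
scene_suite_params <- function(seed)
  scene_params(width = 320L, height = 240L, n_villi = 6L,
               villous_radius_mean = 30, villous_radius_sd = 5,
               villous_radius_range = c(18, 40),
               capillary_radius_mean = 4, capillary_radius_sd = 1,
               capillary_radius_range = c(2, 6), seed = seed)

n_scenes <- 8L
for (s in seq_len(n_scenes)) {
  sc <- generate_image(scene_suite_params(s))
  write_scene(sc, file.path(out, "scenes", sprintf("scene_%02d", s)))
}
cat(sprintf("rendered %d scenes under %s/scenes\n", n_scenes, out))

gp <- default_group_params("full-cohort")
cohort <- generate_cohort_features(gp$pe, gp$ctrl, seed = 1)
write.csv(cohort, file.path(out, "cohort_full.csv"), row.names = FALSE)

sub <- default_group_params("gestation-matched")
cohort_sub <- generate_cohort_features(sub$pe, sub$ctrl, seed = 1)
write.csv(cohort_sub, file.path(out, "cohort_subgroup.csv"), row.names = FALSE)

cat(sprintf("cohorts: %d subjects (full), %d subjects (subgroup)\n",
            nrow(cohort), nrow(cohort_sub)))
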