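#!/usr/bin/env Rscript
# Region-of-interest statistics: code speaking/listening periods (30 s crop,
# 20 s interruption rule), compute proportional face and upper-face fixation
# time per condition cell, and run the statistical battery: 2 (Group) x 2
# (Speech) x 2 (Task) mixed ANOVA per dependent variable, Shapiro-Wilk
# screens, exact nonparametric follow-ups, and AQ/LSAS trait analyses.

library(dyadscan)
library(dplyr)

cfg <- analysis_config()
labeled <- read.csv("scratch/cohort/labeled_fixations.csv")
gaze <- read_gaze_table("scratch/cohort/gaze.csv")
speech <- read_speech_table("scratch/cohort/speech.csv")
traits <- read_trait_table("scratch/cohort/traits.csv")

periods <- code_speech_table(speech, cfg)
outcomes <- compute_proportions(labeled, periods, gaze, cfg) |>
  left_join(traits[, c("participant", "group")], by = "participant")
write_dyad_table(outcomes, "results/roi_outcomes.csv")

cat("Median face fixation time (%) by condition:\n")
tab1 <- roi_summary_table(outcomes, "face_prop")
print(as.data.frame(tab1), digits = 3)
write_dyad_table(tab1, "results/face_prop_medians.csv")
tab2 <- roi_summary_table(outcomes, "upper_prop")
write_dyad_table(tab2, "results/upper_prop_medians.csv")

for (dv in c("face_prop", "upper_prop")) {
  an <- mixed_anova_2x2x2(outcomes, dv)
  cat("\nMixed ANOVA on", dv, "(n =", attr(an, "n_included"), "):\n")
  print(as.data.frame(an), digits = 3)
  write_dyad_table(an, paste0("results/anova_", dv, ".csv"))
}

fu <- bind_rows(
  followup_tests(outcomes, "face_prop", "speech"),
  followup_tests(outcomes, "face_prop", "task"),
  followup_tests(outcomes, "face_prop", "group"),
  followup_tests(outcomes, "upper_prop", "group")
)
cat("\nNonparametric follow-ups:\n")
print(as.data.frame(fu), digits = 3)
write_dyad_table(fu, "results/followups.csv")
write_dyad_table(shapiro_screen(outcomes, "face_prop"),
                 "results/shapiro_face_prop.csv")

ta <- trait_analysis(outcomes, traits, cfg)
cat("\nTrait group comparisons:\n")
print(as.data.frame(ta$group_tests), digits = 3)
write_dyad_table(ta$group_tests, "results/trait_group_tests.csv")
write_dyad_table(ta$correlations, "results/trait_correlations.csv")
cat("\nSignificant trait correlations (p < 0.05):\n")
print(as.data.frame(filter(ta$correlations, p < 0.05)), digits = 3)
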