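#!/usr/bin/env Rscript
# Maximum-likelihood cue combination: from each subject's visual and
# haptic fits, predict the optimal bimodal PSE and JND and compare with
# the observed bimodal fits, children vs adults.

suppressMessages(library(tiltprior))

out_dir <- "results/analysis"
fits <- read.csv(file.path(out_dir, "fits.csv"))

pred <- predict_bimodal_table(fits)
write.csv(pred, file.path(out_dir, "bimodal_predictions.csv"),
          row.names = FALSE)
message(nrow(pred), " subjects with converged fits in all three conditions")

cmp <- compare_groups(pred)
write.csv(cmp, file.path(out_dir, "bimodal_comparison.csv"),
          row.names = FALSE)
message("predicted vs observed bimodal estimates:")
print(cmp, digits = 3)

jnd <- cmp[cmp$measure == "jnd", ]
for (i in seq_len(nrow(jnd))) {
  ratio <- jnd$mean_obs[i] / jnd$mean_pred[i]
  message(sprintf(
    "%s: observed/predicted bimodal JND = %.2f %s", jnd$group[i], ratio,
    if (ratio > 1.2) "(worse than optimal: no evidence of integration)"
    else "(consistent with optimal integration)"))
}
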