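#!/usr/bin/env Rscript
# Fit a cumulative-Gaussian psychometric function (fixed lapse 0.02) to
# every subject x condition by maximum likelihood, then summarise bias
# (PSE) and precision (JND) per age group and modality.

suppressMessages(library(tiltprior))

out_dir <- "results/analysis"
trials <- read_trials(file.path(out_dir, "trials.csv"))

fits <- fit_cohort(trials)
message(sum(!fits$converged), " of ", nrow(fits),
        " fits failed to converge and are excluded")
write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)

summ <- summarize_groups(fits)
write.csv(summ, file.path(out_dir, "group_summary.csv"), row.names = FALSE)

message("group-level biases (deg; negative = A-effect, toward body tilt):")
print(summ[, c("condition", "age_group_label", "n", "mean_bias_deg",
               "sem_bias_deg", "mean_jnd_deg")], digits = 3)

# recovery check against the generating truth
truth <- read.csv(file.path(out_dir, "truth.csv"))
m <- merge(fits[fits$converged, ], truth, by = c("subject_id", "condition"))
message("median |fitted - true| PSE: ",
        signif(median(abs(m$pse_deg - m$true_pse_deg)), 3), " deg")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  summ$age_plot <- summ$mean_age_years
  p <- ggplot(summ, aes(age_plot, mean_bias_deg, colour = condition)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_ribbon(aes(ymin = mean_bias_deg - sem_bias_deg,
                    ymax = mean_bias_deg + sem_bias_deg,
                    fill = condition), alpha = 0.2, colour = NA) +
    geom_line() + geom_point() +
    labs(x = "age group mean age (years)", y = "bias (deg)",
         title = "Verticality bias by age and modality",
         subtitle = "negative = A-effect (toward body tilt)") +
    theme_minimal()
  ggsave(file.path(out_dir, "fig_bias_by_age.pdf"), p,
         width = 7, height = 4.5)
  message("wrote ", out_dir, "/fig_bias_by_age.pdf")
}
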