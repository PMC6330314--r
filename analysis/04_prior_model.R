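#!/usr/bin/env Rscript
# Bayesian prior observer model: fit prior placement, prior width and the
# age trend of sensory noise to the visual and haptic group biases by
# exhaustive least-squares grid search, and draw the prior / likelihood /
# posterior triptych at the optimum.

suppressMessages(library(tiltprior))

out_dir <- "results/analysis"
summ <- read.csv(file.path(out_dir, "group_summary.csv"))

fits <- list()
for (mod in c("visual", "haptic")) {
  obs <- summ[summ$condition == mod,
              c("age_group_label", "mean_age_years", "mean_bias_deg")]
  message("fitting prior model to ", mod, " group biases...")
  fit <- fit_prior_model(obs)
  fits[[mod]] <- fit
  print(fit)
  jsonlite::write_json(
    list(policy = fit$policy, sigma_p_deg = fit$sigma_p_deg,
         a0_deg = fit$a0_deg, a1_deg_per_year = fit$a1_deg_per_year,
         epsilon_deg = fit$epsilon_deg, sse = fit$sse,
         r_squared = fit$r_squared, predicted = fit$predicted),
    file.path(out_dir, paste0("prior_fit_", mod, ".json")),
    auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  x <- seq(-200, 20, by = 0.5)
  panels <- do.call(rbind, lapply(c("visual", "haptic"), function(mod) {
    f <- fits[[mod]]
    do.call(rbind, lapply(seq_len(nrow(f$predicted)), function(i) {
      r <- f$predicted[i, ]
      lik <- dnorm(x, -90, r$sigma_b_deg)
      pri <- if (is.na(r$prior_center_deg)) rep(max(lik) * 0.2, length(x))
      else dnorm(x, r$prior_center_deg, f$sigma_p_deg)
      pos <- lik * pri
      data.frame(modality = mod, group = r$age_group_label,
                 x = rep(x, 3),
                 curve = rep(c("prior", "likelihood", "posterior"),
                             each = length(x)),
                 density = c(pri / max(pri), lik / max(lik),
                             pos / max(pos)))
    }))
  }))
  panels$curve <- factor(panels$curve,
                         levels = c("prior", "likelihood", "posterior"))
  p <- ggplot(panels, aes(x, density, colour = group)) +
    geom_vline(xintercept = -90, linetype = 3, colour = "grey40") +
    geom_line(linewidth = 0.3) +
    facet_grid(curve ~ modality) +
    labs(x = "body orientation (deg; -90 = true tilt)",
         y = "normalised density",
         title = "Best-fitting prior observer model") +
    theme_minimal()
  ggsave(file.path(out_dir, "fig_prior_model.pdf"), p,
         width = 8, height = 6)
  message("wrote ", out_dir, "/fig_prior_model.pdf")
}
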