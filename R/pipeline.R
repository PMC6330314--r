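#' Fit every subject-by-condition psychometric function in a trial table
#'
#' @param trials Trial data frame (see [read_trials()]).
#' @param lapse_rate Fixed lapse rate passed to [fit_psychometric()].
#' @param verbose Emit one message per fit with its convergence status.
#' @return Data frame, one row per subject x condition: `subject_id`,
#'   `age_years`, `condition`, `pse_deg`, `jnd_deg`, `converged`,
#'   `log_likelihood`, `n_trials`.
#' @export
fit_cohort <- function(trials, lapse_rate = default_lapse(),
                       verbose = FALSE) {
  validate_trials(trials)
  key <- interaction(trials$subject_id, trials$condition, drop = TRUE)
  rows <- lapply(split(trials, key), function(d) {
    f <- fit_psychometric(d[, c("stimulus_deg", "response")], lapse_rate)
    if (verbose) {
      message(sprintf("fit %s / %s: PSE %.2f, JND %.2f, converged %s",
                      d$subject_id[1], d$condition[1],
                      f$pse_deg, f$jnd_deg, f$converged))
    }
    data.frame(subject_id = d$subject_id[1], age_years = d$age_years[1],
               condition = d$condition[1], pse_deg = f$pse_deg,
               jnd_deg = f$jnd_deg, converged = f$converged,
               log_likelihood = f$log_likelihood, n_trials = f$n_trials)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# derive an age-group label: children by year, adults pooled
age_group_label <- function(age_years, adult_age = 18) {
  ifelse(age_years >= adult_age, "adult",
         as.character(as.integer(round(age_years))))
}

#' Descriptive per-group summaries of psychometric fits
#'
#' Per modality and age group: subject count, mean bias (PSE) and its
#' standard error, mean JND and its standard error, plus a one-sample t
#' statistic of the biases against 0 as a descriptive column. Only
#' converged fits enter; empty groups are dropped with a warning; a group
#' with a single subject reports `NA` standard errors.
#'
#' @param fits Fit table from [fit_cohort()] (needs `converged`).
#' @param adult_age Children/adults split for the group labels.
#' @return Data frame, one row per modality x age group.
#' @export
summarize_groups <- function(fits, adult_age = 18) {
  fits <- fits[fits$converged, , drop = FALSE]
  if (nrow(fits) == 0L) {
    warning("no converged fits to summarise")
    return(NULL)
  }
  if (!"group_label" %in% names(fits)) {
    fits$group_label <- age_group_label(fits$age_years, adult_age)
  }
  key <- interaction(fits$condition, fits$group_label, drop = TRUE)
  rows <- lapply(split(fits, key), function(d) {
    n <- nrow(d)
    sem <- function(v) if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
    tstat <- if (n > 1 && stats::sd(d$pse_deg) > 0) {
      unname(stats::t.test(d$pse_deg, mu = 0)$statistic)
    } else if (n > 1) 0 else NA_real_
    data.frame(condition = d$condition[1],
               age_group_label = d$group_label[1],
               mean_age_years = mean(d$age_years), n = n,
               mean_bias_deg = mean(d$pse_deg), sem_bias_deg = sem(d$pse_deg),
               mean_jnd_deg = mean(d$jnd_deg), sem_jnd_deg = sem(d$jnd_deg),
               t_vs_zero = tstat)
  })
  out <- do.call(rbind, rows)
  # stable ordering: modality, then children by age, adults last
  ord <- order(match(out$condition, c("visual", "haptic", "bimodal")),
               out$mean_age_years)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run configuration for the full pipeline
#'
#' Exactly one of `trials` (a trial table or CSV path) or `spec` (a
#' [cohort_spec()] to synthesise) must be given.
#'
#' @param trials Trial data frame or path to a trial CSV.
#' @param spec A [cohort_spec()] for synthetic input.
#' @param grids PSI grids (used when synthesising).
#' @param prior_grids Prior-model search grids.
#' @param prior_policies_searched Subset of [prior_policies()] to search.
#' @param epsilon_deg Rectification floor for the prior model.
#' @param lapse_rate Fixed lapse for fitting.
#' @param out_dir Output directory for the result bundle (NULL = do not
#'   write files).
#' @param seed Integer seed; overrides `spec$seed` when a spec is given.
#' @param verbose Per-fit logging.
#' @return A list of class `run_config`.
#' @export
run_config <- function(trials = NULL, spec = NULL, grids = psi_grids(),
                       prior_grids = prior_search_grids(),
                       prior_policies_searched = prior_policies(),
                       epsilon_deg = 0.1, lapse_rate = default_lapse(),
                       out_dir = NULL, seed = NULL, verbose = FALSE) {
  if (is.null(trials) == is.null(spec)) {
    stop("exactly one of `trials` or `spec` must be supplied")
  }
  if (!is.null(spec) && !is.null(seed)) spec$seed <- as.integer(seed)
  structure(list(trials = trials, spec = spec, grids = grids,
                 prior_grids = prior_grids,
                 prior_policies_searched = prior_policies_searched,
                 epsilon_deg = epsilon_deg,
                 lapse_rate = lapse_rate, out_dir = out_dir,
                 seed = seed, verbose = verbose),
            class = "run_config")
}

#' Run the complete analysis pipeline
#'
#' Synthesises or loads trial data, fits every psychometric function,
#' summarises groups, computes MLE cue-combination predictions and the
#' children-vs-adults comparison, and fits the Bayesian prior model to
#' the visual and haptic group biases. When `out_dir` is set, writes the
#' result bundle: `trials.csv`, `truth.csv` (synthetic runs),
#' `fits.csv`, `group_summary.csv`, `bimodal_predictions.csv`,
#' `bimodal_comparison.csv`, `prior_fit_visual.json`,
#' `prior_fit_haptic.json` and `manifest.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with components `trials`, `truth`, `fits`,
#'   `n_excluded`, `group_summary`, `bimodal_predictions`,
#'   `bimodal_comparison`, `prior_fit_visual`, `prior_fit_haptic`,
#'   `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (!is.null(config$spec)) {
    study <- generate_study(config$spec, config$grids)
    trials <- study$trials
    truth <- study$truth
  } else if (is.character(config$trials)) {
    trials <- read_trials(config$trials)
  } else {
    trials <- config$trials
    validate_trials(trials)
  }

  fits <- fit_cohort(trials, config$lapse_rate, config$verbose)
  n_excluded <- sum(!fits$converged)
  if (n_excluded > 0) {
    message(n_excluded, " non-converged fit(s) excluded from group analysis")
  }
  summary <- summarize_groups(fits)

  predictions <- predict_bimodal_table(fits)
  comparison <- tryCatch(compare_groups(predictions),
                         error = function(e) {
                           warning(conditionMessage(e))
                           NULL
                         })

  prior_fits <- lapply(c(visual = "visual", haptic = "haptic"),
                       function(mod) {
    obs <- summary[summary$condition == mod, , drop = FALSE]
    if (nrow(obs) < 3) return(NULL)
    fit_prior_model(obs[, c("age_group_label", "mean_age_years",
                            "mean_bias_deg")],
                    grids = config$prior_grids,
                    epsilon_deg = config$epsilon_deg,
                    policies = config$prior_policies_searched)
  })

  manifest <- list(
    seed = if (!is.null(config$spec)) config$spec$seed else config$seed,
    lapse_rate = config$lapse_rate,
    epsilon_deg = config$epsilon_deg,
    synthetic = !is.null(config$spec),
    n_subjects = length(unique(trials$subject_id)),
    n_trials = nrow(trials),
    n_fits = nrow(fits),
    n_excluded = n_excluded,
    package_version = as.character(utils::packageVersion("tiltprior")),
    r_version = R.version.string)

  bundle <- list(trials = trials, truth = truth, fits = fits,
                 n_excluded = n_excluded, group_summary = summary,
                 bimodal_predictions = predictions,
                 bimodal_comparison = comparison,
                 prior_fit_visual = prior_fits$visual,
                 prior_fit_haptic = prior_fits$haptic,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

prior_fit_as_list <- function(fit) {
  list(policy = fit$policy, sigma_p_deg = fit$sigma_p_deg,
       a0_deg = fit$a0_deg, a1_deg_per_year = fit$a1_deg_per_year,
       epsilon_deg = fit$epsilon_deg, sse = fit$sse,
       r_squared = fit$r_squared,
       predicted = fit$predicted[, c("age_group_label", "mean_age_years",
                                     "sigma_b_deg", "bias_deg")])
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_trials(bundle$trials, p("trials.csv"))
  if (!is.null(bundle$truth)) {
    utils::write.csv(bundle$truth, p("truth.csv"), row.names = FALSE)
  }
  utils::write.csv(bundle$fits, p("fits.csv"), row.names = FALSE)
  utils::write.csv(bundle$group_summary, p("group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$bimodal_predictions,
                   p("bimodal_predictions.csv"), row.names = FALSE)
  if (!is.null(bundle$bimodal_comparison)) {
    utils::write.csv(bundle$bimodal_comparison,
                     p("bimodal_comparison.csv"), row.names = FALSE)
  }
  for (mod in c("visual", "haptic")) {
    fit <- bundle[[paste0("prior_fit_", mod)]]
    if (!is.null(fit)) {
      jsonlite::write_json(prior_fit_as_list(fit),
                           p(paste0("prior_fit_", mod, ".json")),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           dataframe = "rows")
    }
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
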