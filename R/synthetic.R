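#' Default age-group structure of the emulated study
#'
#' Seven age groups: 6 through 11 year olds and adults, with group sizes
#' 6, 7, 10, 8, 15, 7 and 8 (61 subjects in total). Children in a year
#' group share that nominal age; adult ages are drawn uniformly from 22 to
#' 37 years.
#'
#' @return Data frame with columns `label`, `n_subjects`, `age_min`,
#'   `age_max`.
#' @export
default_groups <- function() {
  data.frame(
    label = c("6", "7", "8", "9", "10", "11", "adult"),
    n_subjects = c(6L, 7L, 10L, 8L, 15L, 7L, 8L),
    age_min = c(6, 7, 8, 9, 10, 11, 22),
    age_max = c(6, 7, 8, 9, 10, 11, 37))
}

#' Specification of a synthetic cohort
#'
#' Describes a full synthetic study: the age-group structure, per-group
#' trial counts (50 per condition for children, 100 for adults), how
#' ground-truth observer parameters are generated, and how the bimodal
#' condition relates to the unimodal ones.
#'
#' Generative modes: `"from_prior_model"` derives each group's true
#' unimodal PSE from the prior observer model ([forward_predict()]) with
#' the supplied visual and haptic configurations, adding Gaussian
#' between-subject scatter; `"explicit_truth"` takes a user-supplied truth
#' table verbatim. Integration modes for the bimodal truth:
#' `"mle_integrator"` applies optimal cue combination to the subject's
#' unimodal truths; `"visual_capture"` copies the visual truth;
#' `"no_integration"` copies the more precise (lower-JND) modality's PSE
#' together with its own JND, i.e. no precision benefit.
#'
#' True JNDs are drawn log-normally around an age-declining median (8
#' degrees at age 6 falling to 3 degrees in adulthood), independently per
#' condition.
#'
#' @param groups Age-group table, see [default_groups()].
#' @param trials_children,trials_adults Trials per condition.
#' @param generative_mode `"from_prior_model"` or `"explicit_truth"`.
#' @param integration_mode `"mle_integrator"`, `"visual_capture"` or
#'   `"no_integration"`.
#' @param inter_subject_bias_sd Between-subject sd of true PSEs (degrees).
#' @param visual_config,haptic_config [prior_config()]s generating the
#'   unimodal group biases (defaults: an upright prior for vision at all
#'   ages, sd 24.7 degrees; an upright-for-children / upside-down-for-
#'   adults prior for touch, sd 28.3 degrees).
#' @param visual_params,haptic_params [likelihood_age_params()] for the
#'   two modalities (defaults: a0 = 5.3, a1 = 0.16 visual; a0 = 0.3,
#'   a1 = -0.16 haptic).
#' @param jnd_sdlog Log-scale sd of the JND sampler.
#' @param lapse Observer lapse rate.
#' @param explicit_truth Truth table for `"explicit_truth"` mode: columns
#'   `subject_id`, `age_years`, `condition`, `true_pse_deg`,
#'   `true_jnd_deg`.
#' @param adult_age Children/adults split for trial counts and priors.
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = default_groups(),
                        trials_children = 50L, trials_adults = 100L,
                        generative_mode = c("from_prior_model",
                                            "explicit_truth"),
                        integration_mode = c("mle_integrator",
                                             "visual_capture",
                                             "no_integration"),
                        inter_subject_bias_sd = 3,
                        visual_config = prior_config("upright_all", 24.7),
                        haptic_config = prior_config(
                          "upright_children_upsidedown_adults", 28.3),
                        visual_params = likelihood_age_params(5.3, 0.16),
                        haptic_params = likelihood_age_params(0.3, -0.16),
                        jnd_sdlog = 0.2, lapse = default_lapse(),
                        explicit_truth = NULL, adult_age = 18,
                        seed = 1L) {
  generative_mode <- match.arg(generative_mode)
  integration_mode <- match.arg(integration_mode)
  stopifnot(all(groups$n_subjects >= 1), inter_subject_bias_sd >= 0)
  if (generative_mode == "explicit_truth" && is.null(explicit_truth)) {
    stop("explicit_truth mode requires an explicit_truth table")
  }
  structure(
    list(groups = groups, trials_children = as.integer(trials_children),
         trials_adults = as.integer(trials_adults),
         generative_mode = generative_mode,
         integration_mode = integration_mode,
         inter_subject_bias_sd = inter_subject_bias_sd,
         visual_config = visual_config, haptic_config = haptic_config,
         visual_params = visual_params, haptic_params = haptic_params,
         jnd_sdlog = jnd_sdlog, lapse = lapse,
         explicit_truth = explicit_truth, adult_age = adult_age,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# median true JND declines with age: 8 deg at 6 y.o. to 3 deg by adulthood
.jnd_median <- function(age_years) pmin(8, pmax(3, 8 - 0.25 * (age_years - 6)))

#' Ground-truth observer parameters for a synthetic cohort
#'
#' Samples the cohort (ages per group) and each subject's true PSE and JND
#' in every condition, according to the spec's generative and integration
#' modes. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `subject_id`, `age_years`,
#'   `group_label`, `condition`, `true_pse_deg`, `true_jnd_deg`.
#' @export
make_truth <- function(spec) {
  set.seed(spec$seed)
  g <- spec$groups
  ages <- unlist(lapply(seq_len(nrow(g)), function(i) {
    if (g$age_min[i] == g$age_max[i]) rep(g$age_min[i], g$n_subjects[i])
    else stats::runif(g$n_subjects[i], g$age_min[i], g$age_max[i])
  }))
  labels <- rep(g$label, g$n_subjects)
  ids <- sprintf("g%s_s%02d", labels,
                 unlist(lapply(g$n_subjects, seq_len)))

  if (spec$generative_mode == "explicit_truth") {
    tt <- spec$explicit_truth
    validate_truth(tt)
    return(tt)
  }

  group_ages <- tapply(ages, labels, mean)
  age_tab <- data.frame(age_group_label = names(group_ages),
                        mean_age_years = as.numeric(group_ages))
  vis <- forward_predict(spec$visual_config, spec$visual_params, age_tab,
                         adult_age = spec$adult_age)
  hap <- forward_predict(spec$haptic_config, spec$haptic_params, age_tab,
                         adult_age = spec$adult_age)
  vis_mu <- vis$bias_deg[match(labels, vis$age_group_label)]
  hap_mu <- hap$bias_deg[match(labels, hap$age_group_label)]

  n <- length(ids)
  pse_v <- vis_mu + stats::rnorm(n, 0, spec$inter_subject_bias_sd)
  pse_h <- hap_mu + stats::rnorm(n, 0, spec$inter_subject_bias_sd)
  jnd_v <- stats::rlnorm(n, log(.jnd_median(ages)), spec$jnd_sdlog)
  jnd_h <- stats::rlnorm(n, log(.jnd_median(ages)), spec$jnd_sdlog)

  bim <- switch(
    spec$integration_mode,
    mle_integrator = {
      w <- (1 / jnd_v^2) / (1 / jnd_v^2 + 1 / jnd_h^2)
      list(pse = w * pse_v + (1 - w) * pse_h,
           jnd = predict_bimodal_sigma(jnd_v, jnd_h))
    },
    visual_capture = list(pse = pse_v, jnd = jnd_v),
    no_integration = {
      vb <- jnd_v <= jnd_h
      list(pse = ifelse(vb, pse_v, pse_h), jnd = pmin(jnd_v, jnd_h))
    })

  out <- data.frame(
    subject_id = rep(ids, 3),
    age_years = rep(ages, 3),
    group_label = rep(labels, 3),
    condition = rep(c("visual", "haptic", "bimodal"), each = n),
    true_pse_deg = c(pse_v, pse_h, bim$pse),
    true_jnd_deg = c(jnd_v, jnd_h, bim$jnd))
  out[order(match(out$subject_id, ids),
            match(out$condition, c("visual", "haptic", "bimodal"))), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

validate_truth <- function(tt) {
  need <- c("subject_id", "age_years", "condition", "true_pse_deg",
            "true_jnd_deg")
  miss <- setdiff(need, names(tt))
  if (length(miss)) stop("truth table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tt$true_jnd_deg <= 0)) stop("truth table has non-positive JND")
  invisible(tt)
}

#' Generate a full synthetic study
#'
#' Draws the ground truth with [make_truth()] and then runs one PSI-driven
#' 2AFC session per subject and condition (50 trials per condition for
#' children, 100 for adults), producing trial-level records in the
#' package's trial CSV dialect plus the truth table for recovery checks.
#' Byte-identical output under a fixed `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param grids PSI grids, see [psi_grids()].
#' @return List with elements `trials` (subject_id, age_years, condition,
#'   stimulus_deg, response) and `truth` (see [make_truth()]).
#' @export
generate_study <- function(spec, grids = psi_grids()) {
  truth <- make_truth(spec)     # seeds the RNG; sessions continue the stream
  psi_tables <- init_psi(grids, spec$lapse)
  subjects <- unique(truth[, c("subject_id", "age_years")])
  pieces <- vector("list", nrow(subjects) * 3L)
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    age <- subjects$age_years[i]
    n_tr <- if (age < spec$adult_age) spec$trials_children
    else spec$trials_adults
    for (cond in c("visual", "haptic", "bimodal")) {
      row <- truth[truth$subject_id == sid & truth$condition == cond, ]
      if (nrow(row) == 0L) next
      obs <- simulated_observer(row$true_pse_deg, row$true_jnd_deg,
                                spec$lapse)
      ses <- run_session(obs, n_tr, grids = grids, lapse_rate = spec$lapse,
                         state = psi_tables)
      k <- k + 1L
      pieces[[k]] <- data.frame(
        subject_id = sid, age_years = age, condition = cond,
        stimulus_deg = ses$stimulus_deg, response = ses$response)
    }
  }
  trials <- do.call(rbind, pieces[seq_len(k)])
  rownames(trials) <- NULL
  list(trials = trials, truth = truth)
}
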