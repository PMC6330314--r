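# shared fixtures for the test suite; everything is generated in code

# coarse PSI grids for fast exhaustive-oracle checks
small_grids <- function() {
  psi_grids(alpha = seq(-10, 10, by = 2),
            sigma = c(2, 4, 8),
            stimulus = seq(-15, 15, by = 3))
}

# trials with uniformly placed stimuli from a known observer
uniform_trials <- function(n, pse, jnd, lapse = default_lapse(),
                           range = c(-45, 45)) {
  x <- stats::runif(n, range[1], range[2])
  data.frame(stimulus_deg = x,
             response = stats::rbinom(n, 1, pf_eval(x, pse, jnd, lapse)))
}

# independent oracle: expected posterior entropy by direct summation,
# written without the package's matrix shortcuts
naive_expected_entropy <- function(state) {
  p <- state$posterior
  sapply(seq_along(state$stimulus_grid), function(j) {
    lik1 <- pf_eval(state$stimulus_grid[j], state$theta_alpha,
                    state$theta_sigma, state$lapse_rate)
    eh <- 0
    for (resp in c(1, 0)) {
      lik <- if (resp == 1) lik1 else 1 - lik1
      q <- p * lik
      z <- sum(q)
      q <- q / z
      h <- -sum(ifelse(q > 0, q * log(q), 0))
      eh <- eh + z * h
    }
    eh
  })
}

# a compact three-group cohort for pipeline tests (two child years + adults)
small_cohort_spec <- function(seed = 11, ...) {
  groups <- data.frame(label = c("6", "10", "adult"),
                       n_subjects = c(3L, 3L, 3L),
                       age_min = c(6, 10, 22), age_max = c(6, 10, 37))
  cohort_spec(groups = groups, seed = seed, ...)
}

# coarse prior-model search grids, for pipeline plumbing tests where the
# exact optimum does not matter
small_prior_grids <- function() {
  list(sigma_p = seq(1, 60, by = 3), a0 = seq(-5, 15, by = 1),
       a1 = seq(-0.5, 0.5, by = 0.1))
}

# age structure matching the emulated study's seven groups
study_ages <- function() c(6, 7, 8, 9, 10, 11, 29.5)

# paper-style best-fit configurations used in sign-pattern checks
visual_bestfit <- function() {
  list(config = prior_config("upright_all", 24.7),
       params = likelihood_age_params(5.3, 0.16))
}
haptic_bestfit <- function() {
  list(config = prior_config("upright_children_upsidedown_adults", 28.3),
       params = likelihood_age_params(0.3, -0.16))
}
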