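#' Parameter and stimulus grids for the PSI procedure
#'
#' Defaults: candidate PSEs from -40 to 40 degrees in 1-degree steps;
#' candidate JNDs log-spaced, 25 points from 0.5 to 30 degrees; candidate
#' stimuli from -45 to 45 degrees in 1.5-degree steps (the stimulus range
#' of the task). The alpha grid is symmetric about 0 so that, combined
#' with the smallest-|alpha| tie-break, the initial PSE estimate is 0.
#'
#' @param alpha Ordered numeric vector of candidate PSE values (degrees).
#' @param sigma Ordered positive vector of candidate JND values (degrees).
#' @param stimulus Ordered numeric vector of candidate stimuli, within
#'   \[-45, 45\] degrees.
#' @return A list with components `alpha`, `sigma`, `stimulus`.
#' @export
psi_grids <- function(alpha = seq(-40, 40, by = 1),
                      sigma = exp(seq(log(0.5), log(30), length.out = 25)),
                      stimulus = seq(-45, 45, by = 1.5)) {
  stopifnot(length(alpha) >= 1, length(sigma) >= 1, length(stimulus) >= 1)
  stopifnot(all(sigma > 0))
  stopifnot(all(stimulus >= -45), all(stimulus <= 45))
  list(alpha = as.numeric(alpha), sigma = as.numeric(sigma),
       stimulus = as.numeric(stimulus))
}

#' Initialise a PSI state
#'
#' Builds the joint (PSE, JND) grid with a uniform starting posterior and
#' precomputes the response-likelihood tables used by stimulus selection.
#' The likelihood tables store, for every parameter pair and candidate
#' stimulus, the probability of each response under [pf_eval()] with the
#' package's fixed lapse, plus the corresponding p*log(p) terms, so that
#' each trial's expected-entropy sweep reduces to a handful of
#' matrix-vector products.
#'
#' @param grids A grid specification from [psi_grids()].
#' @param lapse_rate Lapse rate of the internal observer model.
#' @return An object of class `psi_state`.
#' @export
init_psi <- function(grids = psi_grids(), lapse_rate = default_lapse()) {
  theta <- expand.grid(alpha = grids$alpha, sigma = grids$sigma,
                       KEEP.OUT.ATTRS = FALSE)
  nt <- nrow(theta)
  # L[theta, x] = P(response = 1 | x, theta)
  D <- outer(-theta$alpha, grids$stimulus, "+") / theta$sigma
  L <- lapse_rate / 2 + (1 - lapse_rate) * stats::pnorm(D)
  L0 <- 1 - L
  structure(
    list(alpha_grid = grids$alpha, sigma_grid = grids$sigma,
         stimulus_grid = grids$stimulus,
         theta_alpha = theta$alpha, theta_sigma = theta$sigma,
         posterior = rep(1 / nt, nt), trial_count = 0L,
         lapse_rate = lapse_rate,
         L = L, L0 = L0, LlogL = L * log(L), L0logL0 = L0 * log(L0)),
    class = "psi_state"
  )
}

# fresh uniform posterior over an already-built state (tables are reused)
reset_psi <- function(state) {
  state$posterior <- rep(1 / length(state$posterior),
                         length(state$posterior))
  state$trial_count <- 0L
  state
}

#' @export
print.psi_state <- function(x, ...) {
  est <- psi_estimate(x)
  cat(sprintf(
    "PSI state: %d trials, %d x %d parameter grid, %d stimuli\n",
    x$trial_count, length(x$alpha_grid), length(x$sigma_grid),
    length(x$stimulus_grid)))
  cat(sprintf("  posterior mode: PSE %.1f deg, JND %.2f deg\n",
              est["pse_deg"], est["jnd_deg"]))
  invisible(x)
}

# deterministic tie-break used throughout: smallest absolute value first,
# negative before positive
.tie_break_order <- function(values) order(abs(values), values)

#' Posterior-mode parameter estimate from a PSI state
#'
#' The marginal posterior mode for the PSE and JND, with ties broken by
#' smallest absolute value (negative first). On the fresh uniform
#' posterior this returns a PSE of 0, the procedure's initial estimate.
#'
#' @param state A `psi_state`.
#' @return Named numeric vector `c(pse_deg =, jnd_deg =)`.
#' @export
psi_estimate <- function(state) {
  pm <- matrix(state$posterior, nrow = length(state$alpha_grid))
  amarg <- rowSums(pm)
  smarg <- colSums(pm)
  pick <- function(marg, grid) {
    cand <- which(marg >= max(marg) - 1e-15)
    grid[cand[.tie_break_order(grid[cand])[1]]]
  }
  c(pse_deg = pick(amarg, state$alpha_grid),
    jnd_deg = pick(smarg, state$sigma_grid))
}

#' Expected posterior entropy for every candidate stimulus
#'
#' For each stimulus x, the Shannon entropy of the posterior that would
#' result from each response, averaged over the two responses weighted by
#' their posterior-predictive probabilities. Stimulus selection minimises
#' this quantity.
#'
#' @param state A `psi_state`.
#' @return Numeric vector over `state$stimulus_grid`.
#' @export
psi_expected_entropy <- function(state) {
  p <- state$posterior
  plogp <- p * log(p)
  plogp[p <= 0] <- 0
  # sum_theta q log q for the unnormalised posterior q = p * L[, x]:
  # split into  t(L) (p log p)  +  t(L log L) p
  s1 <- drop(crossprod(state$L, p))              # predictive P(r = 1 | x)
  e1 <- drop(crossprod(state$L, plogp)) + drop(crossprod(state$LlogL, p))
  s0 <- 1 - s1
  e0 <- drop(crossprod(state$L0, plogp)) + drop(crossprod(state$L0logL0, p))
  H1 <- ifelse(s1 > 0, log(s1) - e1 / s1, 0)
  H0 <- ifelse(s0 > 0, log(s0) - e0 / s0, 0)
  s1 * H1 + s0 * H0
}

#' Select the next PSI stimulus
#'
#' Returns the candidate stimulus minimising the expected posterior
#' entropy over both psychometric parameters. Ties are broken
#' deterministically by smallest absolute orientation, negative first.
#'
#' @param state A `psi_state`.
#' @return A single stimulus orientation in degrees.
#' @export
select_stimulus <- function(state) {
  eh <- psi_expected_entropy(state)
  cand <- which(eh <= min(eh) + 1e-12)
  state$stimulus_grid[cand[.tie_break_order(state$stimulus_grid[cand])[1]]]
}

#' Bayesian posterior update after one trial
#'
#' Multiplies the current posterior by the Bernoulli likelihood of the
#' observed response under [pf_eval()] (evaluated at the exact stimulus,
#' not snapped to the selection grid) and renormalises.
#'
#' @param state A `psi_state`.
#' @param stimulus_deg Presented stimulus, within \[-45, 45\] degrees.
#' @param response Observed response, 0 or 1.
#' @return The updated `psi_state`.
#' @export
update_posterior <- function(state, stimulus_deg, response) {
  stopifnot(stimulus_deg >= -45, stimulus_deg <= 45)
  stopifnot(response %in% c(0, 1))
  lik <- pf_eval(stimulus_deg, state$theta_alpha, state$theta_sigma,
                 state$lapse_rate)
  if (response == 0) lik <- 1 - lik
  post <- state$posterior * lik
  z <- sum(post)
  if (!is.finite(z) || z <= 0) {
    stop("posterior mass vanished updating on stimulus ", stimulus_deg,
         ", response ", response, " (likelihood numerically zero)")
  }
  state$posterior <- post / z
  state$trial_count <- state$trial_count + 1L
  state
}

#' Simulated 2AFC observer
#'
#' Returns a function mapping a stimulus orientation to a Bernoulli
#' response drawn from [pf_eval()] with the given true parameters. Used to
#' drive simulated PSI sessions.
#'
#' @param pse_deg,jnd_deg True observer parameters (degrees).
#' @param lapse_rate True lapse rate.
#' @return A function `stimulus_deg -> 0/1`.
#' @export
simulated_observer <- function(pse_deg, jnd_deg,
                               lapse_rate = default_lapse()) {
  force(pse_deg); force(jnd_deg); force(lapse_rate)
  function(stimulus_deg) {
    stats::rbinom(1L, 1L, pf_eval(stimulus_deg, pse_deg, jnd_deg, lapse_rate))
  }
}

#' Run a PSI-driven 2AFC session
#'
#' Alternates [select_stimulus()], the observer, and [update_posterior()]
#' for `n_trials` trials. With a fixed `seed` and a deterministic observer
#' RNG the stimulus sequence is reproducible.
#'
#' @param observer A function `stimulus_deg -> 0/1` (see
#'   [simulated_observer()]).
#' @param n_trials Number of trials (50 for children, 100 for adults in the
#'   study design this emulates).
#' @param grids PSI grids, see [psi_grids()].
#' @param seed Optional integer seed set before the first trial.
#' @param lapse_rate Lapse of the internal observer model.
#' @param state Optional prebuilt `psi_state` whose likelihood tables are
#'   reused (its posterior is reset); saves rebuilding the tables when
#'   running many sessions over the same grids.
#' @return A data frame with columns `trial`, `stimulus_deg`, `response`;
#'   the final `psi_state` is attached as attribute `"state"`.
#' @export
run_session <- function(observer, n_trials, grids = psi_grids(),
                        seed = NULL, lapse_rate = default_lapse(),
                        state = NULL) {
  stopifnot(is.function(observer), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  state <- if (is.null(state)) init_psi(grids, lapse_rate)
  else reset_psi(state)
  xs <- numeric(n_trials)
  rs <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    x <- select_stimulus(state)
    r <- observer(x)
    if (!r %in% c(0, 1)) stop("observer returned non-binary response")
    state <- update_posterior(state, x, r)
    xs[i] <- x
    rs[i] <- as.integer(r)
  }
  out <- data.frame(trial = seq_len(n_trials), stimulus_deg = xs,
                    response = rs)
  attr(out, "state") <- state
  out
}
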