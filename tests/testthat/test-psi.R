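test_that("init_psi normalises the posterior and starts at a PSE of 0", {
  st <- init_psi()
  expect_equal(sum(st$posterior), 1, tolerance = 1e-12)
  expect_equal(unname(psi_estimate(st)["pse_deg"]), 0)
  expect_error(init_psi(psi_grids(alpha = numeric(0))))
})

test_that("a point-mass posterior gives zero expected entropy everywhere", {
  st <- init_psi(psi_grids(alpha = 0, sigma = 3))
  expect_equal(length(st$posterior), 1L)
  expect_equal(st$posterior, 1)
  eh <- psi_expected_entropy(st)
  expect_true(all(abs(eh) < 1e-12))
  # all stimuli tie; smallest |stimulus| wins
  expect_equal(select_stimulus(st), 0)
})

test_that("select_stimulus minimises expected entropy (exhaustive oracle)", {
  set.seed(405)
  st <- init_psi(small_grids())
  for (i in 1:5) {
    p <- rexp(length(st$posterior))
    st$posterior <- p / sum(p)
    eh_fast <- psi_expected_entropy(st)
    eh_naive <- naive_expected_entropy(st)
    expect_equal(eh_fast, eh_naive, tolerance = 1e-10)
    chosen <- select_stimulus(st)
    expect_lte(eh_naive[match(chosen, st$stimulus_grid)],
               min(eh_naive) + 1e-10)
  }
})

test_that("selection is mirror-symmetric for a symmetric posterior", {
  st <- init_psi(small_grids())
  # alpha-marginal symmetric about 0 by construction (uniform posterior)
  eh <- psi_expected_entropy(st)
  expect_equal(eh, rev(eh), tolerance = 1e-10)
  chosen <- select_stimulus(st)
  mirror <- -chosen
  expect_equal(eh[match(chosen, st$stimulus_grid)],
               eh[match(mirror, st$stimulus_grid)], tolerance = 1e-10)
})

test_that("expected entropy after the chosen stimulus never exceeds the
           current entropy", {
  set.seed(406)
  st <- init_psi(small_grids())
  for (i in 1:10) {
    p <- rexp(length(st$posterior))
    st$posterior <- p / sum(p)
    h_now <- -sum(st$posterior * log(st$posterior))
    expect_lte(min(psi_expected_entropy(st)), h_now + 1e-10)
  }
})

test_that("update_posterior applies Bayes rule and renormalises", {
  st <- init_psi(small_grids())
  s1 <- update_posterior(st, 3, 1)
  expect_equal(sum(s1$posterior), 1, tolerance = 1e-10)
  expect_equal(s1$trial_count, 1L)
  # sequential updates match a single batch product of likelihoods
  s2 <- update_posterior(s1, -6, 0)
  lik1 <- pf_eval(3, st$theta_alpha, st$theta_sigma, st$lapse_rate)
  lik0 <- 1 - pf_eval(-6, st$theta_alpha, st$theta_sigma, st$lapse_rate)
  batch <- st$posterior * lik1 * lik0
  expect_equal(s2$posterior, batch / sum(batch), tolerance = 1e-12)
  expect_error(update_posterior(st, 90, 1))
  expect_error(update_posterior(st, 3, 2))
})

test_that("an 'away' response at a positive stimulus never shifts the PSE
           mode upward", {
  set.seed(407)
  st <- init_psi(small_grids())
  for (i in 1:10) {
    p <- rexp(length(st$posterior))
    st$posterior <- p / sum(p)
    mode_before <- unname(psi_estimate(st)["pse_deg"])
    st2 <- update_posterior(st, 12, 1)
    expect_lte(unname(psi_estimate(st2)["pse_deg"]), mode_before + 1e-12)
  }
})

test_that("run_session is reproducible and respects the stimulus range", {
  obs <- simulated_observer(-6, 4)
  a <- run_session(obs, 50, seed = 21)
  b <- run_session(obs, 50, seed = 21)
  expect_equal(nrow(a), 50)
  expect_identical(a$stimulus_deg, b$stimulus_deg)
  expect_identical(a$response, b$response)
  expect_true(all(a$stimulus_deg >= -45 & a$stimulus_deg <= 45))
  expect_true(all(a$response %in% 0:1))
  expect_equal(attr(a, "state")$trial_count, 50L)
})

test_that("stimulus placements concentrate near the true PSE", {
  set.seed(408)
  gap_first <- gap_last <- numeric(10)
  st <- init_psi()
  for (i in 1:10) {
    ses <- run_session(simulated_observer(-10, 4), 60, state = st)
    gap_first[i] <- median(abs(ses$stimulus_deg[1:10] + 10))
    gap_last[i] <- median(abs(ses$stimulus_deg[51:60] + 10))
  }
  expect_lt(median(gap_last), median(gap_first))
})

test_that("PSI placement is at least as efficient as uniform placement", {
  set.seed(409)
  st <- init_psi()
  err <- replicate(40, {
    pse <- runif(1, -15, 15); jnd <- runif(1, 2, 8)
    ses <- run_session(simulated_observer(pse, jnd), 50, state = st)
    fp <- fit_psychometric(data.frame(stimulus_deg = ses$stimulus_deg,
                                      response = ses$response))
    fu <- fit_psychometric(uniform_trials(50, pse, jnd))
    c(psi = if (fp$converged) abs(fp$pse_deg - pse) else NA,
      unif = if (fu$converged) abs(fu$pse_deg - pse) else NA)
  })
  expect_lte(median(err["psi", ], na.rm = TRUE),
             median(err["unif", ], na.rm = TRUE))
})
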