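# brute-force oracle: argmax of the prior x likelihood product on a fine
# grid (log densities, so narrow far-apart factors cannot underflow)
grid_peak <- function(mu_p, sigma_p, mu_l, sigma_b, step = 0.01) {
  g <- seq(-180, 0, by = step)
  d <- stats::dnorm(g, mu_p, sigma_p, log = TRUE) +
    stats::dnorm(g, mu_l, sigma_b, log = TRUE)
  g[which.max(d)]
}

test_that("the raw likelihood width is linear in age", {
  expect_equal(sigma_age(25, likelihood_age_params(5.3, 0.16)), 9.3)
  expect_equal(sigma_age(6, likelihood_age_params(0.3, -0.16)), -0.66)
  expect_equal(sigma_age(c(6, 40), likelihood_age_params(7, 0)), c(7, 7))
})

test_that("rectification keeps widths positive and preserves ordering", {
  # all positive: shift by epsilon only
  expect_equal(rectify_sigma(c(2, 3, 4), 0.1), c(2.1, 3.1, 4.1))
  expect_equal(rectify_sigma(c(5, 5, 5), 0.1), c(5.1, 5.1, 5.1))
  # negative values: subtract the min; the smallest maps to epsilon
  raw <- sigma_age(c(6, 7, 8, 9, 10, 11, 37), likelihood_age_params(0.3, -0.16))
  out <- rectify_sigma(raw, 0.1)
  expect_true(all(out > 0))
  expect_equal(min(out), 0.1)
  expect_equal(order(out), order(raw))    # decreasing with age preserved
  expect_equal(out[1], raw[1] - min(raw) + 0.1)
})

test_that("posterior_peak matches the analytic Gaussian product", {
  expect_equal(posterior_peak(NA, NA, -90, 9.4), -90)       # flat prior
  expect_equal(posterior_peak(0, 5, -90, 5), -45)           # equal weight
  pk <- posterior_peak(0, 24.7, -90, 9.3 + 0.1)
  expect_equal(pk, grid_peak(0, 24.7, -90, 9.4), tolerance = 0.02)
  expect_equal(pk, -78.61, tolerance = 0.01)
  expect_error(posterior_peak(0, 5, -90, -1))
})

test_that("posterior_peak equals the numerical product argmax over random
           draws", {
  set.seed(412)
  for (i in 1:200) {
    sp <- runif(1, 1, 60); sb <- runif(1, 0.2, 40)
    mp <- sample(c(0, -180), 1)
    pk <- posterior_peak(mp, sp, -90, sb)
    expect_equal(pk, grid_peak(mp, sp, -90, sb), tolerance = 0.02)
  }
})

test_that("predicted_bias maps peaks to the A/E sign convention", {
  expect_equal(predicted_bias(-90), 0)
  expect_equal(predicted_bias(-78.7), -11.3)
  expect_equal(predicted_bias(-100), 10)
  expect_identical(classify_bias(predicted_bias(-78.7)), "A_effect")
  expect_identical(classify_bias(predicted_bias(-100)), "E_effect")
})

test_that("forward_predict handles the limiting priors", {
  ages <- study_ages()
  params <- likelihood_age_params(5.3, 0.16)
  flat <- forward_predict(prior_config("flat_all"), params, ages)
  expect_equal(flat$bias_deg, rep(0, 7))
  # overwhelming prior at upright: full A-effect
  tight <- forward_predict(prior_config("upright_all", 1e-4), params, ages)
  expect_equal(tight$bias_deg, rep(-90, 7), tolerance = 1e-4)
  # vanishing prior influence
  wide <- forward_predict(prior_config("upright_all", 1e5), params, ages)
  expect_true(all(abs(wide$bias_deg) < 1e-4))
})

test_that("prior influence grows with sensory noise and shrinks with prior
           width", {
  sps <- c(5, 10, 20, 40, 80)
  b_sp <- sapply(sps, function(sp)
    predicted_bias(posterior_peak(0, sp, -90, 8)))
  expect_true(all(diff(abs(b_sp)) < 0))
  sbs <- c(2, 4, 8, 16, 32)
  b_sb <- sapply(sbs, function(sb)
    predicted_bias(posterior_peak(0, 25, -90, sb)))
  expect_true(all(diff(abs(b_sb)) > 0))
})

test_that("the paper-style best-fit parameters reproduce the developmental
           sign pattern", {
  ages <- study_ages()
  v <- visual_bestfit()
  vis <- forward_predict(v$config, v$params, ages)
  expect_true(all(vis$bias_deg < 0))                 # A-effect at every age
  h <- haptic_bestfit()
  hap <- forward_predict(h$config, h$params, ages)
  expect_true(all(hap$bias_deg[ages < 18] < 0))      # children toward tilt
  expect_true(all(hap$bias_deg[ages >= 18] > 0))     # adults away from tilt
})

test_that("noiseless grid-point truths are recovered exactly", {
  g <- prior_search_grids()
  ages <- study_ages()
  # identifiable regime: all raw widths positive (visual-style)
  cfg <- prior_config("upright_all", g$sigma_p[80])       # 24.7
  par <- likelihood_age_params(g$a0[104], g$a1[34])       # 5.3, 0.16
  obs <- forward_predict(cfg, par, ages)
  fit <- fit_prior_model(
    data.frame(age_group_label = obs$age_group_label,
               mean_age_years = obs$mean_age_years,
               mean_bias_deg = obs$bias_deg))
  expect_identical(fit$policy, "upright_all")
  expect_identical(fit$sigma_p_deg, g$sigma_p[80])
  expect_identical(fit$a0_deg, g$a0[104])
  expect_identical(fit$a1_deg_per_year, g$a1[34])
  expect_lt(fit$sse, 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$predicted$bias_deg, obs$bias_deg, tolerance = 1e-9)
})

test_that("all-zero observed biases select the flat prior by tie-break", {
  fit <- fit_prior_model(
    data.frame(age_group_label = as.character(study_ages()),
               mean_age_years = study_ages(),
               mean_bias_deg = rep(0, 7)))
  expect_identical(fit$policy, "flat_all")
  expect_equal(fit$sse, 0)
  expect_equal(fit$predicted$bias_deg, rep(0, 7))
})

test_that("r_squared is consistent with sse and the observed spread", {
  set.seed(413)
  obs <- data.frame(age_group_label = as.character(study_ages()),
                    mean_age_years = study_ages(),
                    mean_bias_deg = rnorm(7, -5, 3))
  fit <- fit_prior_model(obs)
  sst <- sum((obs$mean_bias_deg - mean(obs$mean_bias_deg))^2)
  expect_equal(fit$r_squared, 1 - fit$sse / sst, tolerance = 1e-12)
  expect_lte(fit$r_squared, 1)
})

test_that("a restricted policy search honours its constraint", {
  ages <- study_ages()
  h <- haptic_pattern_condition()
  obs <- forward_predict(h$config, h$params, ages)
  fit <- fit_prior_model(
    data.frame(age_group_label = obs$age_group_label,
               mean_age_years = obs$mean_age_years,
               mean_bias_deg = obs$bias_deg),
    policies = "flat_all")
  expect_identical(fit$policy, "flat_all")
  expect_equal(fit$predicted$bias_deg, rep(0, 7))
})
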