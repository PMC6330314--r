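test_that("explicit truth tables pass through unchanged", {
  tt <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                   age_years = rep(c(8, 30), each = 3),
                   condition = rep(c("visual", "haptic", "bimodal"), 2),
                   true_pse_deg = c(-8, -3, -6, -10, 2, -7),
                   true_jnd_deg = c(4, 5, 3, 3, 3.5, 2.5))
  spec <- small_cohort_spec(generative_mode = "explicit_truth",
                            explicit_truth = tt)
  expect_identical(make_truth(spec), tt)
  expect_error(cohort_spec(generative_mode = "explicit_truth"),
               "explicit_truth")
})

test_that("the optimal-integrator bimodal truth follows the fusion rules", {
  spec <- small_cohort_spec(seed = 41)
  tr <- make_truth(spec)
  wide <- reshape(tr[, c("subject_id", "condition", "true_pse_deg",
                         "true_jnd_deg")],
                  idvar = "subject_id", timevar = "condition",
                  direction = "wide")
  w <- (1 / wide$true_jnd_deg.visual^2) /
    (1 / wide$true_jnd_deg.visual^2 + 1 / wide$true_jnd_deg.haptic^2)
  expect_equal(wide$true_pse_deg.bimodal,
               w * wide$true_pse_deg.visual +
                 (1 - w) * wide$true_pse_deg.haptic, tolerance = 1e-12)
  expect_equal(wide$true_jnd_deg.bimodal,
               predict_bimodal_sigma(wide$true_jnd_deg.visual,
                                     wide$true_jnd_deg.haptic),
               tolerance = 1e-12)

  # no integration: the better cue is used as-is, no precision benefit
  tr2 <- make_truth(small_cohort_spec(seed = 41,
                                      integration_mode = "no_integration"))
  w2 <- reshape(tr2[, c("subject_id", "condition", "true_pse_deg",
                        "true_jnd_deg")],
                idvar = "subject_id", timevar = "condition",
                direction = "wide")
  expect_equal(w2$true_jnd_deg.bimodal,
               pmin(w2$true_jnd_deg.visual, w2$true_jnd_deg.haptic))

  # visual capture copies the visual truth
  tr3 <- make_truth(small_cohort_spec(seed = 41,
                                      integration_mode = "visual_capture"))
  w3 <- reshape(tr3[, c("subject_id", "condition", "true_pse_deg",
                        "true_jnd_deg")],
                idvar = "subject_id", timevar = "condition",
                direction = "wide")
  expect_equal(w3$true_pse_deg.bimodal, w3$true_pse_deg.visual)
})

test_that("without subject scatter, group truths equal the prior-model
           forward predictions", {
  spec <- cohort_spec(inter_subject_bias_sd = 0, seed = 42)
  tr <- make_truth(spec)
  hap <- tr[tr$condition == "haptic", ]
  child_means <- tapply(hap$true_pse_deg[hap$age_years < 18],
                        hap$group_label[hap$age_years < 18], mean)
  expect_true(all(child_means < 0))
  expect_true(mean(hap$true_pse_deg[hap$age_years >= 18]) > 0)
  vis <- tr[tr$condition == "visual", ]
  expect_true(all(vis$true_pse_deg < 0))
})

test_that("generate_study is deterministic and follows the design", {
  groups <- data.frame(label = c("7", "adult"), n_subjects = c(1L, 1L),
                       age_min = c(7, 22), age_max = c(7, 37))
  spec <- cohort_spec(groups = groups, seed = 77)
  a <- generate_study(spec)
  b <- generate_study(spec)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)
  counts <- table(a$trials$subject_id, a$trials$condition)
  expect_true(all(counts[grepl("^g7", rownames(counts)), ] == 50))
  expect_true(all(counts[grepl("^gadult", rownames(counts)), ] == 100))
  expect_true(all(a$trials$stimulus_deg >= -45 &
                    a$trials$stimulus_deg <= 45))
})

test_that("the default study has the full cohort and its parameters are
           recovered from the PSI trials", {
  study <- generate_study(cohort_spec(seed = 43))
  expect_equal(length(unique(study$trials$subject_id)), 61)
  expect_equal(sort(unique(study$trials$condition)),
               sort(c("visual", "haptic", "bimodal")))
  n_per <- table(study$trials$subject_id) / 3
  expect_true(all(n_per %in% c(50, 100)))

  fits <- fit_cohort(study$trials)
  merged <- merge(fits, study$truth,
                  by = c("subject_id", "condition"))
  merged <- merged[merged$converged, ]
  err <- abs(merged$pse_deg - merged$true_pse_deg)
  child <- merged$age_years.x < 18
  expect_lte(median(err[child]), 3)     # 50-trial sessions
  expect_lte(median(err[!child]), 2)    # 100-trial sessions
})

test_that("group biases fitted from simulated cohorts recover the
           generating prior policy", {
  h <- haptic_pattern_condition()
  hits <- 0L
  for (s in 1:4) {
    spec <- cohort_spec(haptic_config = h$config, haptic_params = h$params,
                        seed = 500 + s)
    study <- generate_study(spec)
    fits <- fit_cohort(study$trials)
    summ <- summarize_groups(fits)
    hap <- summ[summ$condition == "haptic", ]
    fit <- fit_prior_model(hap[, c("age_group_label", "mean_age_years",
                                   "mean_bias_deg")])
    vis <- summ[summ$condition == "visual", ]
    vfit <- fit_prior_model(vis[, c("age_group_label", "mean_age_years",
                                    "mean_bias_deg")])
    hits <- hits + (fit$policy == "upright_children_upsidedown_adults" &&
                      vfit$policy == "upright_all")
  }
  expect_gte(hits, 3L)
})
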