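#' Maximum-likelihood cue-combination predictions
#'
#' Under optimal (maximum-likelihood) integration of a visual and a haptic
#' estimate with standard deviations `sigma_v` and `sigma_h`, the bimodal
#' estimate has standard deviation
#' `sigma_vh = sqrt(sigma_v^2 * sigma_h^2 / (sigma_v^2 + sigma_h^2))`,
#' which is always below the better unimodal sigma, and the bimodal PSE is
#' the reliability-weighted average of the unimodal PSEs.
#'
#' @param sigma_v,sigma_h Positive unimodal JNDs (degrees).
#' @return `predict_bimodal_sigma()`: the predicted bimodal JND.
#'   `compute_weights()`: named vector `c(w_v =, w_h =)` with
#'   `w_v + w_h = 1`.
#' @examples
#' predict_bimodal_sigma(3, 4)  # 2.4
#' compute_weights(3, 4)        # 0.64, 0.36
#' @export
predict_bimodal_sigma <- function(sigma_v, sigma_h) {
  stopifnot(all(sigma_v > 0), all(sigma_h > 0))
  sqrt(sigma_v^2 * sigma_h^2 / (sigma_v^2 + sigma_h^2))
}

#' @rdname predict_bimodal_sigma
#' @export
compute_weights <- function(sigma_v, sigma_h) {
  stopifnot(all(sigma_v > 0), all(sigma_h > 0))
  wv <- (1 / sigma_v^2) / (1 / sigma_v^2 + 1 / sigma_h^2)
  c(w_v = wv, w_h = 1 - wv)
}

#' Predict the bimodal PSE and JND from a subject's unimodal fits
#'
#' @param visual,haptic Converged [fit_psychometric()] results (or any
#'   lists with `pse_deg`, `jnd_deg`, `converged`) for the same subject.
#' @return A list of class `bimodal_prediction` with `sigma_vh`, `pse_vh`,
#'   `w_v`, `w_h`.
#' @examples
#' v <- list(pse_deg = -10, jnd_deg = 3, converged = TRUE)
#' h <- list(pse_deg = 2, jnd_deg = 4, converged = TRUE)
#' predict_bimodal_pse(v, h)  # pse_vh = -5.68
#' @export
predict_bimodal_pse <- function(visual, haptic) {
  if (!isTRUE(visual$converged) || !isTRUE(haptic$converged)) {
    stop("cannot predict bimodal estimate: a unimodal fit did not converge")
  }
  w <- compute_weights(visual$jnd_deg, haptic$jnd_deg)
  structure(
    list(sigma_vh = predict_bimodal_sigma(visual$jnd_deg, haptic$jnd_deg),
         pse_vh = unname(w["w_v"] * visual$pse_deg +
                           w["w_h"] * haptic$pse_deg),
         w_v = unname(w["w_v"]), w_h = unname(w["w_h"])),
    class = "bimodal_prediction"
  )
}

#' Per-subject bimodal predictions from a fit table
#'
#' Takes the per-subject fit table (one row per subject x condition) and
#' returns one row per subject who has converged fits in all three
#' conditions, with the MLE-predicted bimodal PSE/JND alongside the
#' observed bimodal fit. Subjects with any non-converged fit, or missing
#' a condition, are dropped (as subjects whose fits fail are excluded
#' from group analysis).
#'
#' @param fits Data frame with columns `subject_id`, `age_years`,
#'   `condition`, `pse_deg`, `jnd_deg`, `converged`.
#' @return Data frame with columns `subject_id`, `age_years`, `w_v`, `w_h`,
#'   `pred_pse_deg`, `pred_jnd_deg`, `obs_pse_deg`, `obs_jnd_deg`.
#' @export
predict_bimodal_table <- function(fits) {
  need <- c("subject_id", "age_years", "condition", "pse_deg", "jnd_deg",
            "converged")
  stopifnot(all(need %in% names(fits)))
  out <- lapply(split(fits, fits$subject_id), function(sf) {
    if (!all(c("visual", "haptic", "bimodal") %in% sf$condition)) return(NULL)
    if (!all(sf$converged)) return(NULL)
    v <- sf[sf$condition == "visual", ][1, ]
    h <- sf[sf$condition == "haptic", ][1, ]
    b <- sf[sf$condition == "bimodal", ][1, ]
    pred <- predict_bimodal_pse(
      list(pse_deg = v$pse_deg, jnd_deg = v$jnd_deg, converged = TRUE),
      list(pse_deg = h$pse_deg, jnd_deg = h$jnd_deg, converged = TRUE))
    data.frame(subject_id = v$subject_id, age_years = v$age_years,
               w_v = pred$w_v, w_h = pred$w_h,
               pred_pse_deg = pred$pse_vh, pred_jnd_deg = pred$sigma_vh,
               obs_pse_deg = b$pse_deg, obs_jnd_deg = b$jnd_deg)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Compare predicted and observed bimodal estimates by age group
#'
#' Splits subjects into children (age < `adult_age`) and adults and, per
#' group, summarises predicted vs observed bimodal JND and PSE with paired
#' t statistics (Bonferroni-corrected over the two groups). Descriptive
#' output only: whether predicted precision matches behaviour (evidence of
#' integration) is left to the caller.
#'
#' @param predictions Output of [predict_bimodal_table()].
#' @param adult_age Age cut separating children from adults (default 18;
#'   the cohorts this targets contain 5-13 year olds and >22 year olds).
#' @return Data frame, one row per group x measure (jnd, pse): n, means of
#'   predicted and observed, mean paired difference (observed - predicted),
#'   t statistic, raw and Bonferroni-corrected p.
#' @export
compare_groups <- function(predictions, adult_age = 18) {
  grp <- ifelse(predictions$age_years < adult_age, "children", "adults")
  rows <- list()
  for (g in c("children", "adults")) {
    d <- predictions[grp == g, ]
    if (nrow(d) < 3) {
      stop("fewer than 3 matched subjects in the ", g, " group")
    }
    for (m in c("jnd", "pse")) {
      ob <- d[[paste0("obs_", m, "_deg")]]
      pr <- d[[paste0("pred_", m, "_deg")]]
      tt <- stats::t.test(ob, pr, paired = TRUE)
      rows[[paste(g, m)]] <- data.frame(
        group = g, measure = m, n = nrow(d),
        mean_pred = mean(pr), mean_obs = mean(ob),
        mean_diff = mean(ob - pr),
        t_stat = unname(tt$statistic), p_value = unname(tt$p.value))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # two groups tested per measure
  out$p_bonferroni <- pmin(1, out$p_value * 2)
  out
}
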