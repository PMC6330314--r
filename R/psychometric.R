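#' Cumulative-Gaussian psychometric function with a fixed lapse rate
#'
#' Probability that a 2AFC observer reports the bar as tilted *away* from
#' body tilt (response = 1), as a function of stimulus orientation. The
#' function is a cumulative Gaussian with mean `pse_deg` (the bias: the
#' orientation judged vertical) and standard deviation `jnd_deg` (the
#' precision), compressed symmetrically by a lapse rate so that the
#' asymptotes are `lapse_rate / 2` and `1 - lapse_rate / 2`.
#'
#' @param stimulus_deg Stimulus orientation in degrees. Negative values are
#'   tilted toward the body tilt (body tilted 90 degrees counterclockwise,
#'   left-ear down).
#' @param pse_deg Point of subjective equality in degrees. Negative values
#'   indicate an A-effect (bias toward body tilt).
#' @param jnd_deg Just noticeable difference in degrees; must be positive.
#' @param lapse_rate Lapse probability in `[0, 0.1]`, split equally across
#'   both asymptotes. Default 0.02.
#' @return Probability of responding "away from body tilt", vectorised over
#'   `stimulus_deg`.
#' @examples
#' pf_eval(0, pse_deg = 0, jnd_deg = 3)            # 0.49 with default lapse
#' pf_eval(-12, pse_deg = -12, jnd_deg = 3, lapse_rate = 0)  # exactly 0.5
#' @export
pf_eval <- function(stimulus_deg, pse_deg, jnd_deg, lapse_rate = 0.02) {
  stopifnot(is.numeric(jnd_deg), all(jnd_deg > 0))
  stopifnot(lapse_rate >= 0, lapse_rate <= 0.1)
  lapse_rate / 2 +
    (1 - lapse_rate) * stats::pnorm((stimulus_deg - pse_deg) / jnd_deg)
}

#' Default lapse rate used throughout the package
#'
#' A small fixed lapse (0.02) is assumed both when fitting psychometric
#' functions and inside the PSI procedure's internal observer model. With
#' 50-trial sessions a free lapse parameter is not identifiable, so it is
#' fixed rather than estimated.
#' @return A single number, 0.02.
#' @export
default_lapse <- function() 0.02

# Bounds defining a trustworthy fit; outside them the optimum is treated as
# non-converged (mirrors exclusion of subjects whose fits do not converge).
.JND_MIN <- 0.2
.JND_MAX <- 40
.PSE_MAX <- 45

#' Maximum-likelihood psychometric fit (PSE and JND)
#'
#' Fits a cumulative Gaussian with fixed lapse to trial-level 2AFC data by
#' maximising the Bernoulli log-likelihood under [pf_eval()]. The JND is
#' optimised on a log scale to avoid boundary pathologies. The fit is
#' flagged `converged = FALSE` when the optimiser fails, when either
#' parameter ends up at an implausible extreme (JND outside (0.2, 40)
#' degrees, |PSE| >= 45 degrees), when the Hessian at the optimum is
#' degenerate, or when the data contain only one response class.
#'
#' @param trials A data frame with columns `stimulus_deg` (degrees) and
#'   `response` (0/1), one row per trial; at least 20 trials.
#' @param lapse_rate Fixed lapse rate; see [default_lapse()].
#' @param start Optional numeric start `c(pse, jnd)`; defaults to a
#'   quantile-based guess from the data.
#' @return An object of class `psychometric_fit`: a list with `pse_deg`,
#'   `jnd_deg`, `lapse_rate`, `log_likelihood`, `converged`, `n_trials`.
#' @examples
#' set.seed(1)
#' x <- runif(200, -45, 45)
#' r <- rbinom(200, 1, pf_eval(x, pse_deg = -10, jnd_deg = 4))
#' fit_psychometric(data.frame(stimulus_deg = x, response = r))
#' @export
fit_psychometric <- function(trials, lapse_rate = default_lapse(),
                             start = NULL) {
  stopifnot(is.data.frame(trials),
            all(c("stimulus_deg", "response") %in% names(trials)))
  x <- as.numeric(trials$stimulus_deg)
  r <- as.integer(trials$response)
  n <- length(x)
  if (n < 20) stop("fit_psychometric() needs at least 20 trials, got ", n)
  if (!all(r %in% c(0L, 1L))) stop("responses must be 0 or 1")

  failed <- function(pse = NA_real_, jnd = NA_real_, ll = NA_real_) {
    new_psychometric_fit(pse, jnd, lapse_rate, ll, FALSE, n)
  }
  # one response class: the likelihood has no interior optimum
  if (length(unique(r)) < 2L) return(failed())

  negll <- function(par) {
    p <- pf_eval(x, par[1], exp(par[2]), lapse_rate)
    -sum(r * log(p) + (1 - r) * log1p(-p))
  }

  if (is.null(start)) {
    # crude start: PSE near the response-weighted centre, JND from spread
    ord <- order(x)
    pse0 <- stats::approx(cumsum(r[ord]) / max(1, sum(r)),
                          x[ord], xout = 0.5, ties = "ordered",
                          rule = 2)$y
    if (!is.finite(pse0)) pse0 <- stats::median(x)
    start <- c(pse0, max(2, stats::sd(x) / 4))
  }
  par0 <- c(start[1], log(start[2]))

  opt <- tryCatch(
    stats::optim(par0, negll, method = "Nelder-Mead", hessian = TRUE,
                 control = list(maxit = 1000, reltol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(opt)) return(failed())

  pse <- opt$par[1]
  jnd <- exp(opt$par[2])
  ll <- -opt$value
  ev <- tryCatch(eigen(opt$hessian, symmetric = TRUE,
                       only.values = TRUE)$values,
                 error = function(e) c(NA_real_, NA_real_))
  ok <- opt$convergence == 0 &&
    all(is.finite(ev)) && all(ev > 1e-8) &&
    jnd > .JND_MIN && jnd < .JND_MAX && abs(pse) < .PSE_MAX
  if (!ok) return(failed(pse, jnd, ll))
  new_psychometric_fit(pse, jnd, lapse_rate, ll, TRUE, n)
}

new_psychometric_fit <- function(pse, jnd, lapse, ll, converged, n) {
  structure(
    list(pse_deg = pse, jnd_deg = jnd, lapse_rate = lapse,
         log_likelihood = ll, converged = converged, n_trials = n),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric fit (cumulative Gaussian, lapse ", x$lapse_rate, ")\n",
      sep = "")
  cat(sprintf("  PSE: %.2f deg   JND: %.2f deg   logLik: %.2f\n",
              x$pse_deg, x$jnd_deg, x$log_likelihood))
  cat(sprintf("  n = %d trials, converged: %s\n", x$n_trials, x$converged))
  invisible(x)
}

#' Classify a verticality bias as A-effect, E-effect, or unbiased
#'
#' Negative PSEs indicate perceived vertical tilted toward the body tilt
#' (Aubert or A-effect, undercompensation); positive PSEs indicate biases
#' away from body tilt (E-effect, overcompensation).
#'
#' @param pse_deg Fitted PSE in degrees.
#' @param threshold_deg Nonnegative dead zone; |PSE| <= threshold is called
#'   "unbiased". Default 0.
#' @return One of `"A_effect"`, `"E_effect"`, `"unbiased"` (vectorised).
#' @examples
#' classify_bias(-11.88)       # "A_effect"
#' classify_bias(3, threshold_deg = 5)  # "unbiased"
#' @export
classify_bias <- function(pse_deg, threshold_deg = 0) {
  stopifnot(threshold_deg >= 0)
  ifelse(pse_deg < -threshold_deg, "A_effect",
         ifelse(pse_deg > threshold_deg, "E_effect", "unbiased"))
}

#' Read / write trial-level 2AFC data
#'
#' The trial CSV dialect has one row per trial and the header
#' `subject_id, age_years, condition, stimulus_deg, response`; angles in
#' degrees, comma-separated, UTF-8. `read_trials()` validates ranges
#' (stimuli within \[-45, 45\], responses 0/1, conditions among visual /
#' haptic / bimodal) and reports the offending row on failure.
#'
#' @param path File path.
#' @param trials Data frame of trials to write.
#' @return `read_trials()` returns a validated data frame;
#'   `write_trials()` invisibly returns `path`.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "condition", "stimulus_deg", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_trials(df)
  df
}

validate_trials <- function(df) {
  bad <- which(df$stimulus_deg < -45 | df$stimulus_deg > 45)
  if (length(bad)) stop("stimulus_deg out of [-45, 45] at row ", bad[1])
  bad <- which(!(df$response %in% c(0, 1)))
  if (length(bad)) stop("response not in {0, 1} at row ", bad[1])
  bad <- which(!(df$condition %in% c("visual", "haptic", "bimodal")))
  if (length(bad)) stop("unknown condition at row ", bad[1])
  bad <- which(df$age_years <= 0)
  if (length(bad)) stop("non-positive age_years at row ", bad[1])
  invisible(df)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
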