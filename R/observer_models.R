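# Synthetic observers for the bisection task.
#
# The decision variable is the signed offset of the (combined) perceived
# probe from the perceived midpoint of the interval.  Each modality m
# delivers an internal estimate x_m ~ Normal(o_m - bias_m, sigma_m),
# where o_m is the probe's true offset from that modality's own
# bisection point.  Bimodal estimates are combined according to the
# observer's integration mode; the response is "closer to third" (1)
# iff the combined estimate is positive.  This construction makes the
# psychometric function in nominal probe time an exact cumulative
# Gaussian whose mean and SD map 1:1 onto the generator parameters.

OBSERVER_MODES <- c("MLE", "AUDIO_DOMINANT", "VISUAL_DOMINANT")

#' Define a synthetic observer
#'
#' @param sigma_A audio temporal noise SD in ms (> 0).
#' @param sigma_V visual temporal noise SD in ms (> 0).
#' @param bias_A audio PSE bias in ms (unisensory audio PSE = 500 + bias_A).
#' @param bias_V visual PSE bias in ms.
#' @param lapse stimulus-independent guessing rate in [0, 0.5]; on a
#'   lapse the observer responds by fair coin.
#' @param mode bimodal integration mode: `"MLE"` (reliability-weighted
#'   combination), `"AUDIO_DOMINANT"` or `"VISUAL_DOMINANT"` (single
#'   modality governs bimodal behaviour).
#' @return object of class `observer_params`.
#' @export
observer_params <- function(sigma_A, sigma_V, bias_A = 0, bias_V = 0,
                            lapse = 0.02, mode = "MLE") {
  mode <- match.arg(mode, OBSERVER_MODES)
  if (!is_number(sigma_A) || sigma_A <= 0 || !is_number(sigma_V) || sigma_V <= 0)
    tb_stop("sigma_A and sigma_V must be positive", "invalid_config")
  if (!is_number(lapse) || lapse < 0 || lapse > 0.5)
    tb_stop("lapse must lie in [0, 0.5]", "invalid_config")
  if (!is_number(bias_A) || !is_number(bias_V))
    tb_stop("biases must be finite numbers", "invalid_config")
  structure(list(sigma_A = sigma_A, sigma_V = sigma_V,
                 bias_A = bias_A, bias_V = bias_V,
                 lapse = lapse, mode = mode),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> sigma_A=%g sigma_V=%g bias_A=%g bias_V=%g lapse=%g mode=%s\n",
    x$sigma_A, x$sigma_V, x$bias_A, x$bias_V, x$lapse, x$mode))
  invisible(x)
}

# Effective decision-variable mean and SD as a function of nominal probe
# time, per condition/mode. Returns list(mean, sd) vectorised over probe.
decision_moments <- function(observer, condition, delta, probe) {
  o_A <- probe - (500 - delta)   # offset from audio bisection point
  o_V <- probe - (500 + delta)   # offset from visual bisection point
  if (condition == "A") {
    list(mean = o_A - observer$bias_A, sd = observer$sigma_A)
  } else if (condition == "V") {
    list(mean = o_V - observer$bias_V, sd = observer$sigma_V)
  } else {
    switch(observer$mode,
      MLE = {
        w <- mle_weights(observer$sigma_V, observer$sigma_A)
        list(mean = w[["w_V"]] * (o_V - observer$bias_V) +
                    w[["w_A"]] * (o_A - observer$bias_A),
             sd = mle_threshold(observer$sigma_V, observer$sigma_A))
      },
      AUDIO_DOMINANT = list(mean = o_A - observer$bias_A,
                            sd = observer$sigma_A),
      VISUAL_DOMINANT = list(mean = o_V - observer$bias_V,
                             sd = observer$sigma_V))
  }
}

#' Analytic response curve of a synthetic observer
#'
#' Probability of responding "closer to third" as a function of nominal
#' probe time: `lapse/2 + (1 - lapse) * pnorm((probe - mu)/sigma_eff)`
#' with `mu` and `sigma_eff` the effective decision mean and SD for the
#' condition and integration mode.
#'
#' @param observer an [observer_params()].
#' @param condition one of [CONDITIONS].
#' @param probe numeric vector of nominal probe times, ms.
#' @param delta conflict Delta (defaults to the condition's level).
#' @return numeric vector of probabilities.
#' @export
response_probability <- function(observer, condition, probe,
                                 delta = condition_delta(condition)) {
  condition <- match.arg(condition, CONDITIONS)
  m <- decision_moments(observer, condition, delta, probe)
  observer$lapse / 2 +
    (1 - observer$lapse) * stats::pnorm(m$mean / m$sd)
}

# Vectorised internal-draw simulation for one observer over trial vectors.
# Draw order (audio, visual, lapse, ties) is fixed so that parameters of
# an unused modality do not perturb the used stream under a shared seed.
simulate_responses_vec <- function(observer, condition, delta, probe) {
  n <- length(probe)
  o_A <- probe - (500 - delta)
  o_V <- probe - (500 + delta)
  x_A <- stats::rnorm(n, o_A - observer$bias_A, observer$sigma_A)
  x_V <- stats::rnorm(n, o_V - observer$bias_V, observer$sigma_V)
  x <- numeric(n)
  iA <- condition == "A"
  iV <- condition == "V"
  ib <- !(iA | iV)
  x[iA] <- x_A[iA]
  x[iV] <- x_V[iV]
  if (any(ib)) {
    x[ib] <- switch(observer$mode,
      MLE = {
        w <- mle_weights(observer$sigma_V, observer$sigma_A)
        w[["w_V"]] * x_V[ib] + w[["w_A"]] * x_A[ib]
      },
      AUDIO_DOMINANT = x_A[ib],
      VISUAL_DOMINANT = x_V[ib])
  }
  r <- as.integer(x > 0)
  tie <- x == 0
  if (any(tie)) r[tie] <- stats::rbinom(sum(tie), 1, 0.5)
  if (observer$lapse > 0) {
    lap <- stats::runif(n) < observer$lapse
    if (any(lap)) r[lap] <- stats::rbinom(sum(lap), 1, 0.5)
  }
  r
}

#' Simulate one binary bisection response
#'
#' With probability `lapse` the observer guesses by fair coin; otherwise
#' per-modality internal estimates are drawn, combined per the
#' integration mode, and the response is 1 ("second closer to third")
#' iff the combined estimate is positive (exact ties: fair coin).
#'
#' @param observer an [observer_params()].
#' @param trial a [build_trial()] object.
#' @param seed optional RNG seed.
#' @return integer 0/1.
#' @export
simulate_response <- function(observer, trial, seed = NULL) {
  stopifnot(inherits(observer, "observer_params"))
  if (!inherits(trial, "bisection_trial"))
    tb_stop("trial must be a bisection_trial", "invalid_input")
  with_seed(seed,
    simulate_responses_vec(observer, trial$condition, trial$delta,
                           trial$probe_nominal))
}

#' Simulate responses for a whole session
#'
#' @param observer an [observer_params()].
#' @param session data frame of trial slots ([build_session()] dialect:
#'   columns `condition`, `delta_ms`, `probe_nominal_ms`, `is_easy`).
#' @param seed optional RNG seed; fixed seed gives identical records.
#' @param subject_id optional id stored in the output.
#' @return the session data frame with a `response` column (and
#'   `subject_id` if given) — one trial record per slot.
#' @export
simulate_dataset <- function(observer, session, seed = NULL,
                             subject_id = NULL) {
  stopifnot(inherits(observer, "observer_params"), is.data.frame(session))
  out <- session
  out$response <- integer(nrow(session))
  if (nrow(session)) {
    out$response <- with_seed(seed, {
      r <- integer(nrow(session))
      for (cond in unique(session$condition)) {
        i <- which(session$condition == cond)
        r[i] <- simulate_responses_vec(observer, cond,
                                       session$delta_ms[i],
                                       session$probe_nominal_ms[i])
      }
      r
    })
  }
  if (!is.null(subject_id))
    out <- cbind(subject_id = subject_id, out, stringsAsFactors = FALSE)
  out
}

#' Cohort specification
#'
#' Population distributions for observer parameters: log-normal for the
#' noise SDs, normal for the PSE biases; lapse and integration mode are
#' shared across the cohort.
#'
#' @param label group label (e.g. `"typical"`).
#' @param n_subjects number of observers to draw (>= 1).
#' @param sigma_A_meanlog,sigma_A_sdlog log-normal parameters of sigma_A.
#' @param sigma_V_meanlog,sigma_V_sdlog log-normal parameters of sigma_V.
#' @param bias_mean,bias_sd normal parameters shared by bias_A and bias_V.
#' @param lapse,mode passed to every observer.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(label, n_subjects,
                        sigma_A_meanlog, sigma_A_sdlog,
                        sigma_V_meanlog, sigma_V_sdlog,
                        bias_mean = 0, bias_sd = 0,
                        lapse = 0.02, mode = "MLE") {
  if (!is_number(n_subjects) || n_subjects < 1)
    tb_stop("n_subjects must be >= 1", "invalid_config")
  if (sigma_A_sdlog < 0 || sigma_V_sdlog < 0 || bias_sd < 0)
    tb_stop("scale parameters must be non-negative", "invalid_config")
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 sigma_A_meanlog = sigma_A_meanlog,
                 sigma_A_sdlog = sigma_A_sdlog,
                 sigma_V_meanlog = sigma_V_meanlog,
                 sigma_V_sdlog = sigma_V_sdlog,
                 bias_mean = bias_mean, bias_sd = bias_sd,
                 lapse = lapse, mode = match.arg(mode, OBSERVER_MODES)),
            class = "cohort_spec")
}

#' Default typical-children cohort
#'
#' Audio more precise than vision (median sigma_A = 100 ms < sigma_V =
#' 200 ms), unbiased PSEs near 500 ms, auditory-dominant bimodal
#' behaviour (no precision gain from vision).
#'
#' @param n_subjects cohort size (default 32).
#' @export
typical_cohort_spec <- function(n_subjects = 32) {
  cohort_spec("typical", n_subjects,
              sigma_A_meanlog = log(100), sigma_A_sdlog = 0.25,
              sigma_V_meanlog = log(200), sigma_V_sdlog = 0.25,
              bias_mean = 0, bias_sd = 20,
              lapse = 0.02, mode = "AUDIO_DOMINANT")
}

#' Default dyslexic-children cohort
#'
#' Audio and visual precision equally degraded (median sigma = 300 ms),
#' a +250 ms unisensory PSE bias (population PSE near 750 ms), and
#' reliability-weighted (MLE) bimodal integration.
#'
#' @param n_subjects cohort size (default 32).
#' @export
dyslexic_cohort_spec <- function(n_subjects = 32) {
  cohort_spec("dyslexic", n_subjects,
              sigma_A_meanlog = log(300), sigma_A_sdlog = 0.25,
              sigma_V_meanlog = log(300), sigma_V_sdlog = 0.25,
              bias_mean = 250, bias_sd = 50,
              lapse = 0.02, mode = "MLE")
}

#' Draw a cohort of observers
#'
#' @param spec a [cohort_spec()].
#' @param seed optional RNG seed.
#' @return list of [observer_params()], named `<label>_01`, ... .
#' @export
sample_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n_subjects
    sA <- stats::rlnorm(n, spec$sigma_A_meanlog, spec$sigma_A_sdlog)
    sV <- stats::rlnorm(n, spec$sigma_V_meanlog, spec$sigma_V_sdlog)
    bA <- stats::rnorm(n, spec$bias_mean, spec$bias_sd)
    bV <- stats::rnorm(n, spec$bias_mean, spec$bias_sd)
    obs <- lapply(seq_len(n), function(i)
      observer_params(sigma_A = sA[i], sigma_V = sV[i],
                      bias_A = bA[i], bias_V = bV[i],
                      lapse = spec$lapse, mode = spec$mode))
    names(obs) <- sprintf("%s_%02d", spec$label, seq_len(n))
    obs
  })
}
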