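# QUEST adaptive placement of the probe time.
#
# A discrete posterior over candidate PSE values is maintained in the
# log domain and updated after every trial with the Bernoulli likelihood
# of the response under an assumed fixed-slope cumulative-Gaussian
# psychometric function.  Regular trials are placed at the posterior
# mode plus a Gaussian perturbation (to sample the whole curve); a
# configurable fraction of encouraging "easy" trials is placed within
# easy_margin of an anchor.  The QUEST readout is only used for
# placement: final estimates always come from fitting the full trial
# log (see fit_cumulative_gaussian).

#' QUEST configuration
#'
#' @param prior_mean,prior_sd Gaussian prior over the PSE, ms.
#' @param assumed_sigma assumed (fixed) psychometric slope, ms.
#' @param assumed_lapse assumed lapse rate of the likelihood.
#' @param perturbation_sd SD of the Gaussian perturbation added to the
#'   posterior mode when placing a regular trial, ms.
#' @param grid_step spacing of the candidate-PSE grid over (1, 999) ms.
#' @return list of class `quest_config`.
#' @export
quest_config <- function(prior_mean = 500, prior_sd = 300,
                         assumed_sigma = 150, assumed_lapse = 0.02,
                         perturbation_sd = 100, grid_step = 1) {
  if (!is_number(prior_sd) || prior_sd <= 0)
    tb_stop("prior_sd must be positive", "invalid_config")
  if (!is_number(assumed_sigma) || assumed_sigma <= 0)
    tb_stop("assumed_sigma must be positive", "invalid_config")
  if (!is_number(perturbation_sd) || perturbation_sd < 0)
    tb_stop("perturbation_sd must be non-negative", "invalid_config")
  structure(list(prior_mean = prior_mean, prior_sd = prior_sd,
                 assumed_sigma = assumed_sigma,
                 assumed_lapse = assumed_lapse,
                 perturbation_sd = perturbation_sd,
                 grid_step = grid_step),
            class = "quest_config")
}

#' Initialize a QUEST state
#'
#' @param prior_mean,prior_sd Gaussian prior over the PSE, ms.
#' @param assumed_sigma assumed psychometric slope, ms (> 0).
#' @param assumed_lapse assumed lapse rate.
#' @param perturbation_sd placement perturbation SD, ms.
#' @param grid strictly increasing numeric vector of candidate PSEs, ms.
#' @return object of class `quest_state` with fields `grid`,
#'   `log_posterior`, `assumed_sigma`, `assumed_lapse`,
#'   `perturbation_sd`, `trial_count`.
#' @export
init_quest <- function(prior_mean = 500, prior_sd = 300,
                       assumed_sigma = 150, assumed_lapse = 0.02,
                       perturbation_sd = 100,
                       grid = seq(1, 999, by = 1)) {
  if (!length(grid)) tb_stop("grid must be non-empty", "invalid_config")
  if (is.unsorted(grid, strictly = TRUE))
    tb_stop("grid must be strictly increasing", "invalid_config")
  if (!is_number(prior_sd) || prior_sd <= 0)
    tb_stop("prior_sd must be positive", "invalid_config")
  if (!is_number(assumed_sigma) || assumed_sigma <= 0)
    tb_stop("assumed_sigma must be positive", "invalid_config")
  lp <- stats::dnorm(grid, prior_mean, prior_sd, log = TRUE)
  structure(list(grid = grid, log_posterior = lp - max(lp),
                 assumed_sigma = assumed_sigma,
                 assumed_lapse = assumed_lapse,
                 perturbation_sd = perturbation_sd,
                 trial_count = 0L),
            class = "quest_state")
}

quest_from_config <- function(cfg) {
  init_quest(cfg$prior_mean, cfg$prior_sd, cfg$assumed_sigma,
             cfg$assumed_lapse, cfg$perturbation_sd,
             grid = seq(1, 999, by = cfg$grid_step))
}

#' Posterior mode and mean of a QUEST state
#'
#' @param state a `quest_state`.
#' @return PSE estimate in ms.
#' @export
quest_posterior_mode <- function(state) {
  state$grid[which.max(state$log_posterior)]
}

#' @rdname quest_posterior_mode
#' @export
quest_posterior_mean <- function(state) {
  w <- exp(state$log_posterior - max(state$log_posterior))
  sum(state$grid * w) / sum(w)
}

#' Place the next probe
#'
#' Regular trials: posterior mode plus a `Normal(0, perturbation_sd)`
#' draw, clipped into (1, 999) ms.  Easy trials: uniform within
#' `easy_margin` of a randomly chosen anchor.
#'
#' @param state a `quest_state`.
#' @param easy logical; is this an easy slot?
#' @param easy_margin ms (default 100).
#' @param seed optional RNG seed.
#' @return probe time in ms.
#' @export
quest_next_probe <- function(state, easy = FALSE, easy_margin = 100,
                             seed = NULL) {
  stopifnot(inherits(state, "quest_state"))
  with_seed(seed, {
    if (easy) {
      draw_easy_probe(1, easy_margin)
    } else {
      clamp(quest_posterior_mode(state) +
              stats::rnorm(1, 0, state$perturbation_sd), 1, 999)
    }
  })
}

#' Update a QUEST state with a trial outcome
#'
#' Adds the Bernoulli log-likelihood of the observed response to the
#' log posterior, under
#' `P(1 | probe, PSE) = lapse/2 + (1 - lapse) * pnorm((probe - PSE)/assumed_sigma)`.
#' Arithmetic stays in the log domain (renormalized to max 0), so the
#' posterior remains normalizable after any update sequence.
#'
#' @param state a `quest_state`.
#' @param probe probe time shown, ms.
#' @param response observed response, 0 or 1.
#' @return the updated `quest_state`.
#' @export
quest_update <- function(state, probe, response) {
  stopifnot(inherits(state, "quest_state"))
  if (!is_number(probe)) tb_stop("probe must be a number", "invalid_input")
  if (!(length(response) == 1L && response %in% c(0, 1)))
    tb_stop("response must be 0 or 1", "invalid_input")
  p1 <- state$assumed_lapse / 2 +
    (1 - state$assumed_lapse) *
      stats::pnorm((probe - state$grid) / state$assumed_sigma)
  p1 <- clamp(p1, 1e-12, 1 - 1e-12)
  ll <- if (response == 1) log(p1) else log1p(-p1)
  lp <- state$log_posterior + ll
  state$log_posterior <- lp - max(lp)
  state$trial_count <- state$trial_count + 1L
  state
}

#' Run a full adaptive session on a synthetic observer
#'
#' One independent QUEST routine per condition tracks that condition's
#' PSE.  Each slot of the session is placed by [quest_next_probe()]
#' (easy slots near an anchor, regular slots at the perturbed posterior
#' mode), answered by [simulate_response()]'s vectorised core, and fed
#' back via [quest_update()].
#'
#' @param observer an [observer_params()].
#' @param config a [session_config()] (its `seed` is ignored here).
#' @param quest a [quest_config()].
#' @param seed RNG seed for the whole session (placement, easy draws and
#'   responses); fixed seed gives an identical trial log.
#' @param subject_id optional id column value.
#' @return trial-record data frame (`trial_index`, `condition`,
#'   `delta_ms`, `probe_nominal_ms`, `is_easy`, `response`), with the
#'   final `quest_state` per condition in attribute `"quest_states"`.
#' @export
run_quest_session <- function(observer, config = session_config(),
                              quest = quest_config(), seed = NULL,
                              subject_id = NULL) {
  stopifnot(inherits(observer, "observer_params"),
            inherits(config, "session_config"),
            inherits(quest, "quest_config"))
  with_seed(seed, {
    slots <- build_session(config)
    states <- lapply(unique(slots$condition), function(x) quest_from_config(quest))
    names(states) <- unique(slots$condition)
    probe <- numeric(nrow(slots))
    resp <- integer(nrow(slots))
    for (i in seq_len(nrow(slots))) {
      cond <- slots$condition[i]
      p <- quest_next_probe(states[[cond]], easy = slots$is_easy[i],
                            easy_margin = config$easy_margin)
      r <- simulate_responses_vec(observer, cond, slots$delta_ms[i], p)
      states[[cond]] <- quest_update(states[[cond]], p, r)
      probe[i] <- p
      resp[i] <- r
    }
    slots$probe_nominal_ms <- probe
    slots$response <- resp
    if (!is.null(subject_id))
      slots <- cbind(subject_id = subject_id, slots, stringsAsFactors = FALSE)
    attr(slots, "quest_states") <- states
    slots
  })
}
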