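# Shared fixtures, all built in code.

# A non-adaptive session of n trials for one condition with uniform
# probes over (0, 1000) ms. Caller controls the RNG (set.seed).
uniform_session <- function(n, condition = "A",
                            delta = condition_delta(condition)) {
  data.frame(trial_index = seq_len(n), condition = condition,
             delta_ms = delta,
             probe_nominal_ms = stats::runif(n, 0, 1000),
             is_easy = FALSE, stringsAsFactors = FALSE)
}

# Half-width of a normal-approximation binomial CI for a proportion.
binom_halfwidth <- function(p, n, level = 0.99) {
  stats::qnorm(1 - (1 - level) / 2) * sqrt(p * (1 - p) / n)
}

# Run a single-condition adaptive track: place each probe with QUEST,
# answer from the analytic observer curve, update. Returns the state
# history requested plus the trial log.
quest_track <- function(pse, sigma, n_trials, lapse = 0.02,
                        quest = quest_config(), easy_rate = 0.2,
                        snapshot_at = integer(0)) {
  state <- init_quest(quest$prior_mean, quest$prior_sd, quest$assumed_sigma,
                      quest$assumed_lapse, quest$perturbation_sd,
                      grid = seq(1, 999, by = quest$grid_step))
  probes <- numeric(n_trials)
  resp <- integer(n_trials)
  snaps <- numeric(length(snapshot_at))
  for (i in seq_len(n_trials)) {
    easy <- stats::runif(1) < easy_rate
    p <- quest_next_probe(state, easy = easy)
    pr <- lapse / 2 + (1 - lapse) * stats::pnorm((p - pse) / sigma)
    r <- stats::rbinom(1, 1, pr)
    state <- quest_update(state, p, r)
    probes[i] <- p
    resp[i] <- r
    j <- match(i, snapshot_at)
    if (!is.na(j)) snaps[j] <- quest_posterior_mode(state)
  }
  list(state = state, probes = probes, responses = resp,
       snapshots = snaps)
}
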