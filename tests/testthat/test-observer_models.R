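test_that("a noise-free unbiased observer answers deterministically", {
  obs <- observer_params(sigma_A = 1e-9, sigma_V = 1e-9, lapse = 0)
  tr <- build_trial("A", probe_nominal = 600)
  for (seed in 1:5)
    expect_identical(simulate_response(obs, tr, seed = seed), 1L)
  tr <- build_trial("A", probe_nominal = 400)
  for (seed in 1:5)
    expect_identical(simulate_response(obs, tr, seed = seed), 0L)
})

test_that("a full lapse produces pure guessing", {
  obs <- observer_params(100, 100, lapse = 0.5)
  # lapse = 0.5 is the configuration ceiling; a fully lapsing observer is
  # emulated with sigma so large that the stimulus carries no information
  obs2 <- observer_params(1e9, 1e9, lapse = 0.5)
  set.seed(21)
  s <- uniform_session(10000, "A")
  s$probe_nominal_ms <- rep(950, 10000)  # far from the PSE
  r <- simulate_dataset(obs2, s, seed = 22)$response
  expect_lt(abs(mean(r) - 0.5), binom_halfwidth(0.5, 10000))
})

test_that("equal-reliability conflict averages to no net offset", {
  obs <- observer_params(sigma_A = 150, sigma_V = 150, lapse = 0, mode = "MLE")
  set.seed(31)
  s <- uniform_session(10000, "AV_pos")
  s$probe_nominal_ms <- rep(500, 10000)
  r <- simulate_dataset(obs, s, seed = 32)$response
  expect_lt(abs(mean(r) - 0.5), binom_halfwidth(0.5, 10000))
})

test_that("unisensory response frequencies match the analytic curve", {
  obs <- observer_params(sigma_A = 120, sigma_V = 250,
                         bias_A = 30, bias_V = -40, lapse = 0.1)
  cases <- expand.grid(cond = c("A", "V"), p = c(350, 500, 560, 700),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cond <- cases$cond[i]; p <- cases$p[i]
    sig <- if (cond == "A") obs$sigma_A else obs$sigma_V
    bias <- if (cond == "A") obs$bias_A else obs$bias_V
    expected <- obs$lapse / 2 +
      (1 - obs$lapse) * pnorm((p - (500 + bias)) / sig)
    s <- data.frame(trial_index = 1:10000, condition = cond, delta_ms = 0,
                    probe_nominal_ms = p, is_easy = FALSE)
    r <- simulate_dataset(obs, s, seed = 100 + i)$response
    expect_lt(abs(mean(r) - expected),
              binom_halfwidth(expected, 10000))
    expect_equal(response_probability(obs, cond, p), expected)
  }
})

test_that("MLE bimodal decision noise equals the optimal-combination SD", {
  sV <- 200; sA <- 100
  obs <- observer_params(sigma_A = sA, sigma_V = sV, lapse = 0.02,
                         mode = "MLE")
  # hand-computed oracle, independent of the package formulas
  sVA <- sqrt(sV^2 * sA^2 / (sV^2 + sA^2))
  wV <- sA^2 / (sA^2 + sV^2); wA <- 1 - wV
  for (p in c(420, 500, 590)) {
    for (d in c(-50, 0, 50)) {
      cond <- c("AV_neg", "AV_zero", "AV_pos")[match(d, c(-50, 0, 50))]
      mu <- wV * (p - (500 + d)) + wA * (p - (500 - d))
      expected <- 0.01 + 0.98 * pnorm(mu / sVA)
      s <- data.frame(trial_index = 1:10000, condition = cond, delta_ms = d,
                      probe_nominal_ms = p, is_easy = FALSE)
      r <- simulate_dataset(obs, s, seed = p + d)$response
      expect_lt(abs(mean(r) - expected),
                binom_halfwidth(expected, 10000))
    }
  }
})

test_that("audio-dominant bimodal behaviour is invariant to visual noise", {
  set.seed(41)
  s <- uniform_session(2000, "AV_pos")
  a1 <- observer_params(120, 100, mode = "AUDIO_DOMINANT")
  a2 <- observer_params(120, 900, mode = "AUDIO_DOMINANT")
  expect_identical(simulate_dataset(a1, s, seed = 7)$response,
                   simulate_dataset(a2, s, seed = 7)$response)
})

test_that("dataset simulation is sized, deterministic, and empty-safe", {
  obs <- observer_params(100, 200)
  s <- build_session(session_config(seed = 5))
  d1 <- simulate_dataset(obs, s, seed = 6)
  d2 <- simulate_dataset(obs, s, seed = 6)
  expect_equal(nrow(d1), 150)
  expect_true(all(d1$response %in% 0:1))
  expect_identical(d1, d2)
  empty <- s[0, ]
  expect_equal(nrow(simulate_dataset(obs, empty, seed = 1)), 0)
})

test_that("cohort draws respect the configured population", {
  dy <- sample_cohort(dyslexic_cohort_spec(32), seed = 51)
  expect_length(dy, 32)
  expect_true(all(vapply(dy, function(o) o$sigma_A > 0 && o$sigma_V > 0,
                         logical(1))))
  expect_true(all(vapply(dy, `[[`, character(1), "mode") == "MLE"))

  # degenerate scales collapse onto the location parameters
  spec <- cohort_spec("fixed", 5, log(100), 0, log(200), 0,
                      bias_mean = 10, bias_sd = 0)
  fixed <- sample_cohort(spec, seed = 52)
  expect_true(all(vapply(fixed, function(o)
    isTRUE(all.equal(c(o$sigma_A, o$sigma_V, o$bias_A),
                     c(100, 200, 10))), logical(1))))

  # configured ordering: typical audio more precise than vision
  ty <- sample_cohort(typical_cohort_spec(1000), seed = 53)
  sA <- vapply(ty, `[[`, numeric(1), "sigma_A")
  sV <- vapply(ty, `[[`, numeric(1), "sigma_V")
  expect_lt(median(sA), median(sV))
})

test_that("observer parameter validation rejects bad input", {
  expect_error(observer_params(-1, 100), class = "tempobisect_invalid_config")
  expect_error(observer_params(100, 100, lapse = 0.6),
               class = "tempobisect_invalid_config")
  expect_error(simulate_response(observer_params(100, 100), "not a trial"),
               class = "tempobisect_invalid_input")
})
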