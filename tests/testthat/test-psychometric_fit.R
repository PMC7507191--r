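test_that("separable step data pin the PSE and floor the slope", {
  probes <- setdiff(seq(420, 580, by = 4), 500)
  trials <- data.frame(probe_nominal_ms = probes,
                       response = as.integer(probes > 500))
  fit <- fit_cumulative_gaussian(trials, lapse = 0)
  expect_lt(abs(fit$pse - 500), 1)
  expect_lte(fit$sigma, 1 + 1e-6)  # slope lower bound
})

test_that("generating parameters are recovered within bootstrap error", {
  set.seed(101)
  s <- uniform_session(3000, "A")
  obs <- observer_params(sigma_A = 150, sigma_V = 150, bias_A = 100,
                         lapse = 0.02)  # PSE = 600
  d <- simulate_dataset(obs, s, seed = 102)
  fit <- fit_with_se(d, lapse = 0.02, n_boot = 100, seed = 103)
  expect_lt(abs(fit$pse - 600), 3 * fit$se_pse)
  expect_lt(abs(fit$sigma - 150), 3 * fit$se_sigma)
  expect_true(fit$converged)
})

test_that("shifting all probes shifts the PSE and leaves sigma fixed", {
  set.seed(111)
  s <- uniform_session(400, "A")
  d <- simulate_dataset(observer_params(120, 120), s, seed = 112)
  f0 <- fit_cumulative_gaussian(d)
  d2 <- d
  d2$probe_nominal_ms <- d$probe_nominal_ms + 100
  f1 <- fit_cumulative_gaussian(d2)
  expect_equal(f1$pse, f0$pse + 100, tolerance = 1e-3)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-3)
})

test_that("fitting refuses unidentifiable or undersized data", {
  d <- data.frame(probe_nominal_ms = runif(30, 0, 1000),
                  response = rep(1L, 30))
  expect_error(fit_cumulative_gaussian(d), class = "tempobisect_nonidentifiable")
  d2 <- data.frame(probe_nominal_ms = c(100, 900), response = c(0L, 1L))
  expect_error(fit_cumulative_gaussian(d2),
               class = "tempobisect_insufficient_data")
})

test_that("bootstrap precision improves when trials double", {
  wins <- 0
  se_small <- se_big <- numeric(20)
  for (r in 1:20) {
    set.seed(200 + r)
    obs <- observer_params(150, 150)
    d1 <- simulate_dataset(obs, uniform_session(100, "A"), seed = 300 + r)
    d2 <- simulate_dataset(obs, uniform_session(200, "A"), seed = 400 + r)
    se_small[r] <- bootstrap_se(d1, n_boot = 50, seed = 500 + r)$se_pse
    se_big[r] <- bootstrap_se(d2, n_boot = 50, seed = 600 + r)$se_pse
  }
  expect_lt(median(se_big), median(se_small))
})

test_that("a degenerate resampler yields zero bootstrap variance", {
  set.seed(121)
  d <- simulate_dataset(observer_params(150, 150), uniform_session(80, "A"),
                        seed = 122)
  se <- bootstrap_se(d, n_boot = 20, seed = 123,
                     resample_fun = function(n) seq_len(n))
  expect_equal(se$se_pse, 0)
  expect_equal(se$se_sigma, 0)
  expect_equal(se$n_failed, 0)
})

test_that("an all-failing bootstrap raises an unreliable-SE error", {
  set.seed(131)
  d <- simulate_dataset(observer_params(150, 150), uniform_session(40, "A"),
                        seed = 132)
  i0 <- which(d$response == 0)[1]
  expect_error(
    bootstrap_se(d, n_boot = 20, seed = 133,
                 resample_fun = function(n) rep(i0, n)),
    class = "tempobisect_unreliable_se")
})

test_that("binned proportions conserve counts and respect order", {
  set.seed(141)
  d <- simulate_dataset(observer_params(120, 120),
                        uniform_session(200, "A"), seed = 142)
  for (k in c(2, 5, 8)) {
    b <- binned_proportions(d, n_bins = k)
    expect_equal(sum(b$count), 200)
    expect_true(all(b$proportion >= 0 & b$proportion <= 1))
    expect_false(is.unsorted(b$bin_center))
  }
  d$response <- 1L
  b <- binned_proportions(d, n_bins = 4)
  expect_true(all(b$proportion == 1))

  # step data: proportions monotone nondecreasing, checked by direct count
  probes <- seq(100, 900, length.out = 120)
  step <- data.frame(probe_nominal_ms = probes,
                     response = as.integer(probes > 500))
  bs <- binned_proportions(step, n_bins = 6)
  expect_false(is.unsorted(bs$proportion))
  expect_equal(sum(bs$count * bs$proportion), sum(step$response))
})

test_that("recovery error shrinks when sessions grow tenfold", {
  set.seed(151)
  n_obs <- 40
  err <- array(NA_real_, c(n_obs, 2, 2))  # observer x (pse, sigma) x (30, 300)
  for (i in seq_len(n_obs)) {
    sigma <- runif(1, 50, 400)
    pse <- runif(1, 300, 800)
    for (j in 1:2) {
      n_tr <- c(30, 300)[j]
      tr <- quest_track(pse = pse, sigma = sigma, n_trials = n_tr)
      d <- data.frame(probe_nominal_ms = tr$probes, response = tr$responses)
      f <- tryCatch(fit_cumulative_gaussian(d),
                    tempobisect_error = function(e) NULL)
      if (!is.null(f)) err[i, , j] <- c(abs(f$pse - pse), abs(f$sigma - sigma))
    }
  }
  med30 <- apply(err[, , 1], 2, median, na.rm = TRUE)
  med300 <- apply(err[, , 2], 2, median, na.rm = TRUE)
  expect_true(all(is.finite(med30)) && all(is.finite(med300)))
  expect_lt(med300[1], 0.6 * med30[1])
  expect_lt(med300[2], 0.6 * med30[2])
})
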