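test_that("the clinical table loads with its documented structure", {
  tab <- load_table1()
  expect_equal(nrow(tab), 32)
  dy01 <- tab[tab$code == "DY01", ]
  expect_equal(dy01$age_months, 84.53)
  expect_equal(dy01$decode_time_s, 358)
  expect_equal(dy01$comprehension_time_s, 302)
  expect_equal(sum(is.na(tab$decode_time_s)), 6)
  expect_equal(sum(is.na(tab$comprehension_time_s)), 6)
  expect_equal(sum(is.na(tab$raven_iq)), 1)
  expect_equal(round(mean(tab$age_months) / 12), 10)
})

test_that("a malformed clinical table fails with a located parse error", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- read.csv(system.file("extdata", "table1.csv",
                              package = "tempobisect"),
                  colClasses = "character")
  tab$age_months[3] <- "oops"
  write.csv(tab, path, row.names = FALSE, na = "NA")
  expect_error(load_table1(path), "row 3", class = "tempobisect_parse")
})

test_that("pooling conflict conditions equals fitting their concatenation", {
  obs <- observer_params(150, 150, mode = "MLE")
  set.seed(171)
  s <- do.call(rbind, lapply(BIMODAL_CONDITIONS, function(cc)
    uniform_session(40, cc)))
  d <- simulate_dataset(obs, s, seed = 172)
  pooled <- pooled_bimodal_fit(d, n_boot = 0)
  direct <- fit_cumulative_gaussian(d[d$condition %in% BIMODAL_CONDITIONS, ])
  expect_equal(pooled$pse, direct$pse)
  expect_equal(pooled$sigma, direct$sigma)
  expect_equal(pooled$n_trials, 120)
  expect_equal(pooled$condition, "AV_pooled")
  expect_error(pooled_bimodal_fit(d[d$condition != "AV_neg", ], n_boot = 0),
               class = "tempobisect_invalid_input")
})

test_that("the paired comparison matches the textbook computation", {
  expect_identical(compare_observed_predicted(1:5, 1:5)$t, 0)
  expect_identical(compare_observed_predicted(1:5, 1:5)$d, 0)
  expect_error(compare_observed_predicted(c(1, 2, 3), c(2, 3, 4)),
               class = "tempobisect_degenerate_variance")
  expect_error(compare_observed_predicted(1:4, 1:5),
               class = "tempobisect_invalid_input")

  set.seed(181)
  for (r in 1:5) {
    x <- rnorm(20, 10, 3)
    y <- rnorm(20, 9, 3)
    got <- compare_observed_predicted(x, y)
    oracle <- t.test(x, y, paired = TRUE)
    expect_equal(got$t, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(got$p, oracle$p.value, tolerance = 1e-10)
    expect_equal(got$df, unname(oracle$parameter))
    expect_equal(got$d, mean(x - y) / sd(x - y), tolerance = 1e-12)
  }
})

test_that("correlation handles perfect, missing, and degenerate input", {
  x <- 1:12
  res <- correlate(x, 2 * x + 1, n_boot = 200, n_perm = 500, seed = 1)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$spearman_rho, 1)
  expect_equal(res$r_squared, res$pearson_r^2, tolerance = 1e-12)
  expect_lt(res$p_rho_perm, 0.01)

  set.seed(191)
  xm <- rnorm(20); ym <- xm + rnorm(20)
  xm[c(2, 5, 9)] <- NA
  res <- correlate(xm, ym, n_boot = 200, n_perm = 500, seed = 2)
  expect_equal(res$n, 17)
  expect_equal(res$n_dropped, 3)
  expect_true(res$rho_ci[1] <= res$rho_ci[2])

  expect_error(correlate(rep(1, 10), rnorm(10), n_boot = 50, n_perm = 50),
               class = "tempobisect_undefined_correlation")
  expect_error(correlate(1:3, 1:3), class = "tempobisect_invalid_input")
})

test_that("the permutation test is calibrated under the null", {
  set.seed(201)
  n_rep <- 500
  p <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(32)
    y <- rnorm(32)
    p[r] <- correlate(x, y, n_boot = 20, n_perm = 1000)$p_rho_perm
  }
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("the correlation z-test matches the Fisher formula", {
  eq <- compare_correlations(0.4, 30, 0.4, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  got <- compare_correlations(0.8, 50, 0.2, 50)
  oracle_z <- (atanh(0.8) - atanh(0.2)) / sqrt(1 / 47 + 1 / 47)
  expect_equal(got$z, oracle_z, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(oracle_z)), tolerance = 1e-12)

  swapped <- compare_correlations(0.2, 50, 0.8, 50)
  expect_equal(swapped$z, -got$z)
  expect_equal(swapped$p, got$p)

  # headline-scale check: r = -0.507 vs -0.029 at n = 32 per group gives
  # |z| near 2 under the standard transform
  z <- compare_correlations(-0.507, 32, -0.029, 32)$z
  expect_lt(abs(abs(z) - 2.0), 0.15)

  expect_error(compare_correlations(1, 10, 0.5, 10),
               class = "tempobisect_domain")
  expect_error(compare_correlations(0.5, 3, 0.5, 10),
               class = "tempobisect_invalid_input")
})

make_fits <- function(ids, group, sigma_A, sigma_V) {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    pr <- mle_prediction(sigma_V[i], sigma_A[i])
    data.frame(
      subject_id = ids[i], group = group,
      condition = c("V", "A", "AV_neg", "AV_zero", "AV_pos", "AV_pooled"),
      pse_ms = c(500, 500, 500 + pr$predicted_shift[["-50"]], 500,
                 500 + pr$predicted_shift[["50"]], 500),
      sigma_ms = c(sigma_V[i], sigma_A[i], rep(pr$sigma_VA, 4)),
      se_pse_ms = 5, se_sigma_ms = 5, n_trials = 30, converged = TRUE,
      stringsAsFactors = FALSE)
  }))
}

test_that("identical groups produce identical report cells", {
  sA <- c(100, 150, 120)
  sV <- c(200, 180, 260)
  fits <- rbind(make_fits(c("a1", "a2", "a3"), "g1", sA, sV),
                make_fits(c("b1", "b2", "b3"), "g2", sA, sV))
  preds <- predict_subjects(fits)
  preds$group <- fits$group[match(preds$subject_id, fits$subject_id)]
  rep_ <- group_report(fits, preds)
  for (cond in names(rep_$groups$g1)) {
    expect_equal(rep_$groups$g1[[cond]], rep_$groups$g2[[cond]])
  }
  # fits constructed exactly at the model predictions: paired tests null
  expect_equal(rep_$tests$g1$pooled_sigma_vs_pred$t, 0)
  expect_equal(rep_$tests$g1$shift_pos_vs_pred$t, 0)
})

test_that("mismatched subject ids abort the report with offenders listed", {
  fits <- make_fits(c("a1", "a2", "a3"), "g1", c(100, 110, 120),
                    c(200, 210, 220))
  preds <- predict_subjects(fits)
  preds$subject_id[1] <- "ghost"
  preds$group <- "g1"
  expect_error(group_report(fits, preds), "ghost",
               class = "tempobisect_join")
})

test_that("report serialization writes valid JSON", {
  fits <- make_fits(c("a1", "a2", "a3"), "g1", c(100, 110, 120),
                    c(200, 210, 220))
  preds <- predict_subjects(fits)
  preds$group <- "g1"
  rep_ <- group_report(fits, preds)
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep_, path)
  back <- jsonlite::read_json(path)
  expect_named(back, c("groups", "subjects", "tests", "correlations"))
  expect_equal(back$groups$g1$A$sigma$mean, mean(c(100, 110, 120)))
})
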