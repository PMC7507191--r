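# Maximum-likelihood cumulative-Gaussian psychometric fitting.
#
# The probability of a "closer to third" response is modelled as
#   P(1 | p) = lapse/2 + (1 - lapse) * pnorm((p - pse) / sigma)
# with the lapse rate fixed (not estimated): 30-trial conditions cannot
# identify a free lapse, and lapse = 0 recovers the plain cumulative
# Gaussian.  The fit maximizes the Bernoulli likelihood by a coarse
# grid seed followed by bounded quasi-Newton refinement; standard
# errors come from a case-resampling bootstrap.

SIGMA_LOWER <- 1
SIGMA_UPPER <- 1000

# negative Bernoulli log-likelihood; probabilities clamped for stability
psy_nll <- function(pse, sigma, probe, response, lapse) {
  p1 <- lapse / 2 + (1 - lapse) * stats::pnorm((probe - pse) / sigma)
  p1 <- clamp(p1, 1e-12, 1 - 1e-12)
  -sum(ifelse(response == 1, log(p1), log1p(-p1)))
}

# pull probe/response vectors out of a trial-record data frame
extract_trials <- function(trials) {
  if (is.data.frame(trials)) {
    stopifnot(all(c("probe_nominal_ms", "response") %in% names(trials)))
    list(probe = trials$probe_nominal_ms, response = trials$response)
  } else {
    tb_stop("trials must be a trial-record data frame", "invalid_input")
  }
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood estimates of the point of subjective equality
#' (PSE, the mean) and the discrimination threshold (sigma, the SD)
#' from binary bisection responses.  Two-stage optimization: the best
#' point of a coarse (PSE x log-sigma) grid seeds `stats::optim`
#' (L-BFGS-B) with sigma bounded to [1, 1000] ms.
#'
#' @param trials trial-record data frame with columns
#'   `probe_nominal_ms` and `response` (0/1).
#' @param lapse fixed lapse rate (default 0.02; use 0 for a plain
#'   cumulative Gaussian).
#' @param min_trials minimum number of trials to attempt a fit
#'   (default 10).
#' @param condition optional label stored in the result.
#' @return object of class `psychometric_estimate`: list with `pse`,
#'   `sigma`, `se_pse`, `se_sigma` (NA until [bootstrap_se()] is run),
#'   `n_trials`, `neg_log_likelihood`, `condition`, `converged`,
#'   `lapse`.
#' @export
fit_cumulative_gaussian <- function(trials, lapse = 0.02,
                                    min_trials = 10, condition = NA_character_) {
  tr <- extract_trials(trials)
  probe <- tr$probe
  response <- tr$response
  n <- length(probe)
  if (n < min_trials)
    tb_stop(sprintf("need at least %d trials, got %d", min_trials, n),
            "insufficient_data")
  if (!all(response %in% c(0, 1)))
    tb_stop("responses must be 0/1", "invalid_input")
  if (length(unique(response)) < 2L)
    tb_stop("both response classes must be present (non-identifiable fit)",
            "nonidentifiable")

  # stage 1: coarse grid seed
  rng <- range(probe)
  pse_grid <- seq(rng[1], rng[2], length.out = 31)
  sigma_grid <- exp(seq(log(2), log(600), length.out = 15))
  nll_grid <- outer(pse_grid, sigma_grid,
                    Vectorize(function(m, s) psy_nll(m, s, probe, response, lapse)))
  best <- arrayInd(which.min(nll_grid), dim(nll_grid))
  start <- c(pse_grid[best[1]], sigma_grid[best[2]])

  # stage 2: bounded refinement
  fn <- function(par) psy_nll(par[1], par[2], probe, response, lapse)
  opt <- tryCatch(
    stats::optim(start, fn, method = "L-BFGS-B",
                 lower = c(-1000, SIGMA_LOWER), upper = c(2000, SIGMA_UPPER),
                 control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(opt) || opt$value > fn(start) + 1e-9) {
    nm <- stats::optim(start, fn, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
    nm$par[2] <- clamp(nm$par[2], SIGMA_LOWER, SIGMA_UPPER)
    nm$value <- fn(nm$par)
    opt <- if (is.null(opt) || nm$value < opt$value) nm else opt
  }

  structure(list(pse = opt$par[1], sigma = opt$par[2],
                 se_pse = NA_real_, se_sigma = NA_real_,
                 n_trials = n, neg_log_likelihood = opt$value,
                 condition = condition,
                 converged = identical(opt$convergence, 0L) ||
                             identical(opt$convergence, 0),
                 lapse = lapse),
            class = "psychometric_estimate")
}

#' @export
print.psychometric_estimate <- function(x, ...) {
  cat(sprintf(
    "<psychometric_estimate>%s PSE = %.1f ms (SE %.1f), sigma = %.1f ms (SE %.1f), n = %d\n",
    if (is.na(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$pse, x$se_pse, x$sigma, x$se_sigma, x$n_trials))
  invisible(x)
}

#' Bootstrap standard errors for a psychometric fit
#'
#' Case-resamples the trials `n_boot` times, refits each resample, and
#' reports the standard deviation of the bootstrap estimates as the
#' standard error.  Resamples on which the fit fails (e.g. a single
#' response class) are dropped and counted.
#'
#' @param trials trial-record data frame.
#' @param n_boot bootstrap iterations (default 100).
#' @param lapse fixed lapse rate of the refits.
#' @param seed optional RNG seed.
#' @param resample_fun function(n) returning resample indices; defaults
#'   to case resampling with replacement.  Exposed for degenerate-case
#'   testing.
#' @return list with `se_pse`, `se_sigma`, `n_failed`, `n_used`.
#' @export
bootstrap_se <- function(trials, n_boot = 100, lapse = 0.02, seed = NULL,
                         resample_fun = NULL) {
  tr <- extract_trials(trials)
  n <- length(tr$probe)
  # the full-data fit must succeed before resampling is meaningful
  fit_cumulative_gaussian(trials, lapse = lapse)
  if (is.null(resample_fun))
    resample_fun <- function(n) sample.int(n, n, replace = TRUE)
  with_seed(seed, {
    est <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      idx <- resample_fun(n)
      f <- tryCatch(
        fit_cumulative_gaussian(
          data.frame(probe_nominal_ms = tr$probe[idx],
                     response = tr$response[idx]),
          lapse = lapse),
        tempobisect_error = function(e) NULL)
      if (!is.null(f)) est[b, ] <- c(f$pse, f$sigma)
    }
    ok <- stats::complete.cases(est)
    if (sum(ok) < n_boot / 2)
      tb_stop(sprintf("more than half of %d bootstrap resamples failed to fit",
                      n_boot), "unreliable_se")
    list(se_pse = stats::sd(est[ok, 1]), se_sigma = stats::sd(est[ok, 2]),
         n_failed = n_boot - sum(ok), n_used = sum(ok))
  })
}

#' Fit with bootstrap SEs in one call
#'
#' @inheritParams fit_cumulative_gaussian
#' @inheritParams bootstrap_se
#' @return a `psychometric_estimate` with `se_pse`/`se_sigma` filled in.
#' @export
fit_with_se <- function(trials, lapse = 0.02, n_boot = 100, seed = NULL,
                        condition = NA_character_) {
  fit <- fit_cumulative_gaussian(trials, lapse = lapse, condition = condition)
  if (n_boot > 0) {
    se <- bootstrap_se(trials, n_boot = n_boot, lapse = lapse, seed = seed)
    fit$se_pse <- se$se_pse
    fit$se_sigma <- se$se_sigma
    fit$n_boot_failed <- se$n_failed
  }
  fit
}

#' Binned response proportions
#'
#' Splits trials into `n_bins` equal-count bins by probe time and
#' reports the proportion of "closer to third" responses per bin —
#' the descriptive counterpart of the fitted curve.
#'
#' @param trials trial-record data frame.
#' @param n_bins number of bins (>= 2).
#' @return data frame with `bin_center` (mean probe time in bin),
#'   `proportion`, `count`; counts sum to the number of trials.
#' @export
binned_proportions <- function(trials, n_bins = 8) {
  tr <- extract_trials(trials)
  if (!is_number(n_bins) || n_bins < 2)
    tb_stop("n_bins must be >= 2", "invalid_config")
  ord <- order(tr$probe)
  p <- tr$probe[ord]
  r <- tr$response[ord]
  n <- length(p)
  bin <- ceiling(seq_len(n) / (n / n_bins))
  bin <- clamp(bin, 1, n_bins)
  data.frame(
    bin_center = as.numeric(tapply(p, bin, mean)),
    proportion = as.numeric(tapply(r, bin, mean)),
    count = as.integer(tapply(r, bin, length))
  )
}

#' Grid-search reference fit
#'
#' Exhaustive minimization of the same Bernoulli negative
#' log-likelihood over an integer grid (PSE 1..999 ms step 1, sigma
#' 5..500 ms step 1 by default).  Slow by construction; used as an
#' independent check of the two-stage optimizer.
#'
#' @param trials trial-record data frame.
#' @param lapse fixed lapse rate.
#' @param pse_grid,sigma_grid search grids, ms.
#' @return list with `pse`, `sigma`, `neg_log_likelihood`.
#' @export
grid_search_fit <- function(trials, lapse = 0.02,
                            pse_grid = seq(1, 999, by = 1),
                            sigma_grid = seq(5, 500, by = 1)) {
  tr <- extract_trials(trials)
  best <- c(NA_real_, NA_real_, Inf)
  r1 <- tr$response == 1
  for (s in sigma_grid) {
    z <- outer(tr$probe, pse_grid, "-") / s
    p1 <- clamp(lapse / 2 + (1 - lapse) * stats::pnorm(z), 1e-12, 1 - 1e-12)
    nll <- -(colSums(log(p1[r1, , drop = FALSE])) +
               colSums(log1p(-p1[!r1, , drop = FALSE])))
    j <- which.min(nll)
    if (nll[j] < best[3]) best <- c(pse_grid[j], s, nll[j])
  }
  list(pse = best[1], sigma = best[2], neg_log_likelihood = best[3])
}

#' Fit every condition of a subject's trial log
#'
#' @param trials trial-record data frame for one subject.
#' @param lapse fixed lapse rate.
#' @param n_boot bootstrap iterations per condition (0 to skip SEs).
#' @param seed optional RNG seed.
#' @return data frame with one row per condition present:
#'   `condition`, `pse_ms`, `sigma_ms`, `se_pse_ms`, `se_sigma_ms`,
#'   `n_trials`, `converged`.
#' @export
fit_conditions <- function(trials, lapse = 0.02, n_boot = 100, seed = NULL) {
  conds <- intersect(CONDITIONS, unique(trials$condition))
  rows <- lapply(seq_along(conds), function(k) {
    sub <- trials[trials$condition == conds[k], ]
    f <- fit_with_se(sub, lapse = lapse, n_boot = n_boot,
                     seed = if (is.null(seed)) NULL else seed + k,
                     condition = conds[k])
    data.frame(condition = conds[k], pse_ms = f$pse, sigma_ms = f$sigma,
               se_pse_ms = f$se_pse, se_sigma_ms = f$se_sigma,
               n_trials = f$n_trials, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
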