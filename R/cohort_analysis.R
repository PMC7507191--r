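# Cohort-level analysis: pooled bimodal thresholds, observed-versus-
# predicted paired tests, correlations with clinical covariates, and
# the packaged clinical table.

#' Load the clinical covariate table
#'
#' Reads the packaged table of 32 subject records (gender code,
#' age in months, years of education, Raven IQ, and reading decode /
#' comprehension times in seconds; lower reading times = better
#' performance).  Missing entries are explicit `NA`s, never zero.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return data frame with columns `code`, `gender`, `age_months`,
#'   `education_years`, `raven_iq`, `decode_time_s`,
#'   `comprehension_time_s`.
#' @export
load_table1 <- function(path = system.file("extdata", "table1.csv",
                                           package = "tempobisect")) {
  if (!nzchar(path) || !file.exists(path))
    tb_stop("clinical table fixture not found", "parse")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  expected <- c("code", "gender", "age_months", "education_years",
                "raven_iq", "decode_time_s", "comprehension_time_s")
  if (!identical(names(df), expected))
    tb_stop("unexpected clinical table columns", "parse")
  num <- expected[-1]
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad))
      tb_stop(sprintf("malformed value in column %s, row %d", col, bad[1]),
              "parse")
    df[[col]] <- v
  }
  if (any(!is.na(df$age_months) & df$age_months <= 0))
    tb_stop("age_months must be positive", "parse")
  df
}

#' Pooled bimodal threshold fit
#'
#' Concatenates the raw trials of the three conflict conditions and
#' fits once; only the threshold (sigma) readout of the pooled fit is
#' interpreted, since the pooled PSE mixes conflict-shifted curves.
#'
#' @param trials trial-record data frame containing all three bimodal
#'   conflict conditions.
#' @param lapse fixed lapse rate.
#' @param n_boot bootstrap iterations (0 to skip SEs).
#' @param seed optional RNG seed for the bootstrap.
#' @return a `psychometric_estimate` with condition `"AV_pooled"`.
#' @export
pooled_bimodal_fit <- function(trials, lapse = 0.02, n_boot = 100,
                               seed = NULL) {
  bi <- trials[trials$condition %in% BIMODAL_CONDITIONS, ]
  present <- sort(unique(as.numeric(bi$delta_ms)))
  if (!isTRUE(all.equal(present, c(-50, 0, 50))))
    tb_stop("pooled fit requires trials from all three conflict levels",
            "invalid_input")
  fit_with_se(bi, lapse = lapse, n_boot = n_boot, seed = seed,
              condition = "AV_pooled")
}

#' Paired observed-versus-predicted comparison
#'
#' Two-sided paired t test with Cohen's d (mean difference over the SD
#' of the differences), computed from the textbook formulas.
#'
#' @param observed,predicted equal-length paired numeric vectors
#'   (n >= 3).
#' @return list with `mean_diff`, `t`, `df`, `p`, `d`, `n`.
#' @export
compare_observed_predicted <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    tb_stop("paired vectors must have equal length", "invalid_input")
  ok <- stats::complete.cases(observed, predicted)
  d <- observed[ok] - predicted[ok]
  n <- length(d)
  if (n < 3) tb_stop("need at least 3 complete pairs", "invalid_input")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0))
      return(list(mean_diff = 0, t = 0, df = n - 1, p = 1, d = 0, n = n))
    tb_stop("differences have zero variance but nonzero mean",
            "degenerate_variance")
  }
  tval <- mean(d) / (sd_d / sqrt(n))
  list(mean_diff = mean(d), t = tval, df = n - 1,
       p = 2 * stats::pt(-abs(tval), n - 1),
       d = mean(d) / sd_d, n = n)
}

# permutation p for Spearman rho via matrix multiplication on centred ranks
spearman_perm_p <- function(x, y, n_perm) {
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  denom <- sqrt(sum(cx^2) * sum(cy^2))
  perm <- replicate(n_perm, sample(cy))
  rho_perm <- as.vector(crossprod(cx, perm)) / denom
  p <- (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  list(rho = rho, p = p)
}

#' Correlation with bootstrap CI and permutation test
#'
#' Pearson r (analytic two-sided p) together with Spearman rho, a
#' percentile bootstrap CI for rho (case resampling) and a two-sided
#' permutation p for rho.  Incomplete pairs are dropped listwise.
#'
#' @param x,y numeric vectors (>= 5 complete pairs).
#' @param n_boot bootstrap resamples for the rho CI (default 10000).
#' @param n_perm permutations for the rho p value (default 10000).
#' @param conf CI level (default 0.95).
#' @param seed optional RNG seed.
#' @return list of class `correlation_result`: `pearson_r`,
#'   `r_squared`, `p_pearson`, `spearman_rho`, `rho_ci` (length 2),
#'   `p_rho_perm`, `n` (complete pairs used), `n_dropped`.
#' @export
correlate <- function(x, y, n_boot = 10000, n_perm = 10000, conf = 0.95,
                      seed = NULL) {
  if (length(x) != length(y))
    tb_stop("x and y must have equal length", "invalid_input")
  ok <- stats::complete.cases(x, y)
  n_dropped <- sum(!ok)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 5) tb_stop("need at least 5 complete pairs", "invalid_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    tb_stop("correlation undefined for a constant vector",
            "undefined_correlation")
  r <- stats::cor(x, y)
  p_pearson <- stats::cor.test(x, y, method = "pearson")$p.value
  with_seed(seed, {
    sp <- spearman_perm_p(x, y, n_perm)
    boot_rho <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(stats::cor(x[idx], y[idx], method = "spearman"))
    }, numeric(1))
    boot_rho <- boot_rho[is.finite(boot_rho)]
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot_rho, c(alpha, 1 - alpha)))
    structure(list(pearson_r = r, r_squared = r^2, p_pearson = p_pearson,
                   spearman_rho = sp$rho, rho_ci = ci,
                   p_rho_perm = sp$p, n = n, n_dropped = n_dropped),
              class = "correlation_result")
  })
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation> r = %.3f (R2 = %.3f, p = %.4f); rho = %.3f, %s CI [%.2f, %.2f], perm p = %.4f; n = %d\n",
    x$pearson_r, x$r_squared, x$p_pearson, x$spearman_rho, "95%",
    x$rho_ci[1], x$rho_ci[2], x$p_rho_perm, x$n))
  invisible(x)
}

#' Compare two independent correlations
#'
#' Fisher r-to-z transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p value.
#'
#' @param r1,r2 correlations (|r| < 1).
#' @param n1,n2 group sizes (>= 4).
#' @return list with `z`, `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (!is_number(r1) || !is_number(r2) || abs(r1) >= 1 || abs(r2) >= 1)
    tb_stop("correlations must satisfy |r| < 1", "domain")
  if (!is_number(n1) || !is_number(n2) || n1 < 4 || n2 < 4)
    tb_stop("both groups need n >= 4", "invalid_input")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

group_mean_se <- function(x) {
  x <- x[is.finite(x)]
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}

#' Group-level report
#'
#' Assembles per-group condition means with SEs, per-subject normalized
#' conflict-PSE shifts, observed-versus-predicted paired tests (pooled
#' bimodal threshold against the optimal-integration prediction, and
#' each normalized conflict shift against its prediction), and optional
#' correlations of audio threshold/PSE with clinical covariates.
#'
#' @param fits data frame ([fit_conditions()] dialect plus
#'   `subject_id`, `group`), including an `AV_pooled` row per subject.
#' @param predictions data frame from [predict_subjects()] plus `group`.
#' @param meta optional clinical table ([load_table1()] dialect) whose
#'   rows are matched to subjects by position within the group given in
#'   `meta_group`.
#' @param meta_group group label the `meta` rows describe.
#' @return list of class `cohort_report` with elements `groups`
#'   (condition cell means/SEs), `subjects` (per-subject observed and
#'   predicted quantities), `tests`, and `correlations` (possibly
#'   empty).
#' @export
group_report <- function(fits, predictions, meta = NULL,
                         meta_group = "dyslexic") {
  stopifnot(all(c("subject_id", "group", "condition", "pse_ms", "sigma_ms")
                %in% names(fits)))
  extra <- setdiff(unique(predictions$subject_id), unique(fits$subject_id))
  missing <- setdiff(unique(fits$subject_id), unique(predictions$subject_id))
  if (length(extra) || length(missing))
    tb_stop(paste0("subject ids do not match between fits and predictions: ",
                   paste(c(extra, missing), collapse = ", ")), "join")

  # per-subject wide table of observed and predicted quantities
  ids <- unique(fits$subject_id)
  subj <- do.call(rbind, lapply(ids, function(id) {
    sub <- fits[fits$subject_id == id, ]
    pred <- predictions[predictions$subject_id == id, ]
    get <- function(cond, what) {
      v <- sub[[what]][sub$condition == cond]
      if (length(v) == 1L) v else NA_real_
    }
    pse0 <- get("AV_zero", "pse_ms")
    data.frame(
      subject_id = id, group = sub$group[1],
      sigma_A = get("A", "sigma_ms"), sigma_V = get("V", "sigma_ms"),
      pse_A = get("A", "pse_ms"), pse_V = get("V", "pse_ms"),
      sigma_AV_pooled = get("AV_pooled", "sigma_ms"),
      sigma_VA_pred = pred$sigma_VA_pred_ms,
      shift_obs_neg = normalize_pse(get("AV_neg", "pse_ms"), pse0),
      shift_obs_zero = 0,
      shift_obs_pos = normalize_pse(get("AV_pos", "pse_ms"), pse0),
      shift_pred_neg = pred$shift_pred_neg_ms,
      shift_pred_zero = pred$shift_pred_zero_ms,
      shift_pred_pos = pred$shift_pred_pos_ms,
      stringsAsFactors = FALSE)
  }))

  groups <- lapply(split(fits, fits$group), function(g) {
    conds <- unique(g$condition)
    out <- lapply(conds, function(cc) {
      gg <- g[g$condition == cc, ]
      list(sigma = as.list(group_mean_se(gg$sigma_ms)),
           pse = as.list(group_mean_se(gg$pse_ms)),
           n = nrow(gg))
    })
    names(out) <- conds
    out
  })

  # groups too small (or degenerate) for a paired test carry the reason
  safe_compare <- function(obs, pred) {
    tryCatch(compare_observed_predicted(obs, pred),
             tempobisect_error = function(e)
               list(mean_diff = mean(obs - pred, na.rm = TRUE), t = NA_real_,
                    df = NA_real_, p = NA_real_, d = NA_real_,
                    n = sum(stats::complete.cases(obs, pred)),
                    note = conditionMessage(e)))
  }
  tests <- lapply(split(subj, subj$group), function(s) {
    list(
      pooled_sigma_vs_pred =
        safe_compare(s$sigma_AV_pooled, s$sigma_VA_pred),
      shift_neg_vs_pred =
        safe_compare(s$shift_obs_neg, s$shift_pred_neg),
      shift_pos_vs_pred =
        safe_compare(s$shift_obs_pos, s$shift_pred_pos)
    )
  })

  correlations <- list()
  if (!is.null(meta)) {
    s <- subj[subj$group == meta_group, ]
    if (nrow(s) && nrow(meta) == nrow(s)) {
      correlations <- list(
        audio_sigma_vs_age =
          correlate(meta$age_months, s$sigma_A, seed = 1),
        audio_sigma_vs_decode =
          correlate(meta$decode_time_s, s$sigma_A, seed = 2),
        audio_pse_vs_decode =
          correlate(meta$decode_time_s, s$pse_A, seed = 3),
        audio_sigma_vs_iq =
          correlate(meta$raven_iq, s$sigma_A, seed = 4)
      )
    }
  }

  structure(list(groups = groups, subjects = subj, tests = tests,
                 correlations = correlations),
            class = "cohort_report")
}

#' Serialize a cohort report
#'
#' @param report a `cohort_report`.
#' @param json_path output JSON path (subjects table included).
#' @return `json_path`, invisibly.
#' @export
write_report_json <- function(report, json_path) {
  out <- unclass(report)
  out$correlations <- lapply(out$correlations, unclass)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(json_path)
}
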