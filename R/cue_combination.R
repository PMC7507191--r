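# Maximum-likelihood (optimal) cue combination.
#
# The bimodal estimate is the reliability-weighted average of the
# unisensory estimates, S_VA = w_V S_V + w_A S_A, with weights
# inversely proportional to the unisensory variances:
#   w_V = sigma_A^2 / (sigma_A^2 + sigma_V^2),  w_A = 1 - w_V.
# The predicted bimodal threshold satisfies
#   sigma_VA^2 = sigma_V^2 sigma_A^2 / (sigma_V^2 + sigma_A^2)
# and never exceeds min(sigma_V, sigma_A); the variance improvement is
# greatest (a factor of 2, i.e. sqrt(2) on the threshold) when the two
# unisensory thresholds are equal.

check_sigmas <- function(sigma_V, sigma_A) {
  if (!is_number(sigma_V) || sigma_V <= 0 || !is_number(sigma_A) || sigma_A <= 0)
    tb_stop("unisensory thresholds must be positive", "domain")
}

#' Optimal cue weights from unisensory thresholds
#'
#' @param sigma_V,sigma_A unisensory visual and audio thresholds, ms.
#' @return named numeric `c(w_V = ..., w_A = ...)`; the weights sum to 1.
#' @examples
#' mle_weights(2, 1)  # vision twice as noisy -> w_V = 0.2
#' @export
mle_weights <- function(sigma_V, sigma_A) {
  check_sigmas(sigma_V, sigma_A)
  vV <- sigma_V^2
  vA <- sigma_A^2
  c(w_V = vA / (vA + vV), w_A = vV / (vA + vV))
}

#' Predicted bimodal threshold
#'
#' @inheritParams mle_weights
#' @return predicted bimodal threshold sigma_VA in ms.
#' @export
mle_threshold <- function(sigma_V, sigma_A) {
  check_sigmas(sigma_V, sigma_A)
  sqrt(sigma_V^2 * sigma_A^2 / (sigma_V^2 + sigma_A^2))
}

#' Combined bimodal point estimate
#'
#' Weighted sum of the unisensory estimates.
#'
#' @param w_V,w_A nonnegative weights summing to 1 (tolerance 1e-8).
#' @param s_V,s_A unisensory estimates, ms.
#' @return combined estimate in ms.
#' @export
mle_pse <- function(w_V, w_A, s_V, s_A) {
  if (!is_number(w_V) || !is_number(w_A) || w_V < 0 || w_A < 0 ||
      abs(w_V + w_A - 1) > 1e-8)
    tb_stop("weights must be nonnegative and sum to 1", "invalid_input")
  w_V * s_V + w_A * s_A
}

#' Predicted conflict-induced PSE shift
#'
#' Under conflict Delta the audio and visual bisection points sit at
#' 500 - Delta and 500 + Delta; the combined PSE is their weighted
#' average, so the predicted shift from the 500 ms midpoint is
#' `Delta * (w_V - w_A)`.  Sign convention: positive = PSE later than
#' 500 ms; full audio dominance with Delta = +50 yields -50 ms.
#'
#' @inheritParams mle_pse
#' @param delta conflict Delta, one of -50, 0, +50 ms.
#' @return predicted shift in ms.
#' @export
predicted_conflict_shift <- function(w_V, w_A, delta) {
  pts <- modality_bisection_points(delta)
  mle_pse(w_V, w_A, s_V = pts[["visual"]], s_A = pts[["audio"]]) - 500
}

#' Normalize a conflict PSE to the no-conflict condition
#'
#' Subtracts the subject's no-conflict PSE from a conflict-condition
#' PSE; the same correction is applied to model predictions before
#' observed-vs-predicted comparison.
#'
#' @param conflict_pse,noconflict_pse PSEs in ms.
#' @return bias shift in ms.
#' @export
normalize_pse <- function(conflict_pse, noconflict_pse) {
  if (!is_number(conflict_pse) || !is_number(noconflict_pse))
    tb_stop("PSEs must be finite numbers", "invalid_input")
  conflict_pse - noconflict_pse
}

#' Full MLE prediction from unisensory thresholds
#'
#' @inheritParams mle_weights
#' @return object of class `mle_prediction`: `w_V`, `w_A`, `sigma_VA`,
#'   and `predicted_shift`, a vector of normalized PSE shifts named
#'   `"-50"`, `"0"`, `"50"`.
#' @export
mle_prediction <- function(sigma_V, sigma_A) {
  w <- mle_weights(sigma_V, sigma_A)
  shifts <- vapply(c(-50, 0, 50), function(d)
    predicted_conflict_shift(w[["w_V"]], w[["w_A"]], d), numeric(1))
  # normalization subtracts the Delta = 0 prediction (identically 0 here)
  shifts <- shifts - shifts[2]
  names(shifts) <- c("-50", "0", "50")
  structure(list(w_V = w[["w_V"]], w_A = w[["w_A"]],
                 sigma_VA = mle_threshold(sigma_V, sigma_A),
                 predicted_shift = shifts),
            class = "mle_prediction")
}

#' @export
print.mle_prediction <- function(x, ...) {
  cat(sprintf(
    "<mle_prediction> w_V = %.3f, w_A = %.3f, sigma_VA = %.1f ms; shifts (-50/0/+50): %s ms\n",
    x$w_V, x$w_A, x$sigma_VA,
    paste(sprintf("%.1f", x$predicted_shift), collapse = "/")))
  invisible(x)
}

#' Per-subject MLE predictions from fitted unisensory estimates
#'
#' Predictions are always computed from each subject's own unisensory
#' fits, never from group means.
#'
#' @param fits data frame with columns `subject_id`, `condition`,
#'   `sigma_ms` (the [fit_conditions()] dialect) containing an `A` and
#'   a `V` row per subject.
#' @return data frame with one row per subject: `subject_id`, `w_V`,
#'   `w_A`, `sigma_VA_pred_ms`, `shift_pred_neg_ms`,
#'   `shift_pred_zero_ms`, `shift_pred_pos_ms`.
#' @export
predict_subjects <- function(fits) {
  stopifnot(all(c("subject_id", "condition", "sigma_ms") %in% names(fits)))
  ids <- unique(fits$subject_id)
  rows <- lapply(ids, function(id) {
    sub <- fits[fits$subject_id == id, ]
    sV <- sub$sigma_ms[sub$condition == "V"]
    sA <- sub$sigma_ms[sub$condition == "A"]
    if (length(sV) != 1L || length(sA) != 1L)
      tb_stop(sprintf("subject %s lacks unisensory fits", id), "invalid_input")
    pr <- mle_prediction(sV, sA)
    data.frame(subject_id = id, w_V = pr$w_V, w_A = pr$w_A,
               sigma_VA_pred_ms = pr$sigma_VA,
               shift_pred_neg_ms = pr$predicted_shift[["-50"]],
               shift_pred_zero_ms = pr$predicted_shift[["0"]],
               shift_pred_pos_ms = pr$predicted_shift[["50"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
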