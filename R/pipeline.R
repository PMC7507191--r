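# One-call study pipeline: cohorts -> adaptive sessions -> fits ->
# optimal-integration predictions -> group report.

#' Run a full synthetic study
#'
#' Draws the two cohorts, runs one adaptive session per observer, fits
#' every condition plus the pooled bimodal threshold per subject,
#' computes the per-subject optimal-integration predictions from the
#' unisensory fits, and assembles the group report.  Fully reproducible
#' from one seed.
#'
#' @param specs list of [cohort_spec()]s (default: the typical and
#'   dyslexic cohorts).
#' @param config a [session_config()].
#' @param quest a [quest_config()].
#' @param lapse fixed lapse rate used in all fits.
#' @param n_boot bootstrap iterations per fit.
#' @param meta optional clinical table for report correlations.
#' @param seed master RNG seed; every stage derives its stream from it.
#' @return list with `trials`, `fits`, `predictions`, `report`.
#' @export
run_study <- function(specs = list(typical_cohort_spec(),
                                   dyslexic_cohort_spec()),
                      config = session_config(),
                      quest = quest_config(),
                      lapse = 0.02, n_boot = 100,
                      meta = NULL, seed = 1) {
  all_trials <- list()
  all_fits <- list()
  k <- 0L
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    cohort <- sample_cohort(spec, seed = seed + 7919L * si)
    for (id in names(cohort)) {
      k <- k + 1L
      log <- run_quest_session(cohort[[id]], config = config, quest = quest,
                               seed = seed + 31L * k, subject_id = id)
      attr(log, "quest_states") <- NULL
      log$group <- spec$label
      all_trials[[id]] <- log
      f <- fit_conditions(log, lapse = lapse, n_boot = n_boot,
                          seed = seed + 1000L * k)
      pooled <- pooled_bimodal_fit(log, lapse = lapse, n_boot = n_boot,
                                   seed = seed + 1000L * k + 500L)
      f <- rbind(f, data.frame(condition = "AV_pooled", pse_ms = pooled$pse,
                               sigma_ms = pooled$sigma,
                               se_pse_ms = pooled$se_pse,
                               se_sigma_ms = pooled$se_sigma,
                               n_trials = pooled$n_trials,
                               converged = pooled$converged,
                               stringsAsFactors = FALSE))
      f <- cbind(subject_id = id, group = spec$label, f,
                 stringsAsFactors = FALSE)
      all_fits[[id]] <- f
    }
  }
  trials <- do.call(rbind, c(all_trials, list(make.row.names = FALSE)))
  fits <- do.call(rbind, c(all_fits, list(make.row.names = FALSE)))
  preds <- predict_subjects(fits)
  preds$group <- fits$group[match(preds$subject_id, fits$subject_id)]
  report <- group_report(fits, preds, meta = meta)
  list(trials = trials, fits = fits, predictions = preds, report = report)
}
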