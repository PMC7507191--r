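# Trial and session construction for the temporal-bisection task.
#
# A trial presents three events (two anchors and a probe) on a nominal
# timeline with anchors at 0 and 1000 ms.  Bimodal trials carry an
# audio-visual conflict Delta applied with opposite sign at the probe
# (+Delta) versus the anchors (-Delta), so the net probe-vs-anchor
# relative conflict is 2*Delta (100 ms at Delta = 50).  The offset is
# split symmetrically (+/- Delta/2 to each modality), which keeps the
# nominal midpoint at 500 ms and makes an equal-weight observer predict
# a zero bias shift.

#' Experimental conditions
#'
#' `V` and `A` are the unisensory conditions; `AV_neg`, `AV_zero` and
#' `AV_pos` are the bimodal conditions with conflict Delta = -50, 0 and
#' +50 ms respectively.
#'
#' @export
CONDITIONS <- c("V", "A", "AV_neg", "AV_zero", "AV_pos")

#' @rdname CONDITIONS
#' @export
BIMODAL_CONDITIONS <- c("AV_neg", "AV_zero", "AV_pos")

#' Conflict level implied by a condition label
#'
#' @param condition character vector of condition labels.
#' @return numeric vector of Delta values in ms (0 for unisensory).
#' @export
condition_delta <- function(condition) {
  map <- c(V = 0, A = 0, AV_neg = -50, AV_zero = 0, AV_pos = 50)
  bad <- setdiff(condition, names(map))
  if (length(bad)) tb_stop(paste("unknown condition:", bad[1]), "invalid_config")
  unname(map[condition])
}

ANCHOR_T1 <- 0
ANCHOR_T3 <- 1000

#' Build one temporal-bisection trial
#'
#' Constructs the per-modality event times (anchor, probe, anchor) for a
#' trial at nominal probe time `probe_nominal` with conflict `delta`.
#' The audio stream is shifted by +delta/2 at the probe and -delta/2 at
#' the anchors; the visual stream by the opposite amounts.
#'
#' @param condition one of [CONDITIONS].
#' @param delta conflict parameter Delta in ms; one of -50, 0, +50.
#'   Must be 0 for unisensory conditions. Defaults to the level implied
#'   by the condition label.
#' @param probe_nominal nominal probe time p in ms, strictly inside
#'   (0, 1000).
#' @return an object of class `bisection_trial` with fields
#'   `audio_times`, `visual_times` (length-3 numeric or `NULL` for an
#'   absent modality), `delta`, `probe_nominal`, `condition`.
#' @examples
#' build_trial("AV_pos", probe_nominal = 500)
#' @export
build_trial <- function(condition, delta = condition_delta(condition),
                        probe_nominal) {
  condition <- match.arg(condition, CONDITIONS)
  if (!is_number(delta) || !delta %in% c(-50, 0, 50))
    tb_stop("delta must be one of -50, 0, +50 ms", "invalid_config")
  if (condition %in% c("V", "A") && delta != 0)
    tb_stop("unisensory conditions require delta = 0", "invalid_config")
  if (delta != condition_delta(condition) && condition %in% BIMODAL_CONDITIONS)
    tb_stop(sprintf("condition %s implies delta = %d", condition,
                    condition_delta(condition)), "invalid_config")
  if (!is_number(probe_nominal) ||
      probe_nominal <= ANCHOR_T1 || probe_nominal >= ANCHOR_T3)
    tb_stop("probe_nominal must lie strictly inside (0, 1000) ms", "domain")

  audio <- c(ANCHOR_T1 - delta / 2, probe_nominal + delta / 2,
             ANCHOR_T3 - delta / 2)
  visual <- c(ANCHOR_T1 + delta / 2, probe_nominal - delta / 2,
              ANCHOR_T3 + delta / 2)
  structure(
    list(
      audio_times  = if (condition != "V") audio else NULL,
      visual_times = if (condition != "A") visual else NULL,
      delta = delta,
      probe_nominal = probe_nominal,
      condition = condition
    ),
    class = "bisection_trial"
  )
}

#' @export
print.bisection_trial <- function(x, ...) {
  cat(sprintf("<bisection_trial> %s  p = %g ms  Delta = %g ms\n",
              x$condition, x$probe_nominal, x$delta))
  if (!is.null(x$audio_times))
    cat("  audio : ", paste(format(x$audio_times), collapse = ", "), "\n")
  if (!is.null(x$visual_times))
    cat("  visual: ", paste(format(x$visual_times), collapse = ", "), "\n")
  invisible(x)
}

#' Per-modality bisection points
#'
#' The nominal probe time at which each modality's probe event exactly
#' bisects that modality's own anchors.  Under the symmetric conflict
#' split these are 500 - Delta (audio) and 500 + Delta (visual); their
#' mean is always the nominal midpoint 500 ms.
#'
#' @param delta conflict Delta in ms, one of -50, 0, +50.
#' @return named numeric vector `c(audio = ..., visual = ...)` in ms.
#' @export
modality_bisection_points <- function(delta) {
  if (!is_number(delta) || !delta %in% c(-50, 0, 50))
    tb_stop("delta must be one of -50, 0, +50 ms", "invalid_config")
  c(audio = 500 - delta, visual = 500 + delta)
}

#' Session configuration
#'
#' @param trials_per_condition trials per condition (default 30, giving
#'   the standard 150-trial session over the five conditions).
#' @param condition_order order of conditions; unisensory blocks come
#'   first (vision, then audio) and the bimodal conflict levels are
#'   randomly interleaved within the final block.
#' @param easy_trial_rate fraction of slots flagged as encouraging
#'   "easy" trials (default 0.20).
#' @param easy_margin easy probes fall within this many ms of an anchor
#'   (default 100).
#' @param seed optional RNG seed for session construction.
#' @return a list of class `session_config`.
#' @export
session_config <- function(trials_per_condition = 30,
                           condition_order = CONDITIONS,
                           easy_trial_rate = 0.20,
                           easy_margin = 100,
                           seed = NULL) {
  if (!is_number(trials_per_condition) || trials_per_condition < 1)
    tb_stop("trials_per_condition must be >= 1", "invalid_config")
  if (!setequal(condition_order, CONDITIONS))
    tb_stop("condition_order must be a permutation of the five conditions",
            "invalid_config")
  if (!is_number(easy_trial_rate) || easy_trial_rate < 0 || easy_trial_rate > 1)
    tb_stop("easy_trial_rate must lie in [0, 1]", "invalid_config")
  if (!is_number(easy_margin) || easy_margin <= 0 || easy_margin >= 500)
    tb_stop("easy_margin must lie in (0, 500) ms", "invalid_config")
  structure(
    list(trials_per_condition = as.integer(trials_per_condition),
         condition_order = condition_order,
         easy_trial_rate = easy_trial_rate,
         easy_margin = easy_margin,
         seed = seed),
    class = "session_config"
  )
}

# draw an easy probe: uniform within `margin` of a randomly chosen anchor
draw_easy_probe <- function(n, margin) {
  near_first <- stats::runif(n) < 0.5
  ifelse(near_first,
         stats::runif(n, 0, margin),
         stats::runif(n, ANCHOR_T3 - margin, ANCHOR_T3))
}

#' Build an ordered session of trial slots
#'
#' Emits `trials_per_condition` slots for each of the five conditions:
#' the vision-only block first, then audio-only, then one bimodal block
#' in which the three conflict levels are randomly interleaved.  Each
#' slot is tagged easy/regular by an independent Bernoulli draw at
#' `easy_trial_rate`; easy probes are placed uniformly within
#' `easy_margin` of a random anchor, regular probes uniformly over the
#' open interval (0, 1000) ms.  Adaptive (QUEST) sessions re-place the
#' regular probes at run time; see [run_quest_session()].
#'
#' @param config a [session_config()].
#' @return data frame with columns `trial_index`, `condition`,
#'   `delta_ms`, `probe_nominal_ms`, `is_easy`.
#' @export
build_session <- function(config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  with_seed(config$seed, {
    n <- config$trials_per_condition
    uni <- intersect(config$condition_order, c("V", "A"))
    bi <- sample(rep(BIMODAL_CONDITIONS, each = n))
    conds <- c(rep(uni, each = n), bi)
    total <- length(conds)
    is_easy <- stats::runif(total) < config$easy_trial_rate
    probe <- stats::runif(total, 0, ANCHOR_T3)
    if (any(is_easy))
      probe[is_easy] <- draw_easy_probe(sum(is_easy), config$easy_margin)
    data.frame(
      trial_index = seq_len(total),
      condition = conds,
      delta_ms = condition_delta(conds),
      probe_nominal_ms = probe,
      is_easy = is_easy,
      stringsAsFactors = FALSE
    )
  })
}

#' Write a session specification to CSV
#'
#' Expands each slot into the full per-modality event times (empty cells
#' for the absent modality of unisensory trials).
#'
#' @param session data frame from [build_session()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path) {
  times <- lapply(seq_len(nrow(session)), function(i) {
    tr <- build_trial(session$condition[i], session$delta_ms[i],
                      session$probe_nominal_ms[i])
    a <- if (is.null(tr$audio_times)) rep(NA_real_, 3) else tr$audio_times
    v <- if (is.null(tr$visual_times)) rep(NA_real_, 3) else tr$visual_times
    c(a, v)
  })
  times <- do.call(rbind, times)
  colnames(times) <- c("audio_t1", "audio_t2", "audio_t3",
                       "visual_t1", "visual_t2", "visual_t3")
  utils::write.csv(cbind(session, times), path, row.names = FALSE, na = "")
  invisible(path)
}
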