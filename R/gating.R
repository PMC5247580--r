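#' Gating parameters
#'
#' Timing constants of the closed-loop presentation scheduler: stimulus
#' onsets are aimed at a fixed offset after the predicted next R-wave —
#' near the end of systole (default 300 ms post R) or mid-diastole
#' (default 500 ms post R) — and each trial begins only after a fixed
#' number of fresh heartbeats has been detected since the previous trial.
#'
#' @param systole_offset_ms Target onset for systole trials, ms after the
#'   predicted R-wave.
#' @param diastole_offset_ms Target onset for diastole trials, ms after the
#'   predicted R-wave. Must exceed `systole_offset_ms`.
#' @param min_beats_between_trials Number of beats that must be detected
#'   between trials before the next prediction is made.
#' @param detection_latency_ms Online detection delay, ms; shifts the
#'   scheduling moment, not R-referenced onsets.
#' @param predictor Predictor variant passed to [predict_next_r()].
#' @return A `gating_params` object.
#' @export
gating_params <- function(systole_offset_ms = 300, diastole_offset_ms = 500,
                          min_beats_between_trials = 4,
                          detection_latency_ms = 1,
                          predictor = "mean") {
  if (systole_offset_ms <= 0 || diastole_offset_ms <= 0) {
    abort("Phase offsets must be positive.")
  }
  if (systole_offset_ms >= diastole_offset_ms) {
    abort("`systole_offset_ms` must be smaller than `diastole_offset_ms`.")
  }
  if (min_beats_between_trials < 3) {
    abort("At least 3 inter-trial beats are needed to form a prediction.")
  }
  structure(list(systole_offset_ms = systole_offset_ms,
                 diastole_offset_ms = diastole_offset_ms,
                 min_beats_between_trials = min_beats_between_trials,
                 detection_latency_ms = detection_latency_ms,
                 predictor = predictor),
            class = "gating_params")
}

#' Intended stimulus onset for a predicted R-wave
#'
#' @param predicted_r Predicted next R-wave time(s), ms.
#' @param intended_phase `"systole"` or `"diastole"` (recycled).
#' @param params A [gating_params()] object.
#' @return Numeric vector of intended onsets (predicted R plus the phase
#'   offset).
#' @examples
#' schedule_onset(3200, "systole")  # 3500
#' schedule_onset(3200, "diastole") # 3700
#' @export
schedule_onset <- function(predicted_r, intended_phase,
                           params = gating_params()) {
  bad <- setdiff(unique(intended_phase), c("systole", "diastole"))
  if (length(bad) > 0) {
    abort(paste0("Unknown phase label(s): ", paste(bad, collapse = ", ")))
  }
  offset <- ifelse(intended_phase == "systole",
                   params$systole_offset_ms, params$diastole_offset_ms)
  predicted_r + offset
}

#' Run the closed-loop gating simulation over a heartbeat series
#'
#' Replays the online experiment against a (simulated or recorded) R-wave
#' series: for each trial, the scheduler waits for
#' `min_beats_between_trials` fresh beats, predicts the next R-wave from
#' the last three of them, and presents the stimulus at the predicted time
#' plus the phase offset. For a-posteriori recoding, the onset is then
#' referred to the nearest *actual* preceding R-wave — which may be a beat
#' that arrived earlier than predicted — giving the trial's onset latency.
#'
#' If the heartbeat series is exhausted before all trials are scheduled,
#' the remaining trials carry NA onsets and the result has attribute
#' `truncated = TRUE` (with a warning).
#'
#' @param rwaves R-wave series (tibble with `time_ms` or numeric vector).
#' @param trials A data frame with one row per trial, containing at least
#'   `intended_phase`; all other columns are carried through.
#' @param params A [gating_params()] object.
#' @return The `trials` tibble augmented with `onset_ms` (actual stimulus
#'   onset), `prev_r_ms` (nearest preceding actual R-wave) and `latency_ms`
#'   (onset minus preceding R).
#' @export
run_closed_loop <- function(rwaves, trials, params = gating_params()) {
  t <- rwave_times(rwaves)
  trials <- as_tibble(trials)
  if (!"intended_phase" %in% names(trials)) {
    abort("`trials` must contain an `intended_phase` column.")
  }
  n_trials <- nrow(trials)
  m <- params$min_beats_between_trials
  onset <- prev_r <- rep(NA_real_, n_trials)

  ptr <- 0L # index of the last beat already consumed
  truncated <- FALSE
  for (i in seq_len(n_trials)) {
    anchor <- ptr + m # the m-th fresh beat triggers the prediction
    if (anchor > length(t)) { truncated <- TRUE; break }
    pred <- predict_next_r(t[(anchor - 2):anchor], params$predictor)
    o <- schedule_onset(pred, trials$intended_phase[i], params)
    # scheduling can only happen once the anchor beat has been *detected*
    o <- max(o, t[anchor] + params$detection_latency_ms)
    j <- findInterval(o, t)
    onset[i] <- o
    prev_r[i] <- t[j]
    ptr <- j
  }
  if (truncated) {
    warn(sprintf("Heartbeat series exhausted after %d of %d trials.",
                 sum(!is.na(onset)), n_trials))
  }
  out <- dplyr::mutate(trials, onset_ms = onset, prev_r_ms = prev_r,
                       latency_ms = onset - prev_r)
  attr(out, "truncated") <- truncated
  out
}
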