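#' R-wave detector parameters
#'
#' Settings for the threshold-crossing R-wave detector, emulating a
#' hardware comparator: an event is emitted at the first sample at or above
#' `amplitude_threshold` after the signal has been below it, and further
#' crossings within `refractory_ms` are ignored. `detection_latency_ms`
#' models the online notification delay between the physical R-peak and the
#' moment the presentation software learns about it (it shifts scheduling
#' moments in [run_closed_loop()], not the detected event times).
#'
#' @param amplitude_threshold Detection threshold in signal units.
#' @param refractory_ms Dead time after an accepted event, ms (> 0).
#' @param detection_latency_ms Emulated online processing delay, ms (>= 0;
#'   real acquisition chains report under 2 ms).
#' @return A `detector_params` object.
#' @export
detector_params <- function(amplitude_threshold, refractory_ms = 200,
                            detection_latency_ms = 1) {
  stopifnot(is.numeric(amplitude_threshold), length(amplitude_threshold) == 1)
  if (refractory_ms <= 0) abort("`refractory_ms` must be positive.")
  if (detection_latency_ms < 0) abort("`detection_latency_ms` must be non-negative.")
  structure(list(amplitude_threshold = amplitude_threshold,
                 refractory_ms = refractory_ms,
                 detection_latency_ms = detection_latency_ms),
            class = "detector_params")
}

#' Detect R-waves in a sampled trace by threshold crossing
#'
#' One event is emitted per upward crossing of the amplitude threshold,
#' outside the refractory period; the event time is the time of the first
#' supra-threshold sample (no peak interpolation), with the first sample of
#' the trace at time 0.
#'
#' @param trace Numeric vector of signal samples, or a data frame with a
#'   `value` column (and optionally `time_ms`, which is ignored in favour of
#'   `sample_period_ms` for uniform sampling).
#' @param params A [detector_params()] object.
#' @param sample_period_ms Sampling period in ms (1 ms mirrors a 1,000 Hz
#'   recording).
#'
#' @return A tibble with columns `beat`, `time_ms`. If no sample crosses the
#'   threshold an empty tibble is returned with a warning.
#' @examples
#' x <- rep(0, 3000); x[c(100, 900, 1700, 2500)] <- 1
#' detect_r_waves(x, detector_params(0.5))
#' @export
detect_r_waves <- function(trace, params, sample_period_ms = 1) {
  if (is.data.frame(trace)) trace <- trace[["value"]]
  if (!is.numeric(trace) || length(trace) == 0) {
    abort("`trace` must be a non-empty numeric vector or a data frame with `value`.")
  }
  stopifnot(inherits(params, "detector_params"))
  thr <- params$amplitude_threshold
  if (thr > max(trace)) {
    warn("No sample reaches the detection threshold; returning an empty series.")
    return(tibble(beat = integer(), time_ms = numeric()))
  }
  above <- trace >= thr
  crossing <- which(above & !c(FALSE, above[-length(above)]))
  times <- (crossing - 1) * sample_period_ms
  # refractory: greedy left-to-right acceptance
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= params$refractory_ms) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times <- times[keep]
  if (length(times) == 0) {
    warn("All threshold crossings fell inside the refractory period.")
    return(tibble(beat = integer(), time_ms = numeric()))
  }
  tibble(beat = seq_along(times), time_ms = times)
}

#' Predict the time of the next R-wave from recent beats
#'
#' The default strategy mirrors online cardiac gating software: from the
#' three preceding R-wave times, take the two inter-beat intervals, and
#' extrapolate the next beat as the last time plus their arithmetic mean.
#' Supplying four times with `strategy = "mean"` gives the three-IBI
#' variant; `"weighted"` weights recent intervals linearly more;
#' `"last"` repeats the most recent interval.
#'
#' @param times Strictly increasing numeric vector of R-wave times, ms.
#'   The canonical call passes exactly three.
#' @param strategy One of `"mean"` (default), `"weighted"`, `"last"`.
#' @return Predicted time of the next R-wave (ms), always greater than
#'   `max(times)`.
#' @examples
#' predict_next_r(c(800, 1600, 2400))   # 3200
#' predict_next_r(c(1000, 1800, 2700))  # 3550
#' @export
predict_next_r <- function(times, strategy = c("mean", "weighted", "last")) {
  strategy <- match.arg(strategy)
  if (!is.numeric(times) || length(times) < 2) {
    abort("`times` must contain at least two R-wave times.")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("R-wave times must be strictly increasing.")
  }
  ibis <- diff(times)
  step <- switch(strategy,
    mean = mean(ibis),
    weighted = sum(ibis * seq_along(ibis)) / sum(seq_along(ibis)),
    last = ibis[length(ibis)])
  times[length(times)] + step
}

#' A-posteriori prediction error of the next-beat predictor
#'
#' Replays the online predictor over a recorded series: for every beat from
#' the fourth onward, the prediction is formed from the three preceding
#' beats and compared with the beat's actual time. With i.i.d. Gaussian
#' IBIs of standard deviation s, the signed error has SD s*sqrt(3/2).
#'
#' @param rwaves R-wave series (tibble with `time_ms`, or numeric vector).
#' @param strategy Predictor variant, see [predict_next_r()].
#' @return A tibble with columns `beat`, `actual_ms`, `predicted_ms`,
#'   `error_ms` (actual minus predicted), one row per beat >= 4.
#' @export
prediction_error_profile <- function(rwaves, strategy = "mean") {
  t <- rwave_times(rwaves)
  n <- length(t)
  if (n < 4) abort("At least 4 beats are needed to profile the predictor.")
  k <- 4:n
  pred <- vapply(k, function(i) predict_next_r(t[(i - 3):(i - 1)], strategy),
                 numeric(1))
  tibble(beat = k, actual_ms = t[k], predicted_ms = pred,
         error_ms = t[k] - pred)
}
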