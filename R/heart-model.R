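#' Heart rhythm model parameters
#'
#' Parameters of the stochastic inter-beat-interval (IBI) model used to
#' simulate R-wave event series. IBIs follow a stationary Gaussian AR(1)
#' process around `mean_ibi` with standard deviation `sdnn` and lag-1
#' autocorrelation `ar1`, optionally modulated by an additive sinusoid
#' emulating respiratory sinus arrhythmia.
#'
#' Generated IBIs are clamped from below at `ibi_floor` (a physiological
#' refractory bound); the realised clamping rate is reported by
#' [simulate_rwaves()] so that heavy clamping — which would distort the
#' nominal SDNN — is visible rather than silent.
#'
#' @param mean_ibi Mean inter-beat interval in ms. Must exceed `ibi_floor`.
#' @param sdnn Standard deviation of the IBIs in ms (SDNN). Non-negative.
#' @param ar1 Lag-1 autocorrelation of the IBI series, in (-1, 1).
#' @param rsa_amp Amplitude (ms) of an optional additive sinusoidal
#'   modulation of the IBI; 0 disables it.
#' @param rsa_freq Frequency of the modulation in Hz (typical respiratory
#'   rates are 0.2-0.3 Hz).
#' @param ibi_floor Hard lower bound on generated IBIs, ms.
#'
#' @return An object of class `heart_model_params` (a named list).
#' @examples
#' heart_model_params(mean_ibi = 850, sdnn = 30)
#' @export
heart_model_params <- function(mean_ibi = 850, sdnn = 30, ar1 = 0,
                               rsa_amp = 0, rsa_freq = 0.25,
                               ibi_floor = 300) {
  stopifnot(is.numeric(mean_ibi), length(mean_ibi) == 1,
            is.numeric(sdnn), length(sdnn) == 1,
            is.numeric(ar1), length(ar1) == 1)
  if (sdnn < 0) abort("`sdnn` must be non-negative.")
  if (abs(ar1) >= 1) abort("`ar1` must lie strictly inside (-1, 1).")
  if (rsa_amp < 0) abort("`rsa_amp` must be non-negative.")
  if (mean_ibi <= ibi_floor) {
    abort(sprintf(
      "`mean_ibi` (%.0f ms) must exceed the physiological floor (%.0f ms).",
      mean_ibi, ibi_floor))
  }
  structure(
    list(mean_ibi = mean_ibi, sdnn = sdnn, ar1 = ar1,
         rsa_amp = rsa_amp, rsa_freq = rsa_freq, ibi_floor = ibi_floor),
    class = "heart_model_params")
}

#' Simulate an R-wave event series
#'
#' Draws `n_beats` R-wave event times from the AR(1) IBI model in `params`.
#' The first beat is placed at time 0; subsequent beats are separated by the
#' simulated IBIs. The AR(1) innovations are scaled so that the stationary
#' IBI standard deviation equals `sdnn` for any admissible `ar1`.
#'
#' @param params A [heart_model_params()] object.
#' @param n_beats Number of beats to generate (>= 4, the minimum any
#'   downstream prediction needs).
#' @param seed Optional integer seed; when supplied the series is fully
#'   reproducible.
#'
#' @return A tibble with columns `beat` (1..n) and `time_ms` (strictly
#'   increasing event times). Attributes: `clamp_rate` — fraction of IBIs
#'   clamped at the floor; `realized_sdnn` — sample SD of the emitted IBIs.
#' @examples
#' rw <- simulate_rwaves(heart_model_params(sdnn = 0, mean_ibi = 800), 5)
#' rw$time_ms # 0 800 1600 2400 3200
#' @export
simulate_rwaves <- function(params, n_beats, seed = NULL) {
  stopifnot(inherits(params, "heart_model_params"))
  if (n_beats < 4) abort("`n_beats` must be at least 4.")
  if (!is.null(seed)) set.seed(seed)

  n_ibi <- n_beats - 1
  # stationary AR(1): innovation sd chosen so marginal sd == sdnn
  x <- numeric(n_ibi)
  if (params$sdnn > 0) {
    innov_sd <- params$sdnn * sqrt(1 - params$ar1^2)
    x[1] <- rnorm(1, 0, params$sdnn)
    if (n_ibi > 1) {
      e <- rnorm(n_ibi - 1, 0, innov_sd)
      for (k in 2:n_ibi) x[k] <- params$ar1 * x[k - 1] + e[k - 1]
    }
  }
  ibi <- params$mean_ibi + x
  if (params$rsa_amp > 0) {
    # modulate by the (approximate) time of each interval's onset
    t_approx <- (seq_len(n_ibi) - 1) * params$mean_ibi / 1000
    ibi <- ibi + params$rsa_amp * sin(2 * pi * params$rsa_freq * t_approx)
  }
  clamped <- ibi < params$ibi_floor
  ibi[clamped] <- params$ibi_floor

  out <- tibble(beat = seq_len(n_beats), time_ms = c(0, cumsum(ibi)))
  attr(out, "clamp_rate") <- mean(clamped)
  attr(out, "realized_sdnn") <- if (n_ibi > 1) sd(ibi) else NA_real_
  class(out) <- c("cg_rwaves", class(out))
  out
}

#' Inter-beat intervals of an R-wave series
#'
#' @param rwaves A tibble from [simulate_rwaves()] or any tibble with a
#'   `time_ms` column, or a numeric vector of event times.
#' @return Numeric vector of successive differences (ms).
#' @export
ibi_series <- function(rwaves) {
  diff(rwave_times(rwaves))
}

# Accept either a numeric vector of times or a tibble with time_ms.
rwave_times <- function(rwaves) {
  t <- if (is.numeric(rwaves)) rwaves else rwaves[["time_ms"]]
  if (is.null(t)) abort("Expected a numeric vector or a tibble with a `time_ms` column.")
  if (anyNA(t) || is.unsorted(t, strictly = TRUE)) {
    abort("R-wave times must be strictly increasing and free of NAs.")
  }
  t
}
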