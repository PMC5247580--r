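#' Cardiac phase recoding windows
#'
#' Fixed post-R-wave windows used to recode trials a-posteriori: onsets in
#' the systolic window (default 200-400 ms after the R-wave, the period of
#' maximal baroreceptor afferent firing) are labelled systole, onsets in
#' the diastolic window (450-800 ms) diastole, and everything else —
#' 0-200 ms, the ambiguous 400-450 ms gap, and beyond 800 ms — is excluded.
#' Both windows are closed intervals: the boundary latencies 200, 400, 450
#' and 800 ms are retained, a convention that changes classification only
#' on a measure-zero set of latencies and maximises retained trials.
#'
#' @param systole Length-2 numeric, closed systolic window (ms post R).
#' @param diastole Length-2 numeric, closed diastolic window (ms post R).
#' @return A `phase_windows` object.
#' @export
phase_windows <- function(systole = c(200, 400), diastole = c(450, 800)) {
  stopifnot(length(systole) == 2, length(diastole) == 2)
  if (systole[1] >= systole[2] || diastole[1] >= diastole[2]) {
    abort("Each window must be an increasing pair.")
  }
  if (systole[2] >= diastole[1]) {
    abort("The systolic window must end before the diastolic window begins.")
  }
  structure(list(systole = systole, diastole = diastole),
            class = "phase_windows")
}

#' Classify onset latencies into cardiac phases
#'
#' @param latency_ms Non-negative onset latencies relative to the preceding
#'   R-wave, ms.
#' @param windows A [phase_windows()] object.
#' @return Character vector: `"systole"`, `"diastole"` or `"excluded"`.
#'   NAs propagate.
#' @examples
#' classify_phase(c(300, 425, 500, 150, 820))
#' @export
classify_phase <- function(latency_ms, windows = phase_windows()) {
  if (any(latency_ms < 0, na.rm = TRUE)) {
    abort("Negative onset latencies indicate an upstream R-matching bug.")
  }
  out <- rep(NA_character_, length(latency_ms))
  ok <- !is.na(latency_ms)
  out[ok] <- "excluded"
  out[ok & latency_ms >= windows$systole[1] & latency_ms <= windows$systole[2]] <- "systole"
  out[ok & latency_ms >= windows$diastole[1] & latency_ms <= windows$diastole[2]] <- "diastole"
  out
}

#' Recode gated trials by actual onset latency
#'
#' Adds a `recoded_phase` column to a trial table produced by
#' [run_closed_loop()]. Recoding depends only on `latency_ms`, never on the
#' intended phase: a diastole-intended trial whose stimulus landed at
#' 350 ms post R becomes a systole trial.
#'
#' @param trials Trial table with a `latency_ms` column.
#' @param windows A [phase_windows()] object.
#' @return `trials` with `recoded_phase` added.
#' @export
recode_phases <- function(trials, windows = phase_windows()) {
  if (!"latency_ms" %in% names(trials)) {
    abort("`trials` must contain `latency_ms` (run `run_closed_loop()` first).")
  }
  dplyr::mutate(as_tibble(trials),
                recoded_phase = classify_phase(.data$latency_ms, windows))
}

#' Fraction of trials excluded by the recoding windows
#'
#' @param trials Recoded trial table (see [recode_phases()]).
#' @param by Optional character vector of grouping columns (e.g.
#'   `"subject"`) for per-group rates; default is the pooled rate.
#' @return The pooled rate as a single number, or a tibble of per-group
#'   rates when `by` is given.
#' @export
exclusion_rate <- function(trials, by = NULL) {
  if (!"recoded_phase" %in% names(trials)) trials <- recode_phases(trials)
  if (nrow(trials) == 0) abort("Empty trial table.")
  if (is.null(by)) {
    return(mean(trials$recoded_phase == "excluded", na.rm = TRUE))
  }
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_excluded = sum(.data$recoded_phase == "excluded", na.rm = TRUE),
      exclusion_rate = .data$n_excluded / .data$n,
      .groups = "drop")
}

#' Cumulative onset-latency curves per intended phase
#'
#' The offline reliability check of the gating procedure: for each intended
#' phase, the cumulative frequency of actual stimulus onsets (ms relative
#' to the preceding R-wave) evaluated on a regular grid. Curves are
#' monotone non-decreasing and end at 1; well-separated curves crossing
#' 50% near their target offsets indicate faithful gating.
#'
#' @param trials Trial table with `latency_ms` and `intended_phase`.
#' @param bin_ms Grid resolution in ms (> 0).
#' @return A tibble of class `cg_onset_curves` with columns
#'   `intended_phase`, `latency_ms` (grid point) and `cum_freq`.
#' @export
cumulative_onset <- function(trials, bin_ms = 10) {
  if (bin_ms <= 0) abort("`bin_ms` must be positive.")
  lat <- trials$latency_ms
  if (all(is.na(lat))) abort("No onset latencies available.")
  grid <- seq(0, ceiling(max(lat, na.rm = TRUE) / bin_ms) * bin_ms, by = bin_ms)
  out <- trials |>
    dplyr::filter(!is.na(.data$latency_ms)) |>
    dplyr::group_by(.data$intended_phase) |>
    dplyr::reframe({
      e <- stats::ecdf(.data$latency_ms)
      tibble(latency_ms = grid, cum_freq = e(grid))
    })
  class(out) <- c("cg_onset_curves", class(out))
  out
}

#' Latency at which a cumulative onset curve crosses a given frequency
#'
#' Linear interpolation of the per-phase cumulative curves; used to check
#' that the median onset sits near the targeted post-R offset.
#'
#' @param curves A `cg_onset_curves` tibble from [cumulative_onset()].
#' @param freq Crossing level in (0, 1), default 0.5.
#' @return A tibble with `intended_phase` and `crossing_ms`.
#' @export
onset_crossing <- function(curves, freq = 0.5) {
  stopifnot(freq > 0, freq < 1)
  cross_one <- function(lat, cum) {
    i <- which(cum >= freq)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1 || cum[i] == cum[i - 1]) return(lat[i])
    lat[i - 1] + (freq - cum[i - 1]) / (cum[i] - cum[i - 1]) *
      (lat[i] - lat[i - 1])
  }
  curves |>
    dplyr::group_by(.data$intended_phase) |>
    dplyr::summarise(
      crossing_ms = cross_one(.data$latency_ms, .data$cum_freq),
      .groups = "drop")
}

#' @describeIn cumulative_onset Plot the cumulative onset curves with the
#'   recoding windows shaded (systole and diastole bands; everything else
#'   excluded).
#' @param object A `cg_onset_curves` tibble.
#' @param windows Recoding windows drawn as shaded bands.
#' @param ... Ignored.
#' @export
autoplot.cg_onset_curves <- function(object, windows = phase_windows(), ...) {
  bands <- tibble(
    phase = c("systole", "diastole"),
    xmin = c(windows$systole[1], windows$diastole[1]),
    xmax = c(windows$systole[2], windows$diastole[2]))
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = 0, ymax = 1,
                   fill = .data$phase),
      alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_step(
      ggplot2::aes(.data$latency_ms, .data$cum_freq,
                   colour = .data$intended_phase)) +
    ggplot2::labs(x = "Stimulus onset relative to R-wave (ms)",
                  y = "Cumulative frequency",
                  colour = "Intended phase", fill = "Recoding window") +
    ggplot2::theme_minimal()
}
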