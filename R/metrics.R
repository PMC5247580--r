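#' Per-subject, per-cell accuracy
#'
#' Accuracy is the number of on-time correct responses divided by the
#' number of (non-excluded) trials in the cell — late and absent responses
#' count against accuracy. Cells are prime x object x recoded phase;
#' excluded trials are removed before counting. Cells that end up empty
#' after exclusion are reported with `NA` accuracy, never 0.
#'
#' @param trials Recoded trial table with columns `subject`, `prime`,
#'   `object`, `recoded_phase`, `on_time`, `correct`.
#' @param design Optional [design_spec()]; when supplied, the output is
#'   completed over the design's full prime x object x phase grid so that
#'   cells emptied by exclusion appear as `NA` rows.
#' @return A tibble: `subject`, `prime`, `object`, `phase`, `n_trials`,
#'   `n_correct`, `accuracy`.
#' @export
accuracy_table <- function(trials, design = NULL) {
  need <- c("subject", "prime", "object", "recoded_phase", "correct")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("`trials` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- trials |>
    dplyr::filter(.data$recoded_phase %in% c("systole", "diastole")) |>
    dplyr::group_by(.data$subject, .data$prime, .data$object,
                    phase = .data$recoded_phase) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_correct = sum(.data$correct),
                     accuracy = .data$n_correct / .data$n_trials,
                     .groups = "drop")
  if (!is.null(design)) {
    out <- tidyr::complete(
      out, .data$subject,
      prime = design$primes, object = design$objects,
      phase = design$phases, fill = list(n_trials = 0L))
  } else {
    out <- tidyr::complete(out, .data$subject, .data$prime, .data$object,
                           .data$phase, fill = list(n_trials = 0L))
  }
  dplyr::arrange(out, .data$subject, .data$prime, .data$object, .data$phase)
}

#' Signal-detection indices from hit and false-alarm rates
#'
#' d' = z(H) - z(F) and criterion C = -(z(H) + z(F)) / 2, with z the
#' standard normal quantile. Extreme rates (0 or 1) are corrected before
#' the transform; the default replaces 0 by 1/(2N) and 1 by 1 - 1/(2N)
#' (per-rate trial counts), the log-linear alternative adds 0.5 to each
#' count and 1 to each denominator for all rates.
#'
#' @param hit_rate,fa_rate Observed rates in \[0, 1\] (vectorised).
#' @param n_signal,n_noise Trial counts behind each rate (> 0).
#' @param correction `"halfN"` (default), `"loglinear"` or `"none"`.
#' @return A tibble: `hit_rate_adj`, `fa_rate_adj`, `d_prime`,
#'   `criterion_c`.
#' @examples
#' sdt_indices(0.69, 0.31, 33, 33) # d' ~ 0.992, C ~ 0
#' @export
sdt_indices <- function(hit_rate, fa_rate, n_signal, n_noise,
                        correction = c("halfN", "loglinear", "none")) {
  correction <- match.arg(correction)
  if (any(c(n_signal, n_noise) <= 0)) {
    abort("Trial counts must be positive.")
  }
  rng <- range(c(hit_rate, fa_rate), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) abort("Rates must lie in [0, 1].")
  adjust <- function(rate, n) {
    switch(correction,
      halfN = pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n)),
      loglinear = (rate * n + 0.5) / (n + 1),
      none = rate)
  }
  h <- adjust(hit_rate, n_signal)
  f <- adjust(fa_rate, n_noise)
  tibble(hit_rate_adj = h, fa_rate_adj = f,
         d_prime = qnorm(h) - qnorm(f),
         criterion_c = -(qnorm(h) + qnorm(f)) / 2)
}

#' Per-subject SDT indices as a function of prime and cardiac phase
#'
#' Rolls the accuracy table up to prime x phase SDT indices using the
#' task's signal/noise object roles: hits are correct responses to the
#' signal object (weapon / armed / sport object), false alarms are errors
#' on the noise object (tool / unarmed / fruit). Error rates are
#' 1 - accuracy, so late and absent responses count as errors, consistent
#' with the on-time accuracy definition.
#'
#' @param accuracy Output of [accuracy_table()].
#' @param design The [design_spec()] whose object roles apply.
#' @param correction Extreme-rate correction, see [sdt_indices()].
#' @return A tibble: `subject`, `prime`, `phase`, `hit_rate`, `fa_rate`,
#'   `n_signal`, `n_noise`, `d_prime`, `criterion_c`.
#' @export
sdt_table <- function(accuracy, design, correction = "halfN") {
  stopifnot(inherits(design, "design_spec"))
  wide <- accuracy |>
    dplyr::mutate(role = ifelse(.data$object == design$signal_object,
                                "signal", "noise")) |>
    dplyr::select("subject", "prime", "phase", "role", "n_trials",
                  "accuracy") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("n_trials", "accuracy"))
  idx <- sdt_indices(wide$accuracy_signal, 1 - wide$accuracy_noise,
                     wide$n_trials_signal, wide$n_trials_noise,
                     correction)
  dplyr::bind_cols(
    wide |>
      dplyr::transmute(.data$subject, .data$prime, .data$phase,
                       hit_rate = .data$accuracy_signal,
                       fa_rate = 1 - .data$accuracy_noise,
                       n_signal = .data$n_trials_signal,
                       n_noise = .data$n_trials_noise),
    idx[c("d_prime", "criterion_c")])
}

#' Process-dissociation estimates of controlled and automatic processing
#'
#' Control is accuracy on stereotype-congruent trials minus the error rate
#' on stereotype-incongruent trials; the automatic estimate is the
#' incongruent error rate divided by the reciprocal of control
#' (1 - control). When control equals 1 the automatic estimate is
#' undefined and returned as `NA`.
#'
#' @param acc_congruent Accuracy on congruent trials, in \[0, 1\].
#' @param err_incongruent Error rate on incongruent trials, in \[0, 1\].
#' @return A tibble: `control`, `automatic`.
#' @examples
#' pdp_indices(0.95, 0.35) # control 0.60, automatic 0.875
#' @export
pdp_indices <- function(acc_congruent, err_incongruent) {
  rng <- range(c(acc_congruent, err_incongruent), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) abort("Inputs must lie in [0, 1].")
  control <- acc_congruent - err_incongruent
  automatic <- ifelse(control < 1, err_incongruent / (1 - control), NA_real_)
  tibble(control = control, automatic = automatic)
}

#' Per-subject PDP indices as a function of prime and cardiac phase
#'
#' Uses the design's stereotype map: for each prime, the congruent cell is
#' the stereotypically associated object (e.g. Black-weapon, White-tool)
#' and the incongruent cell its complement.
#'
#' @inheritParams sdt_table
#' @return A tibble: `subject`, `prime`, `phase`, `acc_congruent`,
#'   `err_incongruent`, `control`, `automatic`.
#' @export
pdp_table <- function(accuracy, design) {
  stopifnot(inherits(design, "design_spec"))
  wide <- accuracy |>
    dplyr::mutate(role = ifelse(design$congruent[.data$prime] == .data$object,
                                "congruent", "incongruent")) |>
    dplyr::select("subject", "prime", "phase", "role", "accuracy") |>
    tidyr::pivot_wider(names_from = "role", values_from = "accuracy") |>
    dplyr::transmute(.data$subject, .data$prime, .data$phase,
                     acc_congruent = .data$congruent,
                     err_incongruent = 1 - .data$incongruent)
  dplyr::bind_cols(wide, pdp_indices(wide$acc_congruent,
                                     wide$err_incongruent))
}

#' First-person-shooter point totals
#'
#' Scores each trial by its outcome: shooting an armed target +10, not
#' shooting an unarmed target +5, shooting an unarmed target -20, failing
#' to shoot an armed target -40, and no response within the 650 ms
#' deadline -10. Responses arriving after the deadline but inside the
#' 1000 ms collection window are scored as timeouts (the online feedback
#' used the deadline).
#'
#' @param trials FPST trial table with `subject`, `object`
#'   (`"armed"`/`"unarmed"`), `correct`, `rt_ms`.
#' @param design The FPST [design_spec()] (supplies payoff and deadline).
#' @return A tibble: `subject`, `points`, plus per-outcome counts.
#' @export
fpst_points <- function(trials, design = design_spec("fpst")) {
  if (is.null(design$payoff)) abort("Design carries no payoff matrix.")
  bad <- setdiff(unique(trials$object), design$objects)
  if (length(bad) > 0) {
    abort(paste0("Unknown object label(s): ", paste(bad, collapse = ", ")))
  }
  scored <- trials |>
    dplyr::mutate(
      in_time = !is.na(.data$rt_ms) & .data$rt_ms <= design$response_deadline_ms,
      outcome = dplyr::case_when(
        !.data$in_time ~ "timeout",
        .data$object == "armed" & .data$correct ~ "hit",
        .data$object == "armed" ~ "miss",
        .data$correct ~ "correct_rejection",
        TRUE ~ "false_alarm"),
      pts = design$payoff[.data$outcome])
  scored |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(points = sum(.data$pts),
                     n_hit = sum(.data$outcome == "hit"),
                     n_correct_rejection = sum(.data$outcome == "correct_rejection"),
                     n_false_alarm = sum(.data$outcome == "false_alarm"),
                     n_miss = sum(.data$outcome == "miss"),
                     n_timeout = sum(.data$outcome == "timeout"),
                     .groups = "drop")
}
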