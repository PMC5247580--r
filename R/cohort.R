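#' Simulate a cardiac-gated behavioural cohort
#'
#' Full generative model of one study: for each subject an R-wave series is
#' drawn from the heart model, the trial sequence (each factorial cell
#' repeated `trials_per_cell` times, uniformly shuffled) is run through the
#' closed-loop gating simulator, onsets are recoded a-posteriori into
#' cardiac phases, and responses are drawn per trial.
#'
#' The response model keys accuracy on the trial's *recoded* phase — the
#' modelled physiological effect depends on where the stimulus actually
#' landed in the cardiac cycle, not on where the scheduler aimed it.
#' Trials falling in the excluded windows draw from the phase-average
#' probability of their prime x object cell (they are dropped before any
#' analysis anyway). Latencies are lognormal; a response is on time when
#' one is produced and its latency is within the design's collection
#' window. Correctness is only awarded to on-time responses.
#'
#' @param design A [design_spec()] object.
#' @param heart A [heart_model_params()] object.
#' @param behavior A [behavior_params()] object.
#' @param n_subjects Number of subjects (>= 2; within-subject statistics
#'   need degrees of freedom).
#' @param seed Optional integer seed for full reproducibility.
#' @param gating A [gating_params()] object.
#' @param windows A [phase_windows()] object for recoding.
#' @return A list of class `cg_cohort` with elements `rwaves` (tibble:
#'   `subject`, `beat`, `time_ms`) and `trials` (tibble: `subject`,
#'   `trial`, `prime`, `object`, `intended_phase`, `congruent`,
#'   `onset_ms`, `prev_r_ms`, `latency_ms`, `recoded_phase`, `response`,
#'   `rt_ms`, `on_time`, `correct`), plus the generating objects as
#'   attributes.
#' @export
simulate_cohort <- function(design, heart = heart_model_params(),
                            behavior, n_subjects = 30, seed = NULL,
                            gating = gating_params(
                              min_beats_between_trials =
                                design$min_beats_between_trials),
                            windows = phase_windows()) {
  stopifnot(inherits(design, "design_spec"),
            inherits(behavior, "behavior_params"))
  if (n_subjects < 2) {
    abort("`n_subjects` must be at least 2 for within-subject statistics.")
  }
  if (!is.null(seed)) set.seed(seed)

  cells <- design_cells(design)
  # lookup tables: per-cell p keyed on phase, and phase-averaged fallback
  p_by_phase <- behavior$p_correct
  p_avg <- p_by_phase |>
    dplyr::group_by(.data$prime, .data$object) |>
    dplyr::summarise(p_avg = mean(.data$p_correct), .groups = "drop")

  # ~5 beats are consumed per trial (4 inter-trial + the reference beat)
  n_beats <- 5L * design$n_trials + 25L

  one_subject <- function(s) {
    rw <- simulate_rwaves(heart, n_beats)
    seq_tbl <- cells[rep(seq_len(nrow(cells)), design$trials_per_cell), ] |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(trial = dplyr::row_number(), .before = 1)
    gated <- run_closed_loop(rw, seq_tbl, gating) |>
      recode_phases(windows)

    gated <- gated |>
      dplyr::left_join(p_by_phase |>
                         dplyr::rename(recoded_phase = "intended_phase",
                                       p_cell = "p_correct"),
                       by = c("prime", "object", "recoded_phase")) |>
      dplyr::left_join(p_avg, by = c("prime", "object")) |>
      dplyr::mutate(p_use = dplyr::coalesce(.data$p_cell, .data$p_avg))

    n <- nrow(gated)
    responded <- runif(n) >= behavior$miss_rate
    rt <- ifelse(responded,
                 rlnorm(n, behavior$rt_meanlog, behavior$rt_sdlog),
                 NA_real_)
    on_time <- responded & rt <= design$collection_window_ms
    chose_correct <- runif(n) < gated$p_use
    correct <- on_time & chose_correct
    other <- setNames(rev(design$objects), design$objects)
    response <- unname(ifelse(responded,
                              ifelse(chose_correct, gated$object,
                                     other[gated$object]),
                              NA_character_))
    list(
      rwaves = dplyr::mutate(rw, subject = s, .before = 1),
      trials = gated |>
        dplyr::select(-"p_cell", -"p_avg", -"p_use") |>
        dplyr::mutate(subject = s, .before = 1) |>
        dplyr::mutate(response = response, rt_ms = round(rt),
                      on_time = on_time, correct = correct))
  }

  per_subject <- purrr::map(seq_len(n_subjects), one_subject)
  out <- list(rwaves = purrr::list_rbind(purrr::map(per_subject, "rwaves")),
              trials = purrr::list_rbind(purrr::map(per_subject, "trials")))
  attr(out, "design") <- design
  attr(out, "heart") <- heart
  attr(out, "behavior") <- behavior
  class(out) <- "cg_cohort"
  out
}

#' @export
print.cg_cohort <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("<cg_cohort> %s design: %d subjects x %d trials (%d cells x %d)\n",
              toupper(d$task), length(unique(x$trials$subject)),
              d$n_trials, d$n_cells, d$trials_per_cell))
  invisible(x)
}

#' Fast cell-level accuracy generator
#'
#' The marginal model of [simulate_cohort()] at the cell level: for each
#' subject and factorial cell, the number of on-time correct responses is
#' Binomial(`n_trials`, `p_correct[cell]`). This path skips heartbeat
#' simulation and gating — the phase label is taken at face value — and is
#' the workhorse for type-I-error and power calibration, where thousands of
#' replicate cohorts are needed and the gating stage contributes nothing to
#' the statistic under study.
#'
#' @param p_correct 8-row cell probability table (see [p_correct_cells()]).
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per cell.
#' @param seed Optional seed.
#' @return A tibble: `subject`, `prime`, `object`, `phase`, `n_trials`,
#'   `n_correct`, `accuracy`.
#' @export
simulate_cell_counts <- function(p_correct, n_subjects = 30, n_trials = 33,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- dplyr::rename(as_tibble(p_correct), phase = "intended_phase")
  out <- tidyr::expand_grid(subject = seq_len(n_subjects),
                            cells[c("prime", "object", "phase", "p_correct")])
  out |>
    dplyr::mutate(n_trials = n_trials,
                  n_correct = rbinom(dplyr::n(), n_trials, .data$p_correct),
                  accuracy = .data$n_correct / n_trials) |>
    dplyr::select(-"p_correct")
}
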