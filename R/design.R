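#' Task design specifications
#'
#' Factorial structure and timing of the three cardiac-gated priming /
#' decision paradigms:
#'
#' * `"wit"` — weapons identification task: Black/White face primes
#'   followed by tool/weapon targets. Prime 200 ms (gated), target 150 ms,
#'   response deadline 500 ms, latencies collected to 650 ms;
#'   33 trials per cell, 264 total.
#' * `"fpst"` — first-person shooter task: photos of armed or unarmed
#'   Black/White men; shoot / don't-shoot decision. Target 200 ms (gated),
#'   deadline 650 ms, latencies collected to 1000 ms; 23 trials per cell
#'   (184 total) and a point payoff per outcome.
#' * `"sfit"` — sport/fruits identification task: same structure and
#'   timing as the WIT with fruit/sport-object targets, probing the
#'   positive Black-athletic association.
#'
#' Every design is a 2 (prime/race) x 2 (object) x 2 (intended phase)
#' within-subject factorial; stimulus onsets are gated on the prime for
#' WIT/SFIT and on the target for FPST.
#'
#' @param task One of `"wit"`, `"fpst"`, `"sfit"`.
#' @param trials_per_cell Trials per factorial cell; defaults to the
#'   task's canonical count (33 for WIT/SFIT, 23 for FPST).
#' @return A `design_spec` object (named list) with fields `task`,
#'   `primes`, `objects`, `signal_object` (SDT "signal" category),
#'   `congruent` (prime -> stereotype-congruent object map), timing fields
#'   (ms), `payoff` (FPST only), `min_beats_between_trials`, `gated`,
#'   `trials_per_cell`, `n_cells`, `n_trials`.
#' @examples
#' design_spec("wit")$n_trials # 264
#' @export
design_spec <- function(task = c("wit", "fpst", "sfit"),
                        trials_per_cell = NULL) {
  task <- match.arg(task)
  base <- switch(task,
    wit = list(
      objects = c("tool", "weapon"), signal_object = "weapon",
      congruent = c(black = "weapon", white = "tool"),
      trials_per_cell = 33, gated = "prime",
      pre_stimulus_mask_ms = 600, prime_ms = 200, target_ms = 150,
      post_mask_ms = 300, response_deadline_ms = 500,
      collection_window_ms = 650, payoff = NULL),
    fpst = list(
      objects = c("unarmed", "armed"), signal_object = "armed",
      congruent = c(black = "armed", white = "unarmed"),
      trials_per_cell = 23, gated = "target",
      pre_stimulus_mask_ms = 450, prime_ms = NA_real_, target_ms = 200,
      post_mask_ms = 0, response_deadline_ms = 650,
      collection_window_ms = 1000,
      payoff = c(hit = 10, correct_rejection = 5, false_alarm = -20,
                 miss = -40, timeout = -10)),
    sfit = list(
      objects = c("fruit", "sport"), signal_object = "sport",
      congruent = c(black = "sport", white = "fruit"),
      trials_per_cell = 33, gated = "prime",
      pre_stimulus_mask_ms = 600, prime_ms = 200, target_ms = 150,
      post_mask_ms = 300, response_deadline_ms = 500,
      collection_window_ms = 650, payoff = NULL))
  if (!is.null(trials_per_cell)) {
    stopifnot(trials_per_cell >= 1)
    base$trials_per_cell <- as.integer(trials_per_cell)
  }
  spec <- c(list(task = task, primes = c("black", "white"),
                 phases = c("systole", "diastole"),
                 min_beats_between_trials = 4),
            base)
  spec$n_cells <- 8L
  spec$n_trials <- spec$n_cells * spec$trials_per_cell
  structure(spec, class = "design_spec")
}

#' Factorial cells of a design
#'
#' @param design A [design_spec()] object.
#' @return A tibble with one row per cell: `prime`, `object`,
#'   `intended_phase`, and `congruent` (whether the prime-object pairing
#'   matches the stereotypical association).
#' @export
design_cells <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  tidyr::expand_grid(prime = design$primes, object = design$objects,
                     intended_phase = design$phases) |>
    dplyr::mutate(congruent = unname(design$congruent[.data$prime] == .data$object))
}

#' Behavioural response model parameters
#'
#' Per-cell Bernoulli accuracy with a lognormal response-latency model.
#' `p_correct` gives the probability of a correct response in each
#' prime x object x phase cell (see [p_correct_cells()] for structured
#' presets); a response is "on time" when it is produced at all
#' (probability `1 - miss_rate`) and its latency does not exceed the
#' design's collection window. Late and absent responses count against
#' accuracy downstream.
#'
#' @param p_correct Tibble with columns `prime`, `object`,
#'   `intended_phase`, `p_correct` covering all 8 cells (as from
#'   [p_correct_cells()]).
#' @param miss_rate Probability that no response is produced at all.
#' @param rt_mean,rt_sd Mean and SD of the response-latency distribution in
#'   ms (lognormal, moment-matched).
#' @return A `behavior_params` object.
#' @export
behavior_params <- function(p_correct, miss_rate = 0.02,
                            rt_mean = 420, rt_sd = 80) {
  stopifnot(is.data.frame(p_correct),
            all(c("prime", "object", "intended_phase", "p_correct") %in%
                  names(p_correct)))
  if (any(p_correct$p_correct < 0 | p_correct$p_correct > 1)) {
    abort("All cell probabilities must lie in [0, 1].")
  }
  if (miss_rate < 0 || miss_rate > 1) abort("`miss_rate` must be in [0, 1].")
  if (rt_mean <= 0 || rt_sd <= 0) abort("Latency moments must be positive.")
  # moment-matched lognormal
  sdlog <- sqrt(log(1 + (rt_sd / rt_mean)^2))
  meanlog <- log(rt_mean) - sdlog^2 / 2
  structure(list(p_correct = as_tibble(p_correct), miss_rate = miss_rate,
                 rt_mean = rt_mean, rt_sd = rt_sd,
                 rt_meanlog = meanlog, rt_sdlog = sdlog),
            class = "behavior_params")
}

#' Structured per-cell accuracy maps
#'
#' Builds the 8-cell `p_correct` table from a baseline accuracy and a
#' congruency gap per cardiac phase: stereotype-congruent cells sit at
#' `baseline + gap/2` and incongruent cells at `baseline - gap/2`. The
#' presets encode the three generator regimes used for calibration:
#'
#' * `effect = "systolic_bias"` — congruency gap at systole only
#'   (default 0.09), mirroring a threat-stereotype effect that is present
#'   when baroreceptor firing is maximal and absent at diastole. This
#'   produces a prime x object x phase three-way interaction plus the
#'   overall prime x object effect.
#' * `effect = "phase_invariant"` — the same congruency gap at both
#'   phases (default 0.05): a prime x object effect with no cardiac
#'   modulation, the pattern of the positive Black-athletic association.
#' * `effect = "null"` — all cells at `baseline`.
#'
#' @param design A [design_spec()] object.
#' @param effect Preset name, or pass `gap_systole`/`gap_diastole`
#'   directly.
#' @param baseline Accuracy of an unbiased cell.
#' @param gap_systole,gap_diastole Congruent-minus-incongruent accuracy
#'   gap at each phase; `NULL` takes the preset's default.
#' @return A tibble of 8 rows: `prime`, `object`, `intended_phase`,
#'   `congruent`, `p_correct`.
#' @export
p_correct_cells <- function(design,
                            effect = c("systolic_bias", "phase_invariant",
                                       "null"),
                            baseline = 0.85,
                            gap_systole = NULL, gap_diastole = NULL) {
  effect <- match.arg(effect)
  defaults <- switch(effect,
    systolic_bias = c(systole = 0.09, diastole = 0),
    phase_invariant = c(systole = 0.05, diastole = 0.05),
    null = c(systole = 0, diastole = 0))
  gs <- gap_systole %||% defaults[["systole"]]
  gd <- gap_diastole %||% defaults[["diastole"]]
  design_cells(design) |>
    dplyr::mutate(
      gap = ifelse(.data$intended_phase == "systole", gs, gd),
      p_correct = baseline + ifelse(.data$congruent, 1, -1) * .data$gap / 2) |>
    dplyr::select(-"gap")
}
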