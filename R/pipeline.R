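#' Condition means across subjects
#'
#' Group-level mean accuracy (and its standard error across subjects) per
#' prime x object x phase cell — the condition-mean summary typically
#' shown as a bar chart alongside the cumulative onset curves.
#'
#' @param accuracy Output of [accuracy_table()].
#' @return A tibble: `prime`, `object`, `phase`, `n_subjects`,
#'   `mean_accuracy`, `se`.
#' @export
condition_means <- function(accuracy) {
  accuracy |>
    dplyr::group_by(.data$prime, .data$object, .data$phase) |>
    dplyr::summarise(n_subjects = sum(!is.na(.data$accuracy)),
                     mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
                     se = sd(.data$accuracy, na.rm = TRUE) /
                       sqrt(.data$n_subjects),
                     .groups = "drop")
}

#' Run the full simulate -> gate -> recode -> metrics -> stats pipeline
#'
#' One call chains every stage of a cardiac-gated study: cohort simulation
#' (heartbeats, closed-loop gating, recoding, responses), exclusion
#' accounting, per-subject accuracies, SDT and PDP indices, the
#' prime x object x phase repeated-measures ANOVA on accuracy, the
#' prime x phase ANOVAs on d', C, PDP-control and PDP-automatic, planned
#' paired contrasts at each phase, Newman-Keuls-corrected pairwise
#' comparisons of the eight condition means, cumulative onset curves, and
#' (for the FPST) per-subject point totals. Deterministic under `seed`.
#'
#' @param study `"wit"`, `"fpst"` or `"sfit"`.
#' @param n_subjects Cohort size (default 30).
#' @param seed Integer seed.
#' @param effect Generator regime passed to [p_correct_cells()], or a
#'   ready-made `p_correct` tibble via `config$p_correct`.
#' @param config Optional named list (or path to a YAML file, see
#'   [read_config()]) overriding generator settings: entries `heart`
#'   (arguments to [heart_model_params()]), `behavior` (arguments to
#'   [behavior_params()] except `p_correct`), `p_correct` (explicit 8-cell
#'   table), `gating` (arguments to [gating_params()]),
#'   `trials_per_cell`, `baseline`, `gap_systole`, `gap_diastole`.
#' @return A list of class `cg_report`: `design`, `cohort`, `exclusions`
#'   (pooled and per-subject rates), `onset_curves`, `accuracy`,
#'   `condition_means`, `sdt`, `pdp`, `anova_accuracy`, `anova_sdt`,
#'   `anova_pdp`, `contrasts`, `posthoc`, and `points` (FPST only).
#' @export
run_pipeline <- function(study = c("wit", "fpst", "sfit"), n_subjects = 30,
                         seed = 1, effect = "systolic_bias",
                         config = NULL) {
  study <- match.arg(study)
  if (is.character(config)) config <- read_config(config)
  config <- config %||% list()

  design <- design_spec(study, trials_per_cell = config$trials_per_cell)
  heart <- do.call(heart_model_params, config$heart %||% list())
  gating <- do.call(gating_params, c(
    list(min_beats_between_trials = design$min_beats_between_trials),
    config$gating %||% list()))
  p_correct <- config$p_correct %||% do.call(p_correct_cells, c(
    list(design = design, effect = effect),
    config[intersect(names(config),
                     c("baseline", "gap_systole", "gap_diastole"))]))
  behavior <- do.call(behavior_params, c(list(p_correct = p_correct),
                                         config$behavior %||% list()))

  cohort <- simulate_cohort(design, heart, behavior, n_subjects,
                            seed = seed, gating = gating)
  trials <- cohort$trials
  exclusions <- list(pooled = exclusion_rate(trials),
                     per_subject = exclusion_rate(trials, by = "subject"))
  curves <- cumulative_onset(trials)
  acc <- accuracy_table(trials, design)
  sdt <- sdt_table(acc, design)
  pdp <- pdp_table(acc, design)

  anova_accuracy <- rm_anova_2x2x2(acc)
  # degenerate subjects (e.g. PDP control = 1, automatic undefined) make a
  # two-way fit impossible; report NULL rather than fake values
  two_way <- function(d, v) {
    tryCatch(rm_anova_within(d, v, c("prime", "phase")),
             error = function(e) NULL)
  }
  anova_sdt <- list(d_prime = two_way(sdt, "d_prime"),
                    criterion_c = two_way(sdt, "criterion_c"))
  anova_pdp <- list(control = two_way(pdp, "control"),
                    automatic = two_way(pdp, "automatic"))

  # planned contrasts: signal- and noise-object identification after
  # black vs white primes, separately at each phase
  contrasts <- tidyr::expand_grid(obj = design$objects,
                                  ph = design$phases) |>
    purrr::pmap(function(obj, ph) {
      sub <- acc |>
        dplyr::filter(.data$object == obj, .data$phase == ph) |>
        tidyr::pivot_wider(id_cols = "subject", names_from = "prime",
                           values_from = "accuracy")
      paired_t_contrast(sub$black, sub$white,
                        label = sprintf("%s: black - white @ %s", obj, ph))
    }) |>
    purrr::list_rbind()

  posthoc <- newman_keuls(
    acc |> dplyr::mutate(cellname = paste(.data$prime, .data$object,
                                          .data$phase, sep = ".")),
    dv = "accuracy", condition = "cellname")

  out <- list(design = design, cohort = cohort, exclusions = exclusions,
              onset_curves = curves, accuracy = acc,
              condition_means = condition_means(acc),
              sdt = sdt, pdp = pdp,
              anova_accuracy = anova_accuracy,
              anova_sdt = anova_sdt, anova_pdp = anova_pdp,
              contrasts = contrasts, posthoc = posthoc)
  if (study == "fpst") out$points <- fpst_points(trials, design)
  class(out) <- "cg_report"
  out
}

#' @export
print.cg_report <- function(x, ...) {
  d <- x$design
  cat(sprintf("== %s: %d subjects x %d trials ==\n", toupper(d$task),
              length(unique(x$accuracy$subject)), d$n_trials))
  cat(sprintf("Pooled exclusion rate: %.2f%%\n", 100 * x$exclusions$pooled))
  cat("\nAccuracy ANOVA (prime x object x phase):\n")
  print(x$anova_accuracy)
  cat("\nPlanned contrasts:\n")
  ct <- x$contrasts |>
    dplyr::mutate(statistic = round(.data$statistic, 2),
                  p_value = signif(.data$p_value, 3),
                  cohen_d = round(.data$cohen_d, 3))
  print(as.data.frame(ct[c("comparison", "statistic", "df", "p_value",
                           "cohen_d")]), row.names = FALSE)
  invisible(x)
}

#' Bar chart of condition means
#'
#' @param report A `cg_report` from [run_pipeline()], or a
#'   [condition_means()] tibble.
#' @return A ggplot.
#' @export
plot_condition_means <- function(report) {
  cm <- if (inherits(report, "cg_report")) report$condition_means else report
  ggplot2::ggplot(cm, ggplot2::aes(.data$prime, .data$mean_accuracy,
                                   fill = .data$phase)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$se,
                   ymax = .data$mean_accuracy + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::facet_wrap(~object) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = "Prime", y = "Mean accuracy", fill = "Cardiac phase") +
    ggplot2::theme_minimal()
}
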