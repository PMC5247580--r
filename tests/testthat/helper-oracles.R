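# Independent oracles and fixtures shared across tests.

# Brute-force repeated-measures sums of squares by inclusion-exclusion over
# margin means: for an effect given by a set of factor columns, each
# observation's deviation is sum_{T subseteq S} (-1)^{|S|-|T|} mean_T(obs),
# and SS = sum of squared deviations over all observations. The error term
# of a within-subject effect S is the SS of S union {subject}. This shares
# no code with rm_anova_within().
bf_margin <- function(df, dv, cols) {
  if (length(cols) == 0) return(rep(mean(df[[dv]]), nrow(df)))
  do.call(stats::ave, c(list(df[[dv]]), df[cols], list(FUN = mean)))
}

bf_effect_ss <- function(df, dv, cols) {
  dev <- rep(0, nrow(df))
  for (k in 0:length(cols)) {
    subsets <- utils::combn(cols, k, simplify = FALSE)
    for (s in subsets) {
      dev <- dev + (-1)^(length(cols) - k) * bf_margin(df, dv, s)
    }
  }
  sum(dev^2)
}

bf_rm_anova <- function(df, dv, within, subject = "subject") {
  n <- length(unique(df[[subject]]))
  effects <- unlist(lapply(seq_along(within), function(k) {
    utils::combn(within, k, simplify = FALSE)
  }), recursive = FALSE)
  do.call(rbind, lapply(effects, function(S) {
    ss_eff <- bf_effect_ss(df, dv, S)
    ss_err <- bf_effect_ss(df, dv, c(S, subject))
    f <- ss_eff / (ss_err / (n - 1))
    data.frame(effect = paste(S, collapse = ":"),
               ss_effect = ss_eff, ss_error = ss_err,
               statistic = f,
               p_value = stats::pf(f, 1, n - 1, lower.tail = FALSE))
  }))
}

# A fixed toy 4-subject x 8-cell accuracy table (values chosen irregular,
# no structure).
toy_accuracy <- function() {
  vals <- c(0.91, 0.78, 0.85, 0.69, 0.88, 0.95, 0.72, 0.81,
            0.84, 0.90, 0.66, 0.77, 0.93, 0.70, 0.89, 0.80,
            0.75, 0.83, 0.92, 0.88, 0.67, 0.86, 0.79, 0.94,
            0.82, 0.71, 0.87, 0.90, 0.76, 0.68, 0.96, 0.85)
  cells <- expand.grid(phase = c("systole", "diastole"),
                       object = c("tool", "weapon"),
                       prime = c("black", "white"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(1:4, function(s) {
    cbind(data.frame(subject = s), cells)
  }))
  out$accuracy <- vals
  out
}

# Random complete within-subject dataset on the 8-cell design.
random_accuracy <- function(n_subjects = 12) {
  cells <- expand.grid(phase = c("systole", "diastole"),
                       object = c("tool", "weapon"),
                       prime = c("black", "white"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    cbind(data.frame(subject = s), cells)
  }))
  out$accuracy <- stats::rnorm(nrow(out), 0.8, 0.1) +
    rep(stats::rnorm(n_subjects, 0, 0.05), each = 8)
  out
}

# Default WIT generator objects used across tests.
wit_default <- function(effect = "systolic_bias") {
  d <- design_spec("wit")
  list(design = d,
       heart = heart_model_params(mean_ibi = 850, sdnn = 30, ar1 = 0),
       behavior = behavior_params(p_correct_cells(d, effect)))
}
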