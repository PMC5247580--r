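#' Fully within-subject repeated-measures ANOVA for 2-level factors
#'
#' Exact sums-of-squares decomposition for designs in which every factor
#' has two levels and every subject contributes one observation per cell
#' (1 to 3 factors, so 2 to 8 cells). Each effect is a +/-1 difference
#' contrast over the cells; its sum of squares is `(sum_i L_i)^2 / (c n)`
#' with `L_i` the subject's contrast score and `c` the number of cells,
#' and it is tested against its own effect-by-subject interaction
#' (`SS_err = sum_i (L_i - mean(L))^2 / c`, df `n - 1`). For 2-level
#' factors this is algebraically identical to the classical
#' cell-mean decomposition, and each F equals the squared paired t of the
#' corresponding difference score — sphericity is trivially satisfied, so
#' no correction is applied.
#'
#' @param data Long data frame with one row per subject x cell.
#' @param dv Name of the response column (string).
#' @param within Character vector of 1-3 within-subject factor names, each
#'   with exactly two levels.
#' @param subject Name of the subject identifier column.
#' @return An object of class `cg_rm_anova`; its `tidy()` method returns
#'   one row per effect with `ss_effect`, `ss_error`, `df1`, `df2`,
#'   `statistic` (F), `p_value` and `partial_eta_sq`
#'   (= SS_effect / (SS_effect + SS_error)).
#' @export
rm_anova_within <- function(data, dv, within, subject = "subject") {
  stopifnot(is.character(dv), length(dv) == 1,
            is.character(within), length(within) >= 1, length(within) <= 3)
  need <- c(subject, within, dv)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  levs <- purrr::map(within, ~ sort(unique(data[[.x]])))
  n_lev <- purrr::map_int(levs, length)
  if (any(n_lev != 2)) {
    abort("Every within-subject factor must have exactly two levels.")
  }

  wide <- data |>
    dplyr::select(dplyr::all_of(need)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(within))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(within),
                       values_from = dplyr::all_of(dv),
                       names_sep = ".")
  y <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(y)) {
    bad <- wide[[subject]][apply(y, 1, anyNA)]
    abort(paste0("Incomplete cells for subject(s): ",
                 paste(bad, collapse = ", ")))
  }
  n <- nrow(y)
  if (n < 2) abort("At least two subjects are required.")
  n_cells <- ncol(y)

  # cell order from pivot_wider: last factor varies fastest
  cell_levels <- purrr::map(seq_along(within), function(j) {
    each <- prod(n_lev[-seq_len(j)] %||% 1)
    rep(rep(levs[[j]], each = max(each, 1)),
        length.out = n_cells)
  })
  half <- purrr::map(cell_levels, ~ ifelse(.x == .x[1], 1, -1))

  effects <- unlist(purrr::map(seq_along(within), function(k) {
    utils::combn(seq_along(within), k, simplify = FALSE)
  }), recursive = FALSE)

  rows <- purrr::map(effects, function(idx) {
    contrast <- Reduce(`*`, half[idx])
    L <- as.numeric(y %*% contrast)
    ss_eff <- sum(L)^2 / (n_cells * n)
    ss_err <- sum((L - mean(L))^2) / n_cells
    f <- if (ss_err == 0) {
      if (ss_eff == 0) NaN else Inf
    } else ss_eff / (ss_err / (n - 1))
    tibble(
      effect = paste(within[idx], collapse = ":"),
      ss_effect = ss_eff, ss_error = ss_err,
      df1 = 1L, df2 = n - 1L, statistic = f,
      p_value = stats::pf(f, 1, n - 1, lower.tail = FALSE),
      partial_eta_sq = if (ss_eff + ss_err == 0) NaN
                       else ss_eff / (ss_eff + ss_err))
  })
  structure(list(table = purrr::list_rbind(rows), n = n,
                 within = within, dv = dv,
                 grand_mean = mean(y)),
            class = "cg_rm_anova")
}

#' 2 x 2 x 2 within-subject ANOVA
#'
#' Convenience wrapper around [rm_anova_within()] for the canonical
#' prime x object x cardiac-phase accuracy analysis: three two-level
#' within factors, all mains, two-ways and the three-way tested against
#' their own subject-interaction error terms with df (1, n - 1).
#'
#' @inheritParams rm_anova_within
#' @export
rm_anova_2x2x2 <- function(data, dv = "accuracy",
                           within = c("prime", "object", "phase"),
                           subject = "subject") {
  if (length(within) != 3) abort("Exactly three within factors expected.")
  rm_anova_within(data, dv, within, subject)
}

#' @export
print.cg_rm_anova <- function(x, ...) {
  cat(sprintf("Within-subject ANOVA on `%s` (n = %d)\n", x$dv, x$n))
  tbl <- x$table |>
    dplyr::mutate(statistic = round(.data$statistic, 2),
                  p_value = signif(.data$p_value, 3),
                  partial_eta_sq = round(.data$partial_eta_sq, 3))
  print(as.data.frame(tbl), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.cg_rm_anova <- function(x, ...) x$table

#' @export
glance.cg_rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n, n_effects = nrow(x$table),
         grand_mean = x$grand_mean)
}

#' Planned paired contrast
#'
#' Classical two-tailed paired t-test on per-subject difference scores,
#' with paired Cohen's d = mean difference / SD of differences. If all
#' differences are zero the contrast is reported as t = 0, p = 1, d = 0;
#' a non-zero mean with zero variance yields an infinite t with a warning.
#'
#' @param x Per-subject values (or differences when `y` is `NULL`).
#' @param y Optional second paired sample.
#' @param label Comparison label carried into the output.
#' @return A one-row tibble of class `cg_contrast`: `comparison`,
#'   `estimate` (mean difference), `statistic` (t), `df`, `p_value`,
#'   `cohen_d`.
#' @examples
#' paired_t_contrast(c(1, 2, 3, 4)) # t ~ 3.873, d ~ 1.936
#' @export
paired_t_contrast <- function(x, y = NULL, label = "contrast") {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) abort("At least two paired observations are required.")
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      t_stat <- 0; p <- 1; cd <- 0
    } else {
      warn("Zero variance of differences with non-zero mean: t is infinite.")
      t_stat <- sign(m) * Inf; p <- 0; cd <- sign(m) * Inf
    }
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), n - 1)
    cd <- m / s
  }
  out <- tibble(comparison = label, estimate = m, statistic = t_stat,
                df = n - 1L, p_value = p, cohen_d = cd)
  class(out) <- c("cg_contrast", class(out))
  out
}

#' Newman-Keuls stepwise correction for pairwise comparisons
#'
#' Stepwise studentized-range procedure over rank-ordered condition means
#' of a within-subject design. The error term is the pooled
#' condition-by-subject mean square from the one-way repeated-measures
#' ANOVA of the means entering the comparison (df (n-1)(k-1)). A pair
#' spanning r rank-ordered means is tested with the studentized range at
#' `nmeans = r`; the stepwise stopping rule is enforced by giving each
#' pair a corrected p equal to the maximum p over all pairs whose rank
#' span contains it, so comparisons nested inside a non-significant range
#' inherit its non-significance and corrected p never falls below the
#' pair's own range p. With two conditions the procedure reduces to a
#' single range test with q = t * sqrt(2).
#'
#' @param data Long data frame with one row per subject x condition.
#' @param dv Response column name.
#' @param condition Condition column name.
#' @param subject Subject column name.
#' @param method `"newman_keuls"` (default) or `"holm"` (Holm-adjusted
#'   pairwise paired t-tests, offered as a conservative alternative).
#' @return A tibble with one row per pair: `comparison`, `mean_diff`,
#'   `span` (number of rank-ordered means covered), `q` (or t), `df`,
#'   `p_value` (own-range p), `p_corrected`.
#' @export
newman_keuls <- function(data, dv, condition, subject = "subject",
                         method = c("newman_keuls", "holm")) {
  method <- match.arg(method)
  need <- c(subject, condition, dv)
  stopifnot(all(need %in% names(data)))
  wide <- data |>
    dplyr::select(dplyr::all_of(need)) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(condition),
                       values_from = dplyr::all_of(dv))
  y <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(y)) abort("Each subject must have a value for every condition.")
  n <- nrow(y); k <- ncol(y)
  if (n <= 1) abort("More than one subject is required.")
  if (k < 2) abort("At least two condition means are required.")

  cond_means <- colMeans(y)
  ord <- order(cond_means)
  means_sorted <- cond_means[ord]
  labels_sorted <- colnames(y)[ord]

  if (method == "holm") {
    pairs <- utils::combn(k, 2, simplify = FALSE)
    rows <- purrr::map(pairs, function(p) {
      ct <- paired_t_contrast(y[, ord[p[2]]], y[, ord[p[1]]],
        label = paste(labels_sorted[p[2]], "-", labels_sorted[p[1]]))
      tibble(comparison = ct$comparison, mean_diff = ct$estimate,
             span = p[2] - p[1] + 1L, q = ct$statistic, df = ct$df,
             p_value = ct$p_value)
    })
    out <- purrr::list_rbind(rows)
    out$p_corrected <- stats::p.adjust(out$p_value, "holm")
    return(out)
  }

  # pooled within-subject error: residual of the additive subject+condition fit
  resid <- y - outer(rowMeans(y), rep(1, k)) -
    outer(rep(1, n), cond_means) + mean(y)
  df_err <- (n - 1) * (k - 1)
  mse <- sum(resid^2) / df_err
  se <- sqrt(mse / n)

  p_mat <- matrix(NA_real_, k, k)
  q_mat <- matrix(NA_real_, k, k)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      q <- (means_sorted[j] - means_sorted[i]) / se
      q_mat[i, j] <- q
      p_mat[i, j] <- ptukey(q, nmeans = j - i + 1, df = df_err,
                            lower.tail = FALSE)
    }
  }
  # stepwise inheritance: max p over containing spans
  p_adj <- p_mat
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      containing <- p_mat[1:i, j:k, drop = FALSE]
      p_adj[i, j] <- max(containing, na.rm = TRUE)
    }
  }
  idx <- which(upper.tri(p_mat), arr.ind = TRUE)
  tibble(
    comparison = paste(labels_sorted[idx[, 2]], "-", labels_sorted[idx[, 1]]),
    mean_diff = means_sorted[idx[, 2]] - means_sorted[idx[, 1]],
    span = idx[, 2] - idx[, 1] + 1L,
    q = q_mat[idx], df = df_err,
    p_value = p_mat[idx],
    p_corrected = p_adj[idx]) |>
    dplyr::arrange(dplyr::desc(.data$span), .data$comparison)
}
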