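test_that("designs carry the canonical trial economies", {
  wit <- design_spec("wit")
  expect_equal(wit$n_trials, 264)
  expect_equal(wit$trials_per_cell, 33)
  expect_equal(wit$prime_ms, 200)
  expect_equal(wit$target_ms, 150)
  expect_equal(wit$response_deadline_ms, 500)
  expect_equal(wit$collection_window_ms, 650)
  expect_equal(wit$min_beats_between_trials, 4)

  fpst <- design_spec("fpst")
  expect_equal(fpst$trials_per_cell, 23)
  expect_equal(fpst$n_trials, 184) # 8 x 23; per-cell count is primitive
  expect_equal(fpst$response_deadline_ms, 650)
  expect_equal(fpst$collection_window_ms, 1000)
  expect_equal(unname(fpst$payoff[c("hit", "correct_rejection",
                                    "false_alarm", "miss", "timeout")]),
               c(10, 5, -20, -40, -10))

  expect_equal(design_spec("sfit")$objects, c("fruit", "sport"))
  expect_equal(nrow(design_cells(wit)), 8)
  expect_equal(sum(design_cells(wit)$congruent), 4)
})

test_that("every generated log has the design's per-cell trial counts", {
  w <- wit_default()
  coh <- simulate_cohort(w$design, w$heart, w$behavior,
                         n_subjects = 3, seed = 101)
  counts <- dplyr::count(coh$trials, subject, prime, object, intended_phase)
  expect_equal(nrow(counts), 3 * 8)
  expect_true(all(counts$n == 33))
  expect_equal(nrow(coh$trials), 3 * 264)
})

test_that("cohort generation is byte-identical under a fixed seed", {
  w <- wit_default()
  a <- simulate_cohort(w$design, w$heart, w$behavior, 2, seed = 55)
  b <- simulate_cohort(w$design, w$heart, w$behavior, 2, seed = 55)
  expect_identical(a$trials, b$trials)
  expect_identical(a$rwaves, b$rwaves)
})

test_that("a perfect responder yields accuracy 1 everywhere", {
  d <- design_spec("wit", trials_per_cell = 5)
  b <- behavior_params(p_correct_cells(d, "null", baseline = 1),
                       miss_rate = 0, rt_mean = 300, rt_sd = 20)
  coh <- simulate_cohort(d, heart_model_params(sdnn = 0), b, 2, seed = 1)
  acc <- accuracy_table(coh$trials)
  expect_true(all(acc$accuracy == 1))
})

test_that("pipeline accuracy recovers the generating cell probabilities", {
  d <- design_spec("wit")
  b <- behavior_params(p_correct_cells(d, "systolic_bias"), miss_rate = 0,
                       rt_mean = 380, rt_sd = 60)
  coh <- simulate_cohort(d, heart_model_params(), b, 60, seed = 7)
  pooled <- accuracy_table(coh$trials) |>
    dplyr::group_by(prime, object, phase) |>
    dplyr::summarise(n = sum(n_trials), acc = sum(n_correct) / sum(n_trials),
                     .groups = "drop") |>
    dplyr::left_join(
      dplyr::rename(b$p_correct, phase = "intended_phase"),
      by = c("prime", "object", "phase"))
  # on-time rate scales expected accuracy: p_correct * P(rt <= window)
  on_time <- stats::plnorm(d$collection_window_ms,
                           b$rt_meanlog, b$rt_sdlog)
  err <- abs(pooled$acc - pooled$p_correct * on_time)
  tol <- 3 * sqrt(pooled$p_correct * (1 - pooled$p_correct) / pooled$n)
  expect_true(all(err < pmax(tol, 0.01)))
})

test_that("cell-count fast path matches the binomial marginal", {
  p <- p_correct_cells(design_spec("wit"), "null", baseline = 0.8)
  cc <- simulate_cell_counts(p, n_subjects = 1000, n_trials = 33, seed = 3)
  grand <- mean(cc$accuracy)
  se <- sqrt(0.8 * 0.2 / (1000 * 8 * 33))
  expect_lt(abs(grand - 0.8), 3 * se)
  expect_true(all(cc$n_correct >= 0 & cc$n_correct <= 33))
})

test_that("degenerate cohorts are rejected", {
  w <- wit_default()
  expect_error(simulate_cohort(w$design, w$heart, w$behavior, 1), "at least 2")
  expect_error(behavior_params(p_correct_cells(w$design) |>
                                 dplyr::mutate(p_correct = 1.2)),
               "\\[0, 1\\]")
})
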