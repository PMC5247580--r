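make_trials <- function(n_correct, n_late, n_total, subject = 1,
                        prime = "black", object = "weapon",
                        phase = "systole") {
  n_wrong <- n_total - n_correct - n_late
  tibble::tibble(
    subject = subject, prime = prime, object = object,
    recoded_phase = phase,
    on_time = rep(c(TRUE, FALSE, TRUE), c(n_correct, n_late, n_wrong)),
    correct = rep(c(TRUE, FALSE, FALSE), c(n_correct, n_late, n_wrong)))
}

test_that("accuracy is on-time correct over cell trials", {
  acc <- accuracy_table(make_trials(30, 0, 33), design_spec("wit"))
  expect_equal(acc$accuracy[!is.na(acc$accuracy)], 30 / 33,
               tolerance = 1e-12)
  # 33 responses all correct but 3 late -> 30/33
  late <- make_trials(30, 3, 33)
  acc2 <- accuracy_table(late)
  expect_equal(acc2$accuracy[!is.na(acc2$accuracy)], 30 / 33)
  # excluded trials never enter the denominator
  acc3 <- accuracy_table(dplyr::bind_rows(
    make_trials(30, 0, 33),
    dplyr::mutate(make_trials(5, 0, 5), recoded_phase = "excluded")))
  expect_equal(acc3$n_trials[acc3$prime == "black" &
                               acc3$object == "weapon" &
                               acc3$phase == "systole"], 33L)
  # empty cells surface as NA, not 0
  expect_true(anyNA(acc$accuracy))
  expect_false(any(acc$accuracy == 0, na.rm = TRUE))
})

test_that("SDT indices match normal-quantile arithmetic", {
  chance <- sdt_indices(0.5, 0.5, 33, 33)
  expect_equal(chance$d_prime, 0)
  expect_equal(chance$criterion_c, 0)

  v <- sdt_indices(0.69, 0.31, 33, 33)
  expect_lt(abs(v$d_prime - 0.992), 0.001)
  expect_lt(abs(v$criterion_c), 1e-10)

  # 1/(2N) correction pulls rate 1 to 1 - 1/(2N)
  v2 <- sdt_indices(1, 0.2, 33, 33)
  expect_equal(v2$hit_rate_adj, 65 / 66)
  expect_equal(v2$d_prime, qnorm(65 / 66) - qnorm(0.2))

  expect_error(sdt_indices(0.7, 0.3, 0, 33), "positive")
  expect_error(sdt_indices(1.1, 0.3, 33, 33), "\\[0, 1\\]")
})

test_that("d' vanishes when H equals F; C is antisymmetric under swap", {
  for (r in c(0.2, 0.5, 0.77)) {
    v <- sdt_indices(r, r, 40, 40)
    expect_equal(v$d_prime, 0, tolerance = 1e-12)
  }
  a <- sdt_indices(0.8, 0.3, 40, 40)
  b <- sdt_indices(0.7, 0.2, 40, 40) # (1-F, 1-H)
  expect_equal(a$criterion_c, -b$criterion_c, tolerance = 1e-12)
  expect_equal(a$d_prime, b$d_prime, tolerance = 1e-12)
})

test_that("sdt_table uses the task's signal roles without bookkeeping drift", {
  d <- design_spec("wit")
  acc <- tidyr::expand_grid(subject = 1:2, prime = c("black", "white"),
                            object = c("tool", "weapon"),
                            phase = c("systole", "diastole")) |>
    dplyr::mutate(n_trials = 33L,
                  accuracy = c(rep(0.8, 8), rep(0.7, 8)),
                  n_correct = round(accuracy * 33))
  s <- sdt_table(acc, d)
  expect_equal(nrow(s), 2 * 2 * 2)
  expect_equal(s$hit_rate[s$subject == 1], rep(0.8, 4))
  expect_equal(s$fa_rate[s$subject == 1], rep(0.2, 4))
  expect_equal(s$d_prime[s$subject == 1],
               rep(qnorm(0.8) - qnorm(0.2), 4))
})

test_that("PDP control and automatic estimates follow the definitions", {
  v <- pdp_indices(0.95, 0.35)
  expect_equal(v$control, 0.6)
  expect_equal(v$automatic, 0.875)
  expect_equal(pdp_indices(0.9, 0)$automatic, 0)
  deg <- pdp_indices(1, 0)
  expect_equal(deg$control, 1)
  expect_true(is.na(deg$automatic))
  expect_error(pdp_indices(1.2, 0.3), "\\[0, 1\\]")
})

test_that("PDP recovers the generating process model", {
  # respond via control with probability c, else via automatic bias a
  set.seed(31)
  c_true <- 0.6; a_true <- 0.4; n <- 1e5
  ctl <- runif(n) < c_true
  auto <- runif(n) < a_true
  acc_con <- mean(ctl | auto)      # congruent: bias produces the correct key
  err_inc <- mean(!ctl & auto)     # incongruent: bias produces the error
  est <- pdp_indices(acc_con, err_inc)
  expect_lt(abs(est$control - c_true), 0.02)
  expect_lt(abs(est$automatic - a_true), 0.02)
})

test_that("FPST points follow the payoff matrix and the 650 ms deadline", {
  base <- tibble::tibble(subject = 1, object = "armed", correct = TRUE,
                         rt_ms = 400)
  expect_equal(fpst_points(base)$points, 10)
  two <- tibble::tibble(subject = 1, object = c("unarmed", "armed"),
                        correct = FALSE, rt_ms = c(500, 520))
  expect_equal(fpst_points(two)$points, -60) # -20 + -40
  timeouts <- tibble::tibble(subject = 1, object = "armed", correct = TRUE,
                             rt_ms = rep(NA_real_, 10))
  expect_equal(fpst_points(timeouts)$points, -100)
  # a correct response after the deadline but inside the collection window
  # scores as a timeout
  late <- tibble::tibble(subject = 1, object = "unarmed", correct = TRUE,
                         rt_ms = 800)
  expect_equal(fpst_points(late)$points, -10)
  expect_equal(fpst_points(dplyr::mutate(base, rt_ms = 650))$points, 10)
  expect_error(fpst_points(dplyr::mutate(base, object = "alien")),
               "Unknown object")
})
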