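test_that("contrast-based ANOVA matches the brute-force SS oracle", {
  toy <- toy_accuracy()
  fit <- tidy(rm_anova_2x2x2(toy))
  oracle <- bf_rm_anova(toy, "accuracy", c("prime", "object", "phase"))
  for (eff in fit$effect) {
    a <- fit[fit$effect == eff, ]
    # oracle builds effect names in its own subset order
    key <- strsplit(eff, ":")[[1]]
    b <- oracle[vapply(strsplit(oracle$effect, ":"), function(x) {
      setequal(x, key)
    }, logical(1)), ]
    expect_lt(abs(a$ss_effect - b$ss_effect) / b$ss_effect, 1e-10)
    expect_lt(abs(a$ss_error - b$ss_error) / b$ss_error, 1e-10)
    expect_lt(abs(a$statistic - b$statistic) / b$statistic, 1e-10)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
  }
})

test_that("ANOVA agrees with base aov error strata on random data", {
  set.seed(77)
  d <- random_accuracy(10)
  d[c("prime", "object", "phase")] <-
    lapply(d[c("prime", "object", "phase")], factor)
  d$subject <- factor(d$subject)
  fit <- tidy(rm_anova_2x2x2(d))
  av <- summary(stats::aov(
    accuracy ~ prime * object * phase + Error(subject / (prime * object * phase)),
    data = d))
  for (eff in c("prime", "object", "phase", "prime:object", "prime:phase",
                "object:phase", "prime:object:phase")) {
    stratum <- av[[paste0("Error: subject:", eff)]][[1]]
    f_aov <- stratum[match(eff, trimws(rownames(stratum))), "F value"]
    expect_equal(fit$statistic[fit$effect == eff], f_aov,
                 tolerance = 1e-8)
  }
})

test_that("each within-subject F equals the squared paired t of its contrast", {
  set.seed(123)
  for (i in 1:100) {
    d <- random_accuracy(8)
    fit <- tidy(rm_anova_2x2x2(d))
    wide <- tidyr::pivot_wider(
      d, names_from = c("prime", "object", "phase"),
      values_from = "accuracy", names_sep = ".")
    # three-way: double difference of the congruency effect across phases
    dd <- with(wide,
      (black.tool.systole - black.tool.diastole) -
      (black.weapon.systole - black.weapon.diastole) -
      (white.tool.systole - white.tool.diastole) +
      (white.weapon.systole - white.weapon.diastole)) / 4
    ct <- paired_t_contrast(dd)
    f3 <- fit$statistic[fit$effect == "prime:object:phase"]
    expect_equal(f3, ct$statistic^2, tolerance = 1e-8)
    p3 <- fit$p_value[fit$effect == "prime:object:phase"]
    expect_equal(p3, ct$p_value, tolerance = 1e-8)
    # a main effect too
    dp <- with(wide,
      (black.tool.systole + black.tool.diastole + black.weapon.systole +
         black.weapon.diastole) / 4 -
      (white.tool.systole + white.tool.diastole + white.weapon.systole +
         white.weapon.diastole) / 4)
    expect_equal(fit$statistic[fit$effect == "prime"],
                 paired_t_contrast(dp)$statistic^2, tolerance = 1e-8)
  }
})

test_that("partial eta squared is SS_effect over SS_effect + SS_error", {
  fit <- tidy(rm_anova_2x2x2(toy_accuracy()))
  expect_equal(fit$partial_eta_sq,
               fit$ss_effect / (fit$ss_effect + fit$ss_error))
  expect_true(all(fit$partial_eta_sq >= 0 & fit$partial_eta_sq <= 1))
  expect_true(all(fit$statistic >= 0))
})

test_that("pure subject offsets produce zero effect SS", {
  d <- random_accuracy(6)
  d$accuracy <- rep(seq(0.5, 0.75, length.out = 6), each = 8)
  fit <- tidy(rm_anova_2x2x2(d))
  expect_true(all(abs(fit$ss_effect) < 1e-20))
})

test_that("incomplete designs fail loudly with the offending subjects", {
  d <- random_accuracy(5)[-3, ]
  expect_error(rm_anova_2x2x2(d), "Incomplete cells .* 1")
})

test_that("paired contrasts match hand arithmetic and flag degeneracy", {
  ct <- paired_t_contrast(c(1, 2, 3, 4))
  expect_equal(ct$estimate, 2.5)
  expect_equal(ct$statistic, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_lt(abs(ct$statistic - 3.873), 0.001)
  expect_lt(abs(ct$cohen_d - 1.936), 0.001)
  expect_equal(ct$df, 3L)

  zero <- paired_t_contrast(rep(0, 10))
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p_value, 1)
  expect_equal(zero$cohen_d, 0)

  expect_warning(inf <- paired_t_contrast(rep(0.3, 5)), "infinite")
  expect_true(is.infinite(inf$statistic))

  neg <- paired_t_contrast(-c(1, 2, 3, 4))
  expect_equal(neg$statistic, -ct$statistic)
  expect_equal(neg$cohen_d, -ct$cohen_d)
})

test_that("Newman-Keuls with two means reduces to the paired t", {
  set.seed(5)
  d <- data.frame(subject = rep(1:12, 2),
                  cond = rep(c("a", "b"), each = 12),
                  y = rnorm(24, rep(c(0, 0.4), each = 12), 0.3))
  nk <- newman_keuls(d, "y", "cond")
  wide <- tidyr::pivot_wider(d, names_from = "cond", values_from = "y")
  ct <- paired_t_contrast(wide$b, wide$a)
  expect_equal(nk$q, abs(ct$statistic) * sqrt(2), tolerance = 1e-10)
  expect_equal(nk$p_value, ct$p_value, tolerance = 1e-10)
  expect_equal(nk$p_corrected, nk$p_value)
})

test_that("Newman-Keuls corrected p is monotone in the stepwise ordering", {
  set.seed(6)
  for (i in 1:20) {
    d <- expand.grid(subject = 1:10, cond = letters[1:4])
    d$y <- rnorm(40, rep(c(0, 0.1, 0.25, 0.3), each = 10), 0.2) +
      rep(rnorm(10, 0, 0.1), 4)
    nk <- newman_keuls(d, "y", "cond")
    expect_true(all(nk$p_corrected >= nk$p_value - 1e-12))
    # the full-span comparison gates everything beneath it
    full <- nk$p_value[nk$span == max(nk$span)]
    expect_true(all(nk$p_corrected >= min(full)))
  }
})

test_that("Newman-Keuls familywise error sits near alpha under the null", {
  set.seed(8)
  rejections <- replicate(400, {
    d <- expand.grid(subject = 1:10, cond = letters[1:4])
    d$y <- rnorm(40) + rep(rnorm(10), 4)
    any(newman_keuls(d, "y", "cond")$p_corrected < 0.05)
  })
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)
})

test_that("Holm alternative is available and at least as conservative", {
  set.seed(9)
  d <- expand.grid(subject = 1:10, cond = letters[1:3])
  d$y <- rnorm(30, rep(c(0, 0.3, 0.6), each = 10), 0.3)
  h <- newman_keuls(d, "y", "cond", method = "holm")
  expect_true(all(h$p_corrected >= h$p_value - 1e-12))
})
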