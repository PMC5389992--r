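make_trials <- function(rates, n = 300) {
  # one subject per rate: n trials with the given choose-better rate
  do.call(rbind, lapply(seq_along(rates), function(i) {
    n_better <- round(rates[i] * n)
    ch <- c(rep("A", n_better), rep("B", n - n_better))
    data.frame(subject_id = sprintf("s%02d", i), trial_index = 1:n,
               pair = "AB", chosen = ch,
               unchosen = ifelse(ch == "A", "B", "A"),
               reward = 1L, omitted = FALSE, stringsAsFactors = FALSE)
  }))
}

test_that("chance performers are excluded by the binomial rule", {
  tr <- make_trials(c(0.5, 0.81, 1.0))
  res <- exclude_chance_performers(tr, task_design())
  expect_equal(res$excluded, "s01")   # 150/300: p ~ 0.52
  expect_true(all(c("s02", "s03") %in% res$retained))
  expect_gt(res$report$p_value[1], 0.05)
  expect_lt(res$report$p_value[2], 0.001)
  # rates just above half are still excluded at n = 300
  res2 <- exclude_chance_performers(make_trials(0.53), task_design())
  expect_equal(res2$excluded, "s01")
})

test_that("condition means, slowing scores and accuracy follow the contract", {
  cap <- data.frame(
    subject_id = "s01", trial_index = 1:6,
    condition = c("high", "high", "none", "none", "low", "low"),
    correct = TRUE,
    rt_ms = c(700, 720, 650, 670, 660, 680))
  cs <- condition_means(cap)
  expect_equal(cs$slowing_high, 50)
  expect_equal(cs$slowing_low, 10)
  expect_equal(cs$slowing_diff, 40)
  # incorrect trials drop out of the RT mean but count against accuracy
  cap2 <- rbind(cap, data.frame(subject_id = "s01", trial_index = 7,
                                condition = "high", correct = FALSE,
                                rt_ms = 5000))
  cs2 <- condition_means(cap2)
  expect_equal(cs2$mean_rt_high, 710)
  expect_equal(cs2$acc_high, 2 / 3)
  # identical RTs give zero slowing everywhere
  cap3 <- cap; cap3$rt_ms <- 600
  cs3 <- condition_means(cap3)
  expect_equal(cs3$slowing_high, 0)
  expect_equal(cs3$slowing_diff, 0)
  expect_error(condition_means(cap[cap$condition != "low", ]), "s01")
})

test_that("repeated-measures ANOVA matches brute-force SS and aov()", {
  # constant condition effect on a small table
  m <- matrix(c(1, 4, 7, 2, 5, 8, 3, 6, 9), nrow = 3)
  colnames(m) <- c("none", "low", "high")
  res <- rm_anova_oneway(m)
  orc <- oracle_rm_anova(m)
  expect_equal(res$F, orc$F, tolerance = 1e-9)
  expect_equal(res$partial_eta_sq, orc$peta, tolerance = 1e-9)

  set.seed(88)
  for (i in 1:100) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    mm <- matrix(rnorm(n * k, 600, 40), n, k) +
      outer(rep(0, n), seq_len(k) * runif(1, 0, 10))
    res <- rm_anova_oneway(mm)
    orc <- oracle_rm_anova(mm)
    expect_equal(res$F, orc$F, tolerance = 1e-9)
    expect_equal(res$p, orc$p, tolerance = 1e-9)
    expect_equal(res$partial_eta_sq, orc$peta, tolerance = 1e-9)
  }

  # cross-check against aov() with a within-subject error stratum
  set.seed(89)
  mm <- matrix(rnorm(60, 600, 30), 20, 3) +
    matrix(rep(c(0, 5, 12), each = 20), 20, 3)
  long <- data.frame(y = as.vector(mm),
                     subj = factor(rep(1:20, 3)),
                     cond = factor(rep(1:3, each = 20)))
  av <- summary(aov(y ~ cond + Error(subj/cond), data = long))
  ftab <- av[["Error: subj:cond"]][[1]]
  res <- rm_anova_oneway(mm)
  expect_equal(res$F, ftab["cond", "F value"], tolerance = 1e-9)
  expect_equal(res$p, ftab["cond", "Pr(>F)"], tolerance = 1e-9)
  expect_equal(res$df_effect, 2L)
  expect_equal(res$df_error, 38L)

  # all condition means equal within subject: F = 0
  eqm <- matrix(rep(rnorm(5, 600, 10), 3), 5, 3)
  expect_equal(rm_anova_oneway(eqm)$F, 0)
})

test_that("linear trend is the squared one-sample t of the end contrast", {
  set.seed(90)
  m <- matrix(rnorm(60, 600, 20), 20, 3)
  colnames(m) <- c("none", "low", "high")
  res <- linear_trend(m)
  ctr <- m[, "high"] - m[, "none"]
  tt <- t.test(ctr)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)
  expect_equal(res$df_effect, 1L)
  expect_equal(res$df_error, 19L)
  # equal condition means: F = 0
  m0 <- matrix(rep(rnorm(6, 600, 5), 3), 6, 3)
  colnames(m0) <- c("none", "low", "high")
  expect_equal(linear_trend(m0)$F, 0)
  # zero-noise constant effect is flagged degenerate with p -> 0
  md <- cbind(none = rep(600, 6), low = rep(610, 6), high = rep(620, 6))
  resd <- linear_trend(md)
  expect_true(resd$degenerate)
  expect_equal(resd$p, 0)
  expect_error(linear_trend(m[, 1:2]), "3 conditions")
})

test_that("pairwise Bonferroni tests match hand arithmetic", {
  # differences (10, 12, 8, 10): mean 10, sd 1.633, t = 12.25 on df 3
  a <- c(110, 112, 108, 110); b <- rep(100, 4)
  res <- pairwise_bonferroni(cbind(x = a, y = b))
  expect_equal(res$t, 10 / (sd(a - b) / 2), tolerance = 1e-9)
  expect_equal(res$t, 12.247, tolerance = 1e-3)
  expect_equal(res$df, 3)
  # identical columns: t = 0, corrected p = 1
  res0 <- pairwise_bonferroni(cbind(x = a, y = a))
  expect_equal(res0$t, 0)
  expect_equal(res0$p_bonferroni, 1)
  # corrected p never below raw p; cap at 1
  set.seed(91)
  m <- matrix(rnorm(30, 600, 20), 10, 3)
  res3 <- pairwise_bonferroni(m)
  expect_equal(nrow(res3), 3)
  expect_true(all(res3$p_bonferroni >= res3$p_raw))
  expect_true(all(res3$p_bonferroni <= 1))
  expect_equal(res3$p_bonferroni, pmin(1, res3$p_raw * 3))
})

test_that("spearman correlation equals rank-Pearson with t-approximate p", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  # hand arithmetic on a permutation: sum d^2 = 8 -> 1 - 48/120
  r <- spearman_cor(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4))
  expect_equal(r$rho, 0.6, tolerance = 1e-12)
  expect_equal(r$rho, cor(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4),
                          method = "spearman"))
  # symmetry
  set.seed(92)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(spearman_cor(x, y)$rho, spearman_cor(y, x)$rho)
  # invariance under strictly monotone transforms
  expect_equal(spearman_cor(exp(x), y)$rho, spearman_cor(x, y)$rho)
  expect_equal(spearman_cor(x, qlogis(plogis(y)))$rho, spearman_cor(x, y)$rho)
  expect_error(spearman_cor(1:5, 1:4), "equal length")
})

test_that("partial spearman equals residualize-then-correlate on ranks", {
  set.seed(93)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    x <- rnorm(n); z <- rnorm(n); y <- 0.5 * z + rnorm(n)
    r <- partial_spearman_cor(x, y, z)
    expect_equal(r$rho, oracle_partial_spearman(x, y, z), tolerance = 1e-10)
    # monotone-transform invariance in every slot
    expect_equal(partial_spearman_cor(exp(x), y, z)$rho, r$rho,
                 tolerance = 1e-12)
    expect_equal(partial_spearman_cor(x, y, z^3 + z)$rho, r$rho,
                 tolerance = 1e-12)
  }
  # x = y with an unrelated control: partial correlation ~ 1
  x <- rnorm(50)
  expect_gt(partial_spearman_cor(x, x + 1e-9 * rnorm(50), rnorm(50))$rho, 0.99)
  # y driven by the control only: partialling removes the association
  set.seed(94)
  z <- rnorm(200); y <- z + 0.3 * rnorm(200); x <- rnorm(200)
  expect_lt(abs(partial_spearman_cor(x, y, z)$rho), 0.2)
  expect_error(partial_spearman_cor(x, y, rep(1, 200)), "constant")
})

test_that("the correlation battery recovers a planted coupling from true parameters", {
  hits <- 0; null_hits <- 0
  for (s in 1:50) {
    p <- draw_subject_params(ref_ab_means_probit, c(.5, .5, .5), 20,
                             seed = s)
    cap <- simulate_capture_task(p, task_design(), coupling_spec(), seed = 600 + s)
    cs <- condition_means(cap)
    r <- partial_spearman_cor(cs$slowing_high, p$alpha_high, p$alpha_low)
    if (r$rho > 0 && r$p < 0.05) hits <- hits + 1
    cap0 <- simulate_capture_task(p, task_design(),
                                  coupling_spec(slowing_slope_high = 0,
                                                slowing_slope_low = 0),
                                  seed = 600 + s)
    cs0 <- condition_means(cap0)
    r0 <- partial_spearman_cor(cs0$slowing_high, p$alpha_high, p$alpha_low)
    if (r0$p < 0.05) null_hits <- null_hits + 1
  }
  expect_gte(hits / 50, 0.9)
  expect_lte(null_hits / 50, 0.1)
})

test_that("capture_learning_report assembles the battery and flags degenerate input", {
  set.seed(95)
  n <- 20
  inputs <- data.frame(
    subject_id = sprintf("s%02d", 1:n),
    alpha_high = runif(n, 0.05, 0.4),
    alpha_low = runif(n, 0.05, 0.3),
    beta = runif(n, 2, 8),
    ab_accuracy = runif(n, 0.6, 0.95),
    final_q_a = runif(n, 0.6, 0.9),
    fit_scope = "AB_only")
  inputs$alpha_diff <- inputs$alpha_high - inputs$alpha_low
  inputs$slowing_high <- 400 * inputs$alpha_high + rnorm(n, 0, 5)
  inputs$slowing_low <- 100 * inputs$alpha_low + rnorm(n, 0, 5)
  inputs$slowing_diff <- inputs$slowing_high - inputs$slowing_low
  rep <- capture_learning_report(inputs)
  expect_false(rep$degenerate)
  expect_gt(rep$slowing_high_vs_alpha_high$rho, 0.5)
  expect_lt(rep$slowing_high_vs_alpha_high$p, 0.05)
  expect_gt(rep$slowing_diff_vs_alpha_diff$rho, 0)
  expect_equal(rep$slowing_diff_vs_alpha_diff_loo$n, n - 1)
  # constant slowing scores flag the degenerate path
  degen <- inputs
  degen$slowing_high <- 10; degen$slowing_low <- 10; degen$slowing_diff <- 0
  expect_true(capture_learning_report(degen)$degenerate)
  expect_error(capture_learning_report(inputs[, 1:4]), "lack columns")
})
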