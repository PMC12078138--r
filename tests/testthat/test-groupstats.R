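test_that("Kruskal-Wallis rows match the rank-sum oracle", {
  # identical groups: H = 0, p = 1, effect size nonpositive
  same <- list(veh = c(5, 5, 5), low = c(5, 5, 5), high = c(5, 5, 5))
  r0 <- kruskal_dose_test(same)
  expect_equal(r0$H, 0)
  expect_equal(r0$p, 1)
  expect_lte(r0$omega_squared, 0)
  expect_equal(r0$omega_squared_display, 0)
  # fully separated groups, n = 12, k = 4: H from hand-computed rank sums
  groups <- list(g0 = c(1, 2, 3), g1 = c(4, 5, 6), g2 = c(7, 8, 9),
                 g3 = c(10, 11, 12))
  r1 <- kruskal_dose_test(groups)
  expect_equal(r1$H, oracle_kruskal_h(groups), tolerance = 1e-10)
  expect_equal(r1$omega_squared, (r1$H - 4 + 1) / (12 - 4), tolerance = 1e-12)
  expect_equal(r1$mean_g0, 2)
  expect_equal(r1$se_g3, sd(c(10, 11, 12)) / sqrt(3))
  # ties: the tie-corrected H still matches the oracle
  tied <- list(a = c(1, 1, 2, 3), b = c(2, 2, 3, 3), c = c(4, 4, 1, 2))
  expect_equal(kruskal_dose_test(tied)$H, oracle_kruskal_h(tied),
               tolerance = 1e-10)
  # relabelling groups leaves H unchanged
  expect_equal(kruskal_dose_test(rev(groups))$H, r1$H, tolerance = 1e-12)
  # epsilon-squared variant
  r2 <- kruskal_dose_test(groups, effect = "epsilon")
  expect_equal(r2$omega_squared, r1$H * 13 / (144 - 1), tolerance = 1e-12)
  expect_error(kruskal_dose_test(list(a = 1, b = c(1, 2))), ">= 2")
})

test_that("two-group comparisons behave in both modes", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  # Welch t against the closed form
  tt <- two_group_compare(a, b, mode = "t")
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(tt$statistic, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(tt$p, 2 * pt(-abs(tt$statistic), df), tolerance = 1e-12)
  # identical lists sit at the null center
  same <- two_group_compare(c(1, 2, 3), c(1, 2, 3), mode = "rank")
  expect_equal(same$p, 1, tolerance = 1e-9)
  # rank mode is invariant under monotone transforms
  r1 <- two_group_compare(a, b, mode = "rank")
  r2 <- two_group_compare(exp(a), exp(b), mode = "rank")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)
  # degenerate zero-variance t comparisons are flagged
  dg <- two_group_compare(c(2, 2), c(2, 2), mode = "t")
  expect_true(dg$degenerate)
  expect_equal(dg$p, 1)
  dg2 <- two_group_compare(c(2, 2), c(3, 3), mode = "t")
  expect_true(dg2$degenerate)
  expect_equal(dg2$p, 0)
  # direction agreement between modes on shifted samples
  set.seed(20)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8) + 1.5
    wt <- two_group_compare(x, y, mode = "t")
    expect_lt(wt$statistic, 0)
    expect_lt(mean(x), mean(y))
  }
})

test_that("blocked dose ANOVA reduces to the paired t with two doses", {
  set.seed(21)
  n <- 8
  df <- data.frame(subject = rep(1:n, 2),
                   dose = rep(c("veh", "high"), each = n),
                   fraction = c(rnorm(n), rnorm(n, 1)))
  res <- region_group_anova(df)
  tt <- t.test(df$fraction[df$dose == "high"], df$fraction[df$dose == "veh"],
               paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey flags exactly the planted dose shift", {
  set.seed(22)
  n <- 6
  doses <- c("0", "0.03", "0.3", "3")
  mk <- function(shift) data.frame(
    subject = rep(1:n, 4), dose = rep(doses, each = n),
    fraction = rnorm(4 * n) + rep(c(0, 0, 0, shift), each = n))
  strong <- region_group_anova(mk(10))
  tk <- strong$tukey
  hits <- grepl("(^3-)|(-3$)", tk$contrast)
  expect_true(all(tk$p.adj[hits] < 0.05))
  expect_lt(strong$p, 1e-6)
  # null: significant pairs are rare
  any_sig <- vapply(1:10, function(i) {
    set.seed(100 + i)
    any(region_group_anova(mk(0))$tukey$p.adj < 0.05)
  }, logical(1))
  expect_lte(sum(any_sig), 2)
  # Friedman variant runs on the same matched layout
  fr <- region_group_anova(mk(10), method = "friedman")
  expect_lt(fr$p, 0.05)
  # missing cells are listed
  bad <- mk(0)[-1, ]
  expect_error(region_group_anova(bad), "missing subject x dose")
})

test_that("region ranking applies the across-region FDR filter", {
  rows <- data.frame(region_id = 1:25, p = seq(0.001, 0.9, length.out = 25))
  rf <- rank_and_flag(rows, q = 0.05)
  expect_identical(unname(rf$fdr$pass), brute_force_stepup(rows$p, 0.05))
  expect_equal(rf$table$p, sort(rows$p))
  expect_equal(rf$p_cutoff, max(rows$p[rf$fdr$pass]))
  # all weak p-values: nothing passes, no cutoff
  none <- rank_and_flag(data.frame(p = rep(0.5, 6)), q = 0.05)
  expect_true(is.na(none$p_cutoff))
  expect_false(any(none$table$fdr_flag))
  # a single strong row passes and defines the cutoff
  one <- rank_and_flag(data.frame(p = 0.01), q = 0.05)
  expect_equal(one$p_cutoff, 0.01)
})

test_that("time-by-treatment ANOVA reports the interaction", {
  set.seed(23)
  subj <- sprintf("s%02d", 1:8)
  grid <- expand.grid(subject = subj, time = 1:6,
                      treatment = NA, KEEP.OUT.ATTRS = FALSE)
  grid$treatment <- ifelse(grid$subject %in% subj[1:4], "veh", "psi")
  # treatment group ramps over time, the other stays flat
  grid$value <- rnorm(nrow(grid), sd = 0.3) +
    ifelse(grid$treatment == "psi", as.numeric(grid$time) * 0.5, 0)
  out <- timecourse_anova(grid)
  expect_setequal(out$effect, c("treatment", "time", "treatment:time"))
  expect_lt(out$p[out$effect == "treatment:time"], 0.01)
  expect_true(all(is.finite(out$F)))
})
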