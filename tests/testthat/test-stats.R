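test_that("ANCOVA with a null covariate reduces exactly to one-way ANOVA", {
  set.seed(41)
  values <- rnorm(40)
  group <- rep(c("a", "b"), each = 20)
  res0 <- ancova_per_index(values, group, covariate = rep(0, 40))
  fit_aov <- anova(lm(values ~ group))
  expect_equal(res0$F, fit_aov["group", "F value"])
  expect_equal(res0$p, fit_aov["group", "Pr(>F)"])
  expect_equal(res0$partial_eta_sq,
               fit_aov["group", "Sum Sq"] /
                 (fit_aov["group", "Sum Sq"] + fit_aov["Residuals", "Sum Sq"]))
  # and the adjusted F differs once a real covariate enters
  cov <- values + rnorm(40)
  expect_false(isTRUE(all.equal(ancova_per_index(values, group, cov)$F,
                                res0$F)))
  expect_error(ancova_per_index(rep(1, 40), group), "constant")
  expect_error(
    ancova_per_index(values, group, as.numeric(group == "a")),
    "collinear")
})

test_that("ANCOVA p values are uniform under label permutation", {
  set.seed(42)
  n <- 60
  values <- rnorm(n)
  cov <- rnorm(n)
  ps <- replicate(200, {
    g <- sample(rep(c("a", "b", "c"), each = n / 3))
    ancova_per_index(values, g, cov)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})

test_that("ANCOVA detects a planted 1-SD group shift with high power", {
  set.seed(43)
  hits <- replicate(200, {
    g <- rep(c("a", "b"), each = 36)
    v <- rnorm(72) + (g == "b")
    ancova_per_index(v, g, rnorm(72))$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("BH adjustment matches hand-worked examples", {
  expect_equal(fdr_adjust(c(0.005, 0.03, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(fdr_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(fdr_adjust(0.73), 0.73)
  p <- c(0.8, 0.001, 0.04, 0.2)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("LSD post-hoc reproduces the omnibus for two groups (F = t^2)", {
  set.seed(44)
  v <- rnorm(30); g <- rep(c("a", "b"), 15); cov <- rnorm(30)
  omni <- ancova_per_index(v, g, cov)
  ph <- lsd_posthoc(v, g, cov)
  expect_equal(nrow(ph), 1)
  expect_equal(ph$t^2, omni$F)
  expect_equal(ph$p, omni$p)
})

test_that("LSD adjusted means and p values agree with emmeans", {
  library(emmeans)
  set.seed(45)
  v <- rnorm(45); g <- rep(c("a", "b", "c"), 15); cov <- rnorm(45)
  ph <- lsd_posthoc(v, g, cov)
  dat <- data.frame(v = v, g = g, cov = cov)
  fit <- lm(v ~ cov + g, data = dat)
  em <- summary(pairs(emmeans(fit, "g"), adjust = "none"))
  expect_equal(ph$diff, em$estimate, tolerance = 1e-10)
  expect_equal(ph$p, em$p.value, tolerance = 1e-10)
})

test_that("LSD separates a shifted third group but not the equal pair", {
  set.seed(46)
  g <- rep(c("a", "b", "c"), each = 20)
  v <- c(rnorm(40, 0, 0.1), rnorm(20, 1, 0.1))
  ph <- lsd_posthoc(v, g, NULL)
  key <- paste(ph$group1, ph$group2)
  expect_gt(ph$p[key == "a b"], 0.05)
  expect_lt(ph$p[key == "a c"], 1e-6)
  expect_lt(ph$p[key == "b c"], 1e-6)
})

test_that("partial correlation equals Pearson without covariates and the
           matrix-inverse oracle with them", {
  set.seed(47)
  x <- rnorm(50); y <- rnorm(50)
  res <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)

  for (rep in 1:20) {
    Z <- matrix(rnorm(50 * 2), 50, 2)
    xx <- rnorm(50) + Z %*% c(0.5, -0.3)
    yy <- rnorm(50) + Z %*% c(-0.2, 0.4)
    expect_equal(partial_correlation(xx, yy, Z)$r, oracle_pcor(xx, yy, Z),
                 tolerance = 1e-10)
  }

  expect_equal(partial_correlation(x, x, Z)$r, 1)
  expect_error(partial_correlation(rnorm(4), rnorm(4), matrix(rnorm(8), 4)),
               "insufficient n")
})

test_that("bootstrap partial correlation is seed-deterministic with sane CIs", {
  set.seed(48)
  Z <- matrix(rnorm(39 * 2), 39, 2)
  x <- rnorm(39); y <- 0.5 * x + rnorm(39)
  b1 <- bootstrap_partial_correlation(x, y, Z, n_boot = 300, seed = 7)
  b2 <- bootstrap_partial_correlation(x, y, Z, n_boot = 300, seed = 7)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  b3 <- bootstrap_partial_correlation(x, y, Z, n_boot = 300, seed = 8)
  expect_false(identical(b1$ci_low, b3$ci_low))
  expect_lte(b1$ci_low, b1$r)
  expect_gte(b1$ci_high, b1$r)

  # a perfectly correlated pair collapses the interval onto 1
  bp <- bootstrap_partial_correlation(x, x, NULL, n_boot = 100, seed = 1)
  expect_equal(bp$ci_low, 1)
  expect_equal(bp$ci_high, 1)

  # the bootstrap must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  invisible(bootstrap_partial_correlation(x, y, NULL, n_boot = 50, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("bootstrap CI covers zero at roughly nominal rate for null pairs", {
  set.seed(49)
  cover <- replicate(150, {
    x <- rnorm(39); y <- rnorm(39)
    b <- bootstrap_partial_correlation(x, y, NULL, n_boot = 200,
                                       seed = sample.int(1e6, 1))
    b$ci_low <= 0 && b$ci_high >= 0
  })
  expect_gt(mean(cover), 0.88)
  expect_lte(mean(cover), 1)
})

test_that("global comparison applies FDR across the 4-index family and gates
           the post-hoc stage", {
  set.seed(50)
  n <- 90
  g <- rep(c("a", "b", "c"), each = 30)
  df <- data.frame(strength = rnorm(n) + 2 * (g == "c"),
                   clustering = rnorm(n) + 2 * (g == "c"),
                   path_length = rnorm(n) - 2 * (g == "c"),
                   efficiency = rnorm(n))
  cmp <- compare_global(df, g, rnorm(n))
  expect_equal(cmp$omnibus$p_fdr, fdr_adjust(cmp$omnibus$p_raw))
  sig <- cmp$omnibus$index[cmp$omnibus$p_fdr < 0.05]
  expect_true(all(c("strength", "clustering", "path_length") %in% sig))
  expect_setequal(unique(cmp$posthoc$index), sig)
  expect_equal(sum(cmp$posthoc$index == "strength"), 3)
})

test_that("family-wise false positives of the global comparison stay near 5%
           under the null", {
  set.seed(51)
  any_sig <- replicate(500, {
    g <- rep(c("a", "b", "c"), each = 12)
    df <- data.frame(strength = rnorm(36), clustering = rnorm(36),
                     path_length = rnorm(36), efficiency = rnorm(36))
    any(compare_global(df, g, rnorm(36))$omnibus$p_fdr < 0.05)
  })
  expect_lte(mean(any_sig), 0.07)
})

test_that("nodal comparison excludes degenerate regions and shrinks the family", {
  set.seed(52)
  n <- 45
  g <- rep(c("a", "b", "c"), each = 15)
  M <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("r", 1:6)))
  M[, 4] <- 0.25
  expect_warning(cmp <- compare_nodal(M, g, rnorm(n)), "degenerate")
  expect_equal(cmp$excluded, "r4")
  expect_equal(nrow(cmp$omnibus), 5)
  expect_equal(cmp$omnibus$p_fdr, fdr_adjust(cmp$omnibus$p_raw))
})

test_that("correlation screen respects per-group covariate sets and group sizes", {
  set.seed(53)
  n <- 30
  g <- rep(c("pat", "ctl"), each = 15)
  dat <- data.frame(strength = rnorm(n), score = rnorm(n),
                    med = c(rnorm(15, 300, 50), rep(NA, 15)))
  out <- correlation_screen(dat, g, "strength", "score",
                            covariates_by_group = list(pat = "med",
                                                       ctl = character(0)),
                            n_boot = 100, seed = 2)
  expect_equal(nrow(out), 2)
  expect_equal(out$covariates[out$group == "pat"], "med")
  expect_equal(out$covariates[out$group == "ctl"], "")
  plain <- partial_correlation(dat$strength[g == "ctl"],
                               dat$score[g == "ctl"])
  expect_equal(out$r[out$group == "ctl"], plain$r)

  tiny <- data.frame(strength = rnorm(3), score = rnorm(3),
                     m1 = rnorm(3), m2 = rnorm(3))
  expect_error(
    correlation_screen(tiny, rep("pat", 3), "strength", "score",
                       covariates_by_group = list(pat = c("m1", "m2")),
                       n_boot = 50, seed = 1),
    "insufficient n")
})

test_that("Wilks pre-test flags a multivariate group effect", {
  set.seed(54)
  g <- rep(c("a", "b", "c"), each = 25)
  df <- data.frame(strength = rnorm(75) + (g == "c"),
                   clustering = rnorm(75) + (g == "c"),
                   path_length = rnorm(75) - (g == "c"),
                   efficiency = rnorm(75))
  res <- manova_pretest(df, g, rnorm(75))
  expect_lt(res$p, 0.01)
  expect_true(res$wilks > 0 && res$wilks < 1)
})
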