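test_that("shapiro_wilk flags degenerate input and detects skew", {
  expect_true(shapiro_wilk(rep(3, 10))$degenerate)
  # perfectly symmetric tiny sample: W at its reference maximum
  expect_gt(shapiro_wilk(c(-1, 0, 1))$W, 0.99)
  set.seed(21)
  expect_lt(shapiro_wilk(rexp(50))$p, 0.01)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("friedman reproduces the rank formula and reference implementation", {
  # rows all [1,2,3]: chi2 = 12/(n k (k+1)) sum Rj^2 - 3 n (k+1) = 6
  f <- friedman(rbind(c(1, 2, 3), c(10, 20, 30), c(0.1, 0.2, 0.3)))
  expect_equal(f$chisq, 6)
  expect_equal(f$df, 2)
  # identical columns: no evidence
  f0 <- friedman(matrix(rep(c(5, 7, 9), 3), nrow = 3))
  expect_equal(f0$chisq, 0)
  expect_equal(f0$p, 1)
  # cross-check against stats::friedman.test, with and without ties
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(rnorm(30), 10, 3)
    if (i > 5) m[sample(30, 6)] <- round(m[sample(30, 6)])  # inject ties
    ref <- stats::friedman.test(m)
    got <- friedman(m)
    expect_equal(got$chisq, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(friedman(matrix(c(1, NA, 3, 4, 5, 6), 2)), "complete")
})

test_that("friedman permutation p matches the independent oracle", {
  set.seed(17)
  m <- matrix(rnorm(30), 10, 3)
  p_sim <- friedman(m, method = "simulate", n_perm = 20000, seed = 4)$p
  p_orc <- friedman_perm_oracle(m, n_perm = 20000, seed = 99)
  mc <- 4 * sqrt(p_orc * (1 - p_orc) / 20000)  # two independent MC draws
  expect_lt(abs(p_sim - p_orc), mc)
  # the asymptotic chi-squared p is a coarser approximation at n = 10
  expect_lt(abs(friedman(m)$p - p_orc), 0.05)
})

test_that("friedman is invariant to strictly monotone row transforms", {
  set.seed(13)
  m <- matrix(rnorm(24), 8, 3)
  f0 <- friedman(m)
  f1 <- friedman(exp(m))          # same transform each row, order-preserving
  f2 <- friedman(t(apply(m, 1, function(r) r^3 + 10)))
  expect_equal(f0$chisq, f1$chisq)
  expect_equal(f0$chisq, f2$chisq)
})

test_that("wilcoxon signed-rank reproduces the worked example and oracle", {
  w <- wilcoxon_signed_rank(c(1, -2, 3, 4, 5), rep(0, 5))
  expect_equal(w$w_minus, 2)
  expect_equal(w$p, 6 / 32)
  expect_true(w$exact)
  # x == y is degenerate
  expect_true(wilcoxon_signed_rank(1:5, 1:5)$degenerate)
  # n = 12 exact equals full enumeration to 1e-12
  set.seed(41)
  for (i in 1:5) {
    d <- round(rnorm(12), 6)
    w <- wilcoxon_signed_rank(d, rep(0, 12))
    expect_true(w$exact)
    expect_equal(w$p, wilcoxon_enum_oracle(d), tolerance = 1e-12)
    # and agrees with the reference implementation
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  }
  # ties force the corrected normal approximation
  wt <- wilcoxon_signed_rank(c(1, 1, 2, -2, 3, 4, 5, -1), rep(0, 8))
  expect_false(wt$exact)
  ref <- suppressWarnings(stats::wilcox.test(
    c(1, 1, 2, -2, 3, 4, 5, -1), exact = FALSE, correct = TRUE))
  expect_equal(wt$p, ref$p.value, tolerance = 1e-9)
})

test_that("rm_anova matches the from-scratch sum-of-squares oracle", {
  m <- rbind(c(5.1, 5.9, 6.3), c(4.8, 5.6, 5.9),
             c(5.5, 6.1, 6.8), c(4.9, 5.2, 6.0))
  got <- rm_anova(m)
  orc <- rm_anova_oracle(m)
  expect_equal(got$F, orc$F, tolerance = 1e-12)
  expect_equal(got$p, orc$p, tolerance = 1e-12)
  expect_equal(got$df1, 2)
  expect_equal(got$df2, 6)
  # identical columns: F = 0, p = 1
  m0 <- matrix(rep(c(1, 2, 3, 4), 3), ncol = 3)
  expect_equal(rm_anova(m0)$F, 0)
  expect_equal(rm_anova(m0)$p, 1)
  # Greenhouse-Geisser epsilon stays in [1/(k-1), 1]
  set.seed(2)
  gg <- rm_anova(matrix(rnorm(30), 10, 3), gg = TRUE)
  expect_true(gg$epsilon >= 0.5 && gg$epsilon <= 1)
  expect_error(rm_anova(matrix(c(1, NA, 3, 4), 2)), "complete")
})

test_that("paired t and effect sizes behave at the edges", {
  x <- c(3, 4, 5, 6, 7); y <- x - 1
  pt <- paired_t(x, y)          # constant +1 differences: sd = 0
  expect_true(pt$degenerate)
  expect_true(is.na(effect_size(x, y, "parametric")))  # guarded
  expect_equal(effect_size(x, x, "parametric"), 0)
  expect_equal(effect_size(x, x, "nonparametric"), 0)
  set.seed(6)
  d <- rnorm(1e4, 0.8, 1)
  expect_equal(effect_size(d, rep(0, 1e4), "parametric"), 0.8,
               tolerance = 0.03)
  # plain paired t against the reference implementation
  set.seed(7)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  ref <- stats::t.test(a, b, paired = TRUE)
  got <- paired_t(a, b)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("severity analysis gates post-hoc tests and finds nothing in null data", {
  # identical timepoints: no significant results anywhere
  base <- expand.grid(knee = 1:8, timepoint = c("KL1", "KL2", "KL3"),
                      measure = c("Ma", "La"), stringsAsFactors = FALSE)
  base$family <- "t2"
  base$value <- 40 + as.integer(factor(base$measure)) + base$knee * 0.1
  res <- run_severity_analysis(base)
  expect_true(all(res$comparison == "omnibus"))
  expect_false(any(res$significant))

  # injected effect: omnibus + pairwise appear, and gatekeeping holds
  set.seed(55)
  tab <- expand.grid(knee = 1:15, timepoint = c("KL1", "KL2", "KL3"),
                     measure = c("eff", "null"), stringsAsFactors = FALSE)
  tab$family <- "t2"
  bump <- ifelse(tab$measure == "eff" & tab$timepoint != "KL1", 5, 0)
  tab$value <- 40 + bump + rnorm(nrow(tab))
  res2 <- run_severity_analysis(tab)
  pw <- res2[res2$comparison != "omnibus", ]
  for (i in seq_len(nrow(pw))) {
    om <- res2[res2$comparison == "omnibus" & res2$measure == pw$measure[i], ]
    expect_true(om$significant)  # pairwise rows only exist under a sig omnibus
  }
  eff12 <- pw[pw$measure == "eff" & pw$comparison == "KL1-KL2", ]
  expect_true(eff12$significant)
  expect_equal(eff12$direction, 1)
  # explicit route overrides are honoured
  res_np <- run_severity_analysis(tab, gate = "nonparametric")
  expect_true(all(res_np$route == "nonparametric"))
  expect_true(all(res_np[res_np$comparison == "omnibus", "test"] == "friedman"))
})

test_that("incomplete knees are dropped from the measure matrix", {
  tab <- expand.grid(knee = 1:6, timepoint = c("KL1", "KL2", "KL3"),
                     stringsAsFactors = FALSE)
  tab$family <- "thickness"; tab$measure <- "Mc"
  tab$value <- 2 + 0.1 * tab$knee
  tab <- tab[!(tab$knee == 6 & tab$timepoint == "KL3"), ]  # knee 6 incomplete
  m <- qmricart:::.measure_matrix(
    transform(tab, measure_id = paste(family, measure, "full", sep = "|")),
    "thickness|Mc|full")
  expect_equal(nrow(m), 5)
  expect_equal(attr(m, "n_dropped"), 1)
})
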