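test_that("Spearman correlation matches midrank Pearson and handles monotone data", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(cor_spearman(x, x^2)$estimate, 1)
  expect_equal(cor_spearman(x, -sqrt(x))$estimate, -1)

  set.seed(41)
  for (i in 1:5) {
    a <- sample(0:3, 10, TRUE); b <- rnorm(10)
    r <- cor_spearman(a, b)
    expect_equal(r$estimate, stats::cor(rank(a), rank(b)))
    expect_equal(r$n, 10)
  }
  expect_error(cor_spearman(rep(1, 5), rnorm(5)), "constant")
})

test_that("Kendall tau-b matches pairwise enumeration with ties", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  expect_equal(cor_kendall_tau_b(x, y)$estimate, 1)

  # the 15-pair hand enumeration for a fully tied-in-x design
  xt <- c(0, 0, 1, 1, 2, 2); yt <- c(1, 2, 1, 2, 1, 2)
  expect_equal(cor_kendall_tau_b(xt, yt)$estimate, tau_b_oracle(xt, yt))

  set.seed(42)
  for (i in 1:10) {
    a <- sample(0:2, 12, TRUE); b <- sample(0:4, 12, TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(cor_kendall_tau_b(a, b)$estimate, tau_b_oracle(a, b),
                 tolerance = 1e-12)
  }

  # independence at large n: tau-b near zero
  set.seed(43)
  a <- sample(0:2, 1000, TRUE); b <- sample(0:2, 1000, TRUE)
  expect_lt(abs(cor_kendall_tau_b(a, b)$estimate), 0.1)
  expect_error(cor_kendall_tau_b(rep(1, 6), 1:6), "tied")
})

test_that("Mann-Whitney U behaves at the extremes and matches enumeration", {
  r <- mann_whitney(1:4, 11:15)
  expect_equal(unname(r$statistic), 0)

  a <- c(1, 2, 3, 4)
  r2 <- mann_whitney(a, a)
  expect_equal(unname(r2$statistic), length(a)^2 / 2)
  expect_gt(r2$p_value, 0.9)

  set.seed(44)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(mann_whitney(x, y)$p_value, mw_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("Wilcoxon signed-rank matches sign-flip enumeration and handles zeros", {
  p <- wilcoxon_signed_rank(1:6, 1:6 + 1)
  expect_equal(p$p_value, 2 / 64)

  expect_warning(pz <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(pz$p_value, 1)

  set.seed(45)
  for (i in 1:10) {
    pre <- rnorm(8); post <- rnorm(8)
    expect_equal(wilcoxon_signed_rank(pre, post)$p_value,
                 wsr_enum_oracle(pre, post), tolerance = 1e-12)
  }
})

test_that("ROC analysis: AUC, Youden cutoff and the Mann-Whitney identity", {
  # perfect separation
  r <- roc_youden(c(0.9, 0.8, 0.85, 0.2, 0.3), c(1, 1, 1, 0, 0), n_boot = 0)
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$cutoff > 0.3 && r$cutoff <= 0.8)

  # cutoff consistency with its confusion matrix, and the U identity
  set.seed(46)
  for (i in 1:20) {
    s <- sample(seq(0, 1, 0.05), 40, TRUE)
    l <- as.logical(rbinom(40, 1, 0.5))
    if (length(unique(l)) < 2) next
    r <- roc_youden(s, l, n_boot = 0)
    u <- suppressWarnings(stats::wilcox.test(s[l], s[!l]))$statistic
    expect_equal(r$auc, unname(u) / (sum(l) * sum(!l)), tolerance = 1e-12)
    expect_equal(r$sensitivity, mean(s[l] >= r$cutoff))
    expect_equal(r$specificity, mean(s[!l] < r$cutoff))
  }

  # independent cross-check of the empirical AUC against pROC
  set.seed(52)
  s3 <- sample(seq(0, 1, 0.1), 50, TRUE)
  l3 <- as.logical(rbinom(50, 1, 0.5))
  auc_proc <- as.numeric(pROC::auc(pROC::roc(
    response = l3, predictor = s3, levels = c(FALSE, TRUE),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_youden(s3, l3, n_boot = 0)$auc, auc_proc,
               tolerance = 1e-12)

  # label-independent scores: AUC near 0.5 at large n
  set.seed(47)
  s <- runif(4000); l <- as.logical(rbinom(4000, 1, 0.5))
  expect_lt(abs(roc_youden(s, l, n_boot = 0)$auc - 0.5), 0.05)

  # bootstrap CI is seeded and reproducible
  set.seed(48)
  s2 <- c(rnorm(25, 1), rnorm(25)); l2 <- rep(c(TRUE, FALSE), each = 25)
  r1 <- roc_youden(s2, l2, n_boot = 200, seed = 5)
  r2 <- roc_youden(s2, l2, n_boot = 200, seed = 5)
  expect_equal(r1$auc_ci_low, r2$auc_ci_low)
  expect_true(r1$auc_ci_low < r1$auc && r1$auc < r1$auc_ci_high)
  expect_error(roc_youden(1:5, rep(TRUE, 5)), "both classes")
})

test_that("ICC(2,1) matches the hand-computed ANOVA oracle", {
  m <- matrix(c(0.70, 0.80, 0.60, 0.90, 0.75, 0.65,
                0.72, 0.78, 0.55, 0.95, 0.70, 0.60), ncol = 2)
  r <- suppressWarnings(icc_2_1(m))
  expect_equal(r$icc, icc21_oracle(m), tolerance = 1e-10)
  expect_true(r$icc_ci_low < r$icc && r$icc < r$icc_ci_high)

  set.seed(49)
  for (i in 1:5) {
    m2 <- matrix(runif(12, 0.3, 0.9), ncol = 2)
    expect_equal(suppressWarnings(icc_2_1(m2))$icc, icc21_oracle(m2),
                 tolerance = 1e-10)
  }

  # duplicated session: perfect agreement
  dup <- cbind(c(0.2, 0.5, 0.7, 0.9), c(0.2, 0.5, 0.7, 0.9))
  rd <- suppressWarnings(icc_2_1(dup))
  expect_equal(rd$icc, 1)
  expect_equal(suppressWarnings(sem_mdc(rd))$mdc95, 0, tolerance = 1e-12)

  # no subject effect: ICC near 0 in simulation
  set.seed(50)
  noise <- matrix(rnorm(400), ncol = 2)
  expect_lt(abs(suppressWarnings(icc_2_1(noise))$icc), 0.15)

  expect_error(icc_2_1(matrix(1:4, ncol = 2)), "3 subjects")
  w <- capture_warnings(rz <- icc_2_1(matrix(1, 5, 2)))
  expect_true(any(grepl("zero total variance", w)))
  expect_true(is.na(rz$icc))
})

test_that("SEM and MDC follow the trial+error variance formula", {
  r <- sem_mdc(0.0075, 0.0025)   # sem = 0.1
  expect_equal(r$sem, 0.1)
  expect_equal(round(r$mdc95, 2), 0.28)
  expect_equal(sem_mdc(0, 0)$mdc95, 0)
  expect_equal(r$mdc95 / r$sem, sqrt(2) * 1.96)
  expect_warning(r2 <- sem_mdc(-0.01, 0.04), "clamped")
  expect_equal(r2$sem, 0.2)
})

test_that("reliability battery combines ICC, SEM/MDC and systematic error", {
  set.seed(51)
  subj <- runif(20, 0.4, 0.9)
  t1 <- pmin(pmax(subj + rnorm(20, 0, 0.05), 0), 1)
  t2 <- pmin(pmax(subj + rnorm(20, 0, 0.05), 0), 1)
  r <- suppressWarnings(reliability(t1, t2))
  expect_gt(r$icc, 0.5)
  expect_equal(r$mdc95, r$sem * sqrt(2) * 1.96)
  expect_true(r$systematic_p >= 0 && r$systematic_p <= 1)
  expect_equal(r$n, 20)
  # the alternative SD*sqrt(1-ICC) form is available but distinct
  r2 <- suppressWarnings(reliability(t1, t2, sem_method = "sd_icc"))
  expect_equal(r2$icc, r$icc)
})

test_that("Bonferroni adjustment divides alpha by the family size", {
  b <- bonferroni(runif(11), alpha = 0.05)
  expect_equal(b$adjusted_alpha, 0.05 / 11)
  expect_equal(bonferroni(0.04)$adjusted_alpha, 0.05)
  expect_true(bonferroni(0.04)$significant)
  expect_false(any(bonferroni(rep(1, 5))$significant))
})
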