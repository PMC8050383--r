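test_that("descriptive statistics reproduce the published cohort numbers", {
  t2 <- pcd_table2()
  d <- descriptive(t2$delta_v_mm3)
  expect_equal(round(d$mean, 2), 2295.14)
  expect_equal(round(d$sd, 2), 1181.42)
  expect_identical(d$n, 16L)

  h <- descriptive(c(1, 2, 3, 4, 5))
  expect_identical(h$mean, 3)
  expect_equal(h$sd, sqrt(2.5))
  expect_equal(h$cv, sqrt(2.5) / 3)

  k <- descriptive(rep(7, 5))
  expect_identical(k$sd, 0)
  expect_identical(k$cv, 0)
  expect_error(descriptive(1), "at least 2")
  expect_error(descriptive(c(-1, 1)), "zero mean")
})

test_that("the paired Wilcoxon normal approximation reproduces the cohort p-value", {
  t2 <- pcd_table2()
  w <- wilcoxon_signed_rank(t2$v_pre_mm3, t2$v_post_mm3)
  expect_identical(w$statistic, 136) # all 16 differences positive
  expect_equal(round(w$p_value, 4), 4e-04)
  expect_equal(w$z, 3.5162, tolerance = 1e-4)

  # agrees with the base-R implementation of the same approximation
  ref <- wilcox.test(t2$v_post_mm3, t2$v_pre_mm3, paired = TRUE,
                     exact = FALSE, correct = FALSE)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)

  # antisymmetric differences: z = 0, p = 1
  pre <- c(10, 20, 30, 40, 50, 60)
  post <- pre + c(3, -3, 5, -5, 7, -7)
  wa <- wilcoxon_signed_rank(pre, post)
  expect_equal(wa$z, 0)
  expect_equal(wa$p_value, 1)

  expect_error(wilcoxon_signed_rank(1:5, 1:5), "all paired differences are zero")
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("normal approximation tracks exhaustive enumeration at n = 8", {
  set.seed(51)
  for (i in 1:5) {
    pre <- rnorm(8, 100, 10)
    post <- pre + rnorm(8, 1.5, 2)
    if (any(post == pre)) next
    approx <- wilcoxon_signed_rank(pre, post)
    exact <- wilcoxon_signed_rank(pre, post, exact = TRUE)
    # two-sided p within a factor 2 of the exact 2^8 enumeration
    expect_lt(approx$p_value, 2 * exact$p_value + 1e-12)
    expect_gt(approx$p_value, exact$p_value / 2 - 1e-12)
  }
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  x <- c(3, 9, 1, 7, 5, 10, 2)
  expect_identical(spearman_rho(x, sort(x)[rank(x)])$statistic, 1)
  expect_identical(spearman_rho(x, x)$statistic, 1)
  expect_identical(spearman_rho(x, -x)$statistic, -1)

  set.seed(52)
  a <- sample(1:8, 20, replace = TRUE) # plenty of ties
  b <- sample(1:8, 20, replace = TRUE)
  got <- spearman_rho(a, b)
  ra <- rank(a); rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(got$statistic, oracle, tolerance = 1e-12)

  # invariance under strictly monotone transforms
  expect_equal(spearman_rho(exp(a), b^3 + b)$statistic, got$statistic,
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:3, 3:1), "n >= 4")
})

test_that("absolute-agreement ICC behaves per the two-way model", {
  set.seed(53)
  base <- rnorm(30, 100, 15)
  same <- cbind(base, base, base, base)
  expect_equal(icc_absolute(same, "single")$statistic, 1, tolerance = 1e-12)
  expect_equal(icc_absolute(same, "mean_k")$statistic, 1, tolerance = 1e-12)

  # equal subject and error variance with k = 2 raters drives ICC(A,1) to 0.5
  n <- 500
  subj <- rnorm(n, 0, 1)
  mat <- cbind(subj + rnorm(n), subj + rnorm(n))
  i1 <- icc_absolute(mat, "single")
  expect_equal(i1$statistic, 0.5, tolerance = 0.1)
  expect_true(i1$ci[1] <= i1$statistic && i1$statistic <= i1$ci[2])

  # ICC(A,k) >= ICC(A,1) whenever between-subject variance dominates
  for (i in 1:10) {
    m <- matrix(rnorm(8 * 3, 50, 3), 8, 3) + rnorm(8, 0, 15)
    s1 <- icc_absolute(m, "single")$statistic
    sk <- icc_absolute(m, "mean_k")$statistic
    expect_gte(sk, s1 - 1e-12)
    expect_lt(s1, 1 + 1e-12)
  }

  # cross-check the mean squares against a direct two-way aov decomposition
  m <- matrix(rnorm(12 * 4, 20, 5), 12, 4)
  dat <- data.frame(y = as.vector(m),
                    subj = factor(rep(1:12, 4)), rater = factor(rep(1:4, each = 12)))
  ms <- anova(aov(y ~ subj + rater, data = dat))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 4; n2 <- 12
  ref1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n2) * (msc - mse))
  refk <- (msr - mse) / (msr + (msc - mse) / n2)
  expect_equal(icc_absolute(m, "single")$statistic, ref1, tolerance = 1e-10)
  expect_equal(icc_absolute(m, "mean_k")$statistic, refk, tolerance = 1e-10)

  expect_error(icc_absolute(matrix(5, 3, 3)), "zero total variance")
  expect_error(icc_absolute(matrix(rnorm(4), 4, 1)), ">= 2")
})

test_that("outcome correlations use patient-averaged delta-V", {
  dv <- data.frame(patient = c("P1", "P2", "P2", "P3", "P4", "P5"),
                   delta_v_mm3 = c(1000, 2000, 3000, 1500, 4000, 800))
  out <- data.frame(patient = c("P1", "P2", "P3", "P4", "P5"),
                    pain = c(10, 25, 15, 40, 8))
  res <- correlate_outcomes(dv, out)
  # patient-averaged delta-V (P2 -> 2500) is perfectly rank-aligned with pain
  expect_identical(res$pain$statistic, 1)

  swapped <- out
  swapped$pain <- c(10, 15, 25, 40, 8) # one inversion
  r2 <- correlate_outcomes(dv, swapped)
  avg <- c(1000, 2500, 1500, 4000, 800)
  expect_equal(r2$pain$statistic, cor(rank(avg), rank(swapped$pain)),
               tolerance = 1e-12)
  expect_error(correlate_outcomes(dv[1:3, ], out[1:2, ]), "fewer than 4")
})

test_that("swapping pre and post negates z and preserves the two-sided p", {
  set.seed(54)
  pre <- rnorm(10, 50, 5)
  post <- pre + rnorm(10, 2, 3)
  a <- wilcoxon_signed_rank(pre, post)
  b <- wilcoxon_signed_rank(post, pre)
  expect_equal(a$z, -b$z, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})
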