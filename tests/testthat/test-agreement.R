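test_that("percent agreement matches the reported rounding convention", {
  a <- rep(1, 30)
  b27 <- a; b27[1:3] <- 0
  expect_identical(percent_agreement(a, b27), 90)
  b29 <- a; b29[1] <- 0
  expect_identical(percent_agreement(a, b29), 97)   # 96.67 reported as 97
  expect_identical(percent_agreement(a, b29, digits = 2), 96.67)
  expect_identical(percent_agreement(a, a), 100)
  expect_error(percent_agreement(1:3, 1:4), "length")
})

test_that("Cohen's kappa hits hand-computable anchors", {
  # perfect agreement
  expect_identical(cohens_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3), n_boot = 0)$kappa,
                   1)
  # perfect symmetric disagreement on two categories
  expect_identical(cohens_kappa(c(0, 1, 0, 1), c(1, 0, 1, 0), n_boot = 0)$kappa,
                   -1)
  # 2x2 table [[45, 25], [15, 15]]: po = 0.60, pe = 0.54, kappa = 6/46
  a <- rep(c(1, 1, 0, 0), times = c(45, 25, 15, 15))
  b <- rep(c(1, 0, 1, 0), times = c(45, 25, 15, 15))
  k <- cohens_kappa(a, b, n_boot = 0)
  expect_equal(k$kappa, 0.06 / 0.46, tolerance = 1e-12)
  expect_identical(k$percent_agreement, 60)
})

test_that("Cohen's kappa agrees with the e1071 oracle on random tables", {
  skip_if_not_installed("e1071")
  set.seed(14)
  for (i in 1:5) {
    a <- sample(0:3, 60, replace = TRUE)
    b <- ifelse(runif(60) < 0.6, a, sample(0:3, 60, replace = TRUE))
    mine <- cohens_kappa(a, b, n_boot = 0)$kappa
    lv <- factor(0:3)
    oracle <- e1071::classAgreement(table(factor(a, lv), factor(b, lv)))$kappa
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("Fleiss's kappa matches an independent brute-force computation", {
  fleiss_oracle <- function(tab, levels) {
    n <- nrow(tab); m <- ncol(tab)
    P_i <- numeric(n)
    for (i in seq_len(n)) {
      agree <- 0
      for (r1 in seq_len(m - 1)) for (r2 in (r1 + 1):m)
        agree <- agree + (tab[i, r1] == tab[i, r2])
      P_i[i] <- agree / choose(m, 2)
    }
    p_j <- vapply(levels, function(l) mean(tab == l), numeric(1))
    (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
  }
  set.seed(8)
  tab <- matrix(sample(0:3, 25 * 4, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), 25, 4)
  k <- fleiss_kappa(tab, levels = 0:3, n_boot = 0)
  expect_equal(k$kappa, fleiss_oracle(tab, 0:3), tolerance = 1e-12)
  # identical raters on a mixed cohort: kappa exactly 1
  same <- cbind(0:3, 0:3, 0:3)
  expect_identical(fleiss_kappa(same, n_boot = 0)$kappa, 1)
  expect_error(fleiss_kappa(matrix(1, 5, 1)), "2 raters")
})

test_that("kappa is near zero for independent raters", {
  set.seed(41)
  a <- sample(0:3, 10000, replace = TRUE)
  b <- sample(0:3, 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b, n_boot = 0)$kappa), 0.05)
  tab <- matrix(sample(0:3, 10000 * 3, replace = TRUE), ncol = 3)
  expect_lt(abs(fleiss_kappa(tab, n_boot = 0)$kappa), 0.05)
})

test_that("bootstrap confidence intervals are seeded and bracket the estimate", {
  set.seed(2)
  a <- sample(0:3, 40, replace = TRUE)
  b <- ifelse(runif(40) < 0.8, a, sample(0:3, 40, replace = TRUE))
  k1 <- cohens_kappa(a, b, n_boot = 500, seed = 7)
  k2 <- cohens_kappa(a, b, n_boot = 500, seed = 7)
  expect_identical(k1$ci_lower, k2$ci_lower)
  expect_identical(k1$ci_upper, k2$ci_upper)
  expect_lte(k1$ci_lower, k1$ci_upper)
  expect_gte(k1$kappa, k1$ci_lower - 0.15)
  expect_lte(k1$kappa, k1$ci_upper + 0.15)
  tabm <- cbind(a, b, ifelse(runif(40) < 0.8, a, sample(0:3, 40, TRUE)))
  f1 <- fleiss_kappa(tabm, n_boot = 500, seed = 7)
  expect_true(f1$ci_lower - 0.15 <= f1$kappa && f1$kappa <= f1$ci_upper + 0.15)
})

test_that("Bland-Altman statistics match a hand-worked fixture", {
  x <- c(1.0, 2.0, 3.0)
  y <- c(1.1, 2.3, 3.2)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, 0.2, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0.1, tolerance = 1e-12)
  expect_equal(ba$loa_lower, 0.2 - 1.96 * 0.1, tolerance = 1e-12)
  expect_equal(ba$loa_upper, 0.2 + 1.96 * 0.1, tolerance = 1e-12)
  expect_equal(ba$differences, y - x)
  expect_equal(ba$averages, (x + y) / 2)
  # identical measurements: zero bias and collapsed limits
  ba0 <- bland_altman(x, x)
  expect_identical(ba0$bias, 0)
  expect_identical(ba0$loa_lower, 0)
  expect_error(bland_altman(1, 1), "2 pairs")
})

test_that("regression recovers an exact linear relation", {
  x <- seq(1, 3, length.out = 12)
  fit <- pearson_regression(x, 2 * x + 1)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-10)
  # anti-correlated
  expect_equal(pearson_regression(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_regression(rep(1, 5), 1:5), "variance")
})

test_that("concordance summary partitions shifts per reader", {
  scores <- data.frame(
    subject_id = rep(sprintf("s%d", 1:4), times = 2),
    reader = "reader1",
    modality = rep(c("conventional", "reprojected"), each = 4),
    score = c(0, 1, 2, 3,   0, 2, 2, 1)   # shifts 0, 1, 0, 2
  )
  cs <- concordance_summary(scores)
  expect_identical(cs$concordant, 2L)
  expect_identical(cs$minor, 1L)
  expect_identical(cs$major, 1L)
  expect_identical(cs$n, 4L)
  expect_identical(cs$percent_agreement, 50)
  expect_error(concordance_summary(scores[, -4]), "columns")
})
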