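# Comparison analytics: Sn scale, outlier screening, Bland-Altman,
# correlations, JND transformation, block-wise RM-ANOVA.

test_that("Sn is translation invariant, scale equivariant, and matches the oracle", {
  set.seed(12)
  x <- rnorm(21)
  expect_equal(sn_scale(x + 5), sn_scale(x), tolerance = 1e-12)
  expect_equal(sn_scale(-2.5 * x), 2.5 * sn_scale(x), tolerance = 1e-12)

  for (i in 1:100) {
    n <- sample(2:50, 1)
    y <- rnorm(n, sd = runif(1, 0.1, 10))
    expect_identical(sn_scale(y), oracle_sn(y))
  }
  expect_error(sn_scale(1), "at least 2")
})

test_that("Sn resists contamination that destroys the SD", {
  # 40% point-mass contamination sits below Sn's 50% breakdown point: the
  # estimate stays bounded (near its known maximum-bias factor of ~2.5)
  # while the SD explodes with the outlier magnitude.
  set.seed(13)
  x <- rnorm(30)
  contaminated <- c(x[1:18], rep(1e4, 12))  # 40% huge outliers
  expect_lt(sn_scale(contaminated) / sn_scale(x), 4)
  expect_gt(sd(contaminated) / sd(x), 10)
  # and the bound does not depend on how huge the outlier is
  worse <- c(x[1:18], rep(1e8, 12))
  expect_equal(sn_scale(worse), sn_scale(contaminated), tolerance = 1e-6)
})

test_that("the Sn screen flags gross outliers and respects affine maps", {
  set.seed(14)
  x <- c(rnorm(20), 10)
  scr <- screen_outliers(x, criterion = 3)
  expect_true(scr$flag[21])
  expect_false(any(scr$flag[1:20]))

  scr2 <- screen_outliers(3 * x - 7, criterion = 3)
  expect_identical(scr$flag, scr2$flag)

  expect_warning(scr3 <- screen_outliers(rep(2, 10)), "degenerate")
  expect_false(any(scr3$flag))
  expect_error(screen_outliers(c(1, 2)), "at least 3")
})

test_that("Bland-Altman reproduces hand arithmetic and its symmetries", {
  a <- c(1, 2, 3, 4); b <- c(1.1, 1.9, 3.2, 3.8)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$span, 2 * 1.96 * sd(d), tolerance = 1e-12)
  tcrit <- qt(0.975, 3)
  expect_equal(ba$ci_bias, mean(d) + c(-1, 1) * tcrit * sd(d) / 2,
               tolerance = 1e-12)
  expect_equal(ba$ci_loa_low,
               ba$loa_low + c(-1, 1) * tcrit * sd(d) * sqrt(3 / 4),
               tolerance = 1e-12)

  # swapping the arguments negates the bias and mirrors the limits
  ba_rev <- bland_altman(b, a)
  expect_equal(ba_rev$bias, -ba$bias, tolerance = 1e-12)
  expect_equal(ba_rev$loa_low, -ba$loa_high, tolerance = 1e-12)
  expect_equal(ba_rev$loa_high, -ba$loa_low, tolerance = 1e-12)

  # degenerate pairs
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(same$span, 0)
  shifted <- bland_altman(c(1, 2, 3) + 0.5, c(1, 2, 3))
  expect_equal(shifted$bias, 0.5)
  expect_equal(shifted$sd_diff, 0)

  expect_error(bland_altman(1:4, 1:5), "equal length")
  expect_named(tidy(ba)[1:5], c("pair", "n", "bias", "sd_diff", "loa_low"))
})

test_that("limits of agreement cover ~95% of differences", {
  set.seed(15)
  truth <- rnorm(200, 10, 2)
  a <- truth + rnorm(200, 0, 0.5)
  b <- truth + rnorm(200, 0, 0.5)
  ba <- bland_altman(a, b)
  inside <- mean(ba$data$diff >= ba$loa_low & ba$data$diff <= ba$loa_high)
  expect_gte(inside, 0.92)
  expect_lte(inside, 0.98)
})

test_that("the normality gate picks Pearson or Spearman appropriately", {
  set.seed(16)
  x <- rnorm(30)
  y <- 0.8 * x + rnorm(30, 0, 0.3)
  ct <- correlation_auto(x, y)
  expect_identical(ct$method, "pearson")
  # textbook covariance formula
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$estimate, r_manual, tolerance = 1e-12)

  expect_equal(correlation_auto(x, x)$estimate, 1, tolerance = 1e-12)
  expect_equal(correlation_auto(x, y)$estimate,
               correlation_auto(y, x)$estimate, tolerance = 1e-15)

  # heavily skewed monotone transform: Spearman 1, Pearson would be < 1
  z <- exp(4 * x)
  ct2 <- correlation_auto(x, z)
  expect_identical(ct2$method, "spearman")
  expect_equal(ct2$estimate, 1, tolerance = 1e-12)
  expect_lt(cor(x, z), 1)

  expect_error(correlation_auto(rep(1, 10), rnorm(10)), "constant")
})

test_that("the JND transform is a (shifted) log with sane scaling", {
  j <- c(0.05, 0.08, 0.12, 0.2)
  tj <- transform_jnd(j)
  expect_equal(as.numeric(tj), log(j), tolerance = 1e-12)
  expect_identical(attr(tj, "shift"), 0)
  # multiplying by k adds log k
  expect_equal(as.numeric(transform_jnd(3 * j)) - as.numeric(tj),
               rep(log(3), 4), tolerance = 1e-12)

  expect_warning(tneg <- transform_jnd(c(-0.02, 0.05, 0.1)), "non-positive")
  expect_gt(attr(tneg, "shift"), 0.02)
  expect_true(all(is.finite(tneg)))
})

test_that("a log-normal sample profile-likelihood supports the log choice", {
  set.seed(17)
  x <- exp(rnorm(200, -2.3, 0.4))  # realistic JND-like magnitudes
  lambda_hat <- oracle_boxcox_lambda(x)
  expect_gt(lambda_hat, -0.3)
  expect_lt(lambda_hat, 0.3)
})

test_that("the RM-ANOVA partition matches aov and handles degeneracy", {
  # hand-worked 4-subject x 3-block table
  df <- tibble::tibble(
    observer_id = rep(1:4, each = 3),
    block = rep(1:3, 4),
    jnd = c(5, 4, 3, 6, 5, 5, 7, 6, 4, 5, 5, 3)
  )
  res <- block_analysis(df, value = "jnd")
  ao <- summary(stats::aov(jnd ~ factor(block) + Error(factor(observer_id)),
                           data = df))
  tab <- ao[["Error: Within"]][[1]]
  expect_equal(res$f_statistic, tab["factor(block)", "F value"],
               tolerance = 1e-10)
  expect_equal(res$p_value, tab["factor(block)", "Pr(>F)"], tolerance = 1e-10)
  expect_identical(res$df, c(2L, 6L))
  expect_equal(res$pairwise$mean_diff[res$pairwise$block_a == 1 &
                                      res$pairwise$block_b == 3],
               mean(df$jnd[df$block == 3]) - mean(df$jnd[df$block == 1]),
               tolerance = 1e-12)

  # identical values across blocks: F defined as 0
  flat <- tibble::tibble(observer_id = rep(1:4, each = 3),
                         block = rep(1:3, 4),
                         jnd = rep(c(5, 6, 7, 8), each = 3))
  res_flat <- block_analysis(flat, value = "jnd")
  expect_identical(res_flat$f_statistic, 0)
  expect_identical(res_flat$p_value, 1)

  # incomplete observers are dropped with a warning
  expect_warning(
    res_drop <- block_analysis(df[-1, ], value = "jnd"),
    "incomplete"
  )
  expect_identical(res_drop$n_observers, 3L)
  expect_true(is.data.frame(tidy(res)))
  expect_named(glance(res), c("statistic", "df1", "df2", "p.value", "nobs"))
})
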