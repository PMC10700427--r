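# Psychometric model: Eq.-style cumulative Gaussian with lapse, its
# inversion, JND, likelihood, and ML fitting.

test_that("pf_yes matches its closed form, asymptotes, and quadrature oracle", {
  expect_equal(pf_yes(1.6, m = 1.6, sd = 0.1, lapse = 0), 0.5, tolerance = 1e-12)
  expect_equal(pf_yes(1.6, m = 1.6, sd = 0.1, lapse = 0.05), 0.5, tolerance = 1e-12)
  expect_equal(pf_yes(1e6, m = 1.6, sd = 0.1, lapse = 0.06), 0.94, tolerance = 1e-12)
  expect_equal(pf_yes(-1e6, m = 1.6, sd = 0.1, lapse = 0.06), 0.06, tolerance = 1e-12)

  # quadrature oracle on an interior value
  expect_equal(pf_yes(1.7, m = 1.6, sd = 0.1, lapse = 0.02),
               oracle_p_yes(1.7, m = 1.6, sd = 0.1, lapse = 0.02),
               tolerance = 1e-9)
  expect_equal(pf_yes(0.4, m = 0.1, sd = 0.25, lapse = 0.04),
               oracle_p_yes(0.4, m = 0.1, sd = 0.25, lapse = 0.04),
               tolerance = 1e-9)

  # monotone increasing for sd > 0, decreasing for sd < 0
  xs <- seq(-1, 1, length.out = 50)
  expect_true(all(diff(pf_yes(xs, 0, 0.3, 0.02)) > 0))
  expect_true(all(diff(pf_yes(xs, 0, -0.3, 0.02)) < 0))

  expect_error(pf_yes(0, m = 0, sd = 0), "sd")
  expect_error(pf_yes(0, m = 0, sd = 1, lapse = 0.5), "lapse")
})

test_that("pf_yes is symmetric about m for any lapse", {
  set.seed(101)
  for (i in 1:20) {
    m <- runif(1, -5, 5); s <- runif(1, 0.05, 3); l <- runif(1, 0, 0.45)
    d <- runif(5, 0, 10)
    expect_equal(pf_yes(m + d, m, s, l) + pf_yes(m - d, m, s, l),
                 rep(1, 5), tolerance = 1e-12)
  }
})

test_that("pf_quantile inverts pf_yes (bisection oracle and round trips)", {
  expect_identical(pf_quantile(0.5, m = 0, sd = 1), 0)
  expect_equal(pf_quantile(0.75, m = 0, sd = 1),
               oracle_quantile(0.75, m = 0, sd = 1), tolerance = 1e-9)
  expect_equal(pf_quantile(0.75, m = 0, sd = 1), qnorm(0.75), tolerance = 1e-12)

  set.seed(202)
  for (i in 1:100) {
    m <- runif(1, -2, 2); s <- runif(1, 0.05, 2); l <- runif(1, 0, 0.2)
    p <- runif(1, l + 0.01, 1 - l - 0.01)
    x <- pf_quantile(p, m, s, l)
    expect_equal(pf_yes(x, m, s, l), p, tolerance = 1e-9)
  }

  expect_error(pf_quantile(0.02, m = 0, sd = 1, lapse = 0.05), "unreachable")
  expect_error(pf_quantile(0.97, m = 0, sd = 1, lapse = 0.05), "unreachable")
})

test_that("pf_jnd matches the quantile definition and its invariances", {
  expect_equal(pf_jnd(sd = 0.1, lapse = 0),
               (oracle_quantile(0.75, 0, 0.1) - oracle_quantile(0.25, 0, 0.1)) / 2,
               tolerance = 1e-9)
  expect_equal(pf_jnd(sd = 0.1), qnorm(0.75) * 0.1, tolerance = 1e-9)
  # linear in sd when lapse = 0; independent of m; positive for sd > 0
  expect_equal(pf_jnd(sd = 0.3) / pf_jnd(sd = 0.15), 2, tolerance = 1e-12)
  expect_equal(pf_jnd(sd = 2, lapse = 0.1, m = -57),
               pf_jnd(sd = 2, lapse = 0.1, m = 12), tolerance = 1e-12)
  expect_gt(pf_jnd(sd = 0.05, lapse = 0.2), 0)
  # lapse widens the JND (the 75% response point moves outward)
  expect_gt(pf_jnd(sd = 1, lapse = 0.2), pf_jnd(sd = 1, lapse = 0))
  expect_error(pf_jnd(sd = 1, lapse = 0.3), "unreachable")
})

test_that("pf_loglik is the Bernoulli sum and agrees with a product oracle", {
  one <- tibble::tibble(stimulus = 1.6, response = 1)
  expect_equal(pf_loglik(one, m = 1.6, sd = 0.1), log(0.5), tolerance = 1e-12)
  two <- dplyr::bind_rows(one, one)
  expect_equal(pf_loglik(two, m = 1.6, sd = 0.1),
               2 * pf_loglik(one, m = 1.6, sd = 0.1), tolerance = 1e-12)

  set.seed(303)
  trials <- tibble::tibble(stimulus = runif(20, 1.2, 2.0),
                           response = rbinom(20, 1, 0.5))
  p <- pf_yes(trials$stimulus, 1.55, 0.12, 0.02)
  oracle <- log(prod(ifelse(trials$response == 1, p, 1 - p)))
  expect_equal(pf_loglik(trials, 1.55, 0.12, 0.02), oracle, tolerance = 1e-10)

  expect_error(pf_loglik(tibble::tibble(stimulus = numeric(0),
                                        response = integer(0)), 0, 1),
               "non-empty")
})

test_that("fit_psychometric recovers parameters from noiseless data", {
  xs <- seq(1.2, 2.0, by = 0.05)
  n_per <- 600  # ~1e4 trials in total
  p <- pf_yes(xs, m = 1.62, sd = 0.1, lapse = 0.02)
  trials <- trials_from_counts(xs, rep(n_per, length(xs)),
                               round(n_per * p))
  fit <- fit_psychometric(trials, bounds = list(m = c(1.2, 2.0),
                                                sd = c(0.02, 0.3),
                                                lapse = c(0, 0.06)))
  expect_true(fit$converged)
  expect_equal(fit$m, 1.62, tolerance = 1e-3)
  expect_equal(fit$sd, 0.1, tolerance = 5e-3)
  expect_equal(fit$pse, fit$m, tolerance = 1e-9)
  expect_equal(fit$jnd, pf_jnd(fit$sd, fit$lapse), tolerance = 1e-9)
})

test_that("inverted responses need the negative-slope mode", {
  xs <- seq(1.2, 2.0, by = 0.05)
  p <- pf_yes(xs, m = 1.6, sd = 0.1, lapse = 0.01)
  trials <- trials_from_counts(xs, rep(200, length(xs)),
                               round(200 * (1 - p)))  # mirror image
  pos <- fit_psychometric(trials)
  neg <- fit_psychometric(trials, allow_negative_slope = TRUE)
  expect_lt(neg$sd, 0)
  expect_lt(neg$jnd, 0)
  expect_gt(neg$loglik, pos$loglik)
  expect_equal(neg$m, 1.6, tolerance = 0.01)
})

test_that("degenerate single-category data never crash and are flagged", {
  trials <- tibble::tibble(stimulus = seq(1.3, 1.9, by = 0.1),
                           response = rep(1L, 7))
  fit <- expect_no_error(fit_psychometric(trials))
  expect_false(fit$converged)
  expect_true(fit$degenerate)
})

test_that("ML estimation error shrinks as trials grow", {
  bounds <- list(m = c(1.2, 2.0), sd = c(0.02, 0.3), lapse = c(0, 0.06))
  med_err <- vapply(c(64, 184, 1000), function(n) {
    errs <- vapply(1:50, function(s) {
      set.seed(7000 + s)
      x <- runif(n, 1.2, 2.0)
      tr <- tibble::tibble(stimulus = x,
                           response = rbinom(n, 1, pf_yes(x, 1.6, 0.1, 0.01)))
      abs(fit_psychometric(tr, bounds = bounds)$m - 1.6)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("the generating parameters beat perturbed ones in likelihood", {
  wins <- 0L
  for (s in 1:50) {
    set.seed(8000 + s)
    x <- runif(300, 1.2, 2.0)
    tr <- tibble::tibble(stimulus = x,
                         response = rbinom(300, 1, pf_yes(x, 1.6, 0.1, 0.02)))
    ll_true <- pf_loglik(tr, 1.6, 0.1, 0.02)
    ll_pert <- pf_loglik(tr, 1.65, 0.14, 0.02)
    if (ll_true >= ll_pert) wins <- wins + 1L
  }
  expect_gte(wins, 45L)  # >= 90% of seeds
})

test_that("tidy and glance methods expose the fit", {
  xs <- seq(1.2, 2.0, by = 0.1)
  p <- pf_yes(xs, 1.6, 0.1)
  fit <- fit_psychometric(trials_from_counts(xs, rep(50, length(xs)),
                                             round(50 * p)))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("m", "sd", "lapse", "pse", "jnd"))
  gl <- glance(fit)
  expect_equal(gl$nobs, sum(rep(50, length(xs))))
  expect_true(is.finite(gl$logLik))
})
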