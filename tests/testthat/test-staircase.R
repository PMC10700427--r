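# Interleaved simple up-down staircase: stepping rule, reversals,
# termination, conventional threshold, and binning.

test_that("step_track applies the reversal-indexed schedule", {
  sc <- experiment_config(1)$staircase
  # at 1.6 with zero reversals, "yes" moves down a full 0.2 step
  tr <- step_track(NULL, response = 1L, config = sc, start = 1.6)
  expect_equal(tr$value, 1.4)
  # after two reversals the step drops to 0.1
  tr <- step_track(tr, 0L, sc)   # reversal 1, moves up by 0.2
  expect_equal(tr$n_reversals, 1L)
  expect_equal(tr$value, 1.6)
  tr <- step_track(tr, 1L, sc)   # reversal 2, step now 0.1
  expect_equal(tr$n_reversals, 2L)
  expect_equal(tr$value, 1.5)
  tr <- step_track(tr, 1L, sc)   # no reversal, still 0.1
  expect_equal(tr$value, 1.4)
})

test_that("alternating responses produce a reversal every trial after the first", {
  sc <- experiment_config(2)$staircase
  tr <- NULL
  resp <- rep(c(1L, 0L), 6)
  for (k in seq_along(resp)) {
    tr <- step_track(tr, resp[k], sc, start = if (k == 1) 0 else NULL)
    expect_equal(tr$n_reversals, max(k - 1L, 0L))
  }
})

test_that("values clamp at the bounds and boundary presentations count", {
  sc <- experiment_config(1)$staircase
  tr <- step_track(NULL, response = 1L, config = sc, start = 1.2)
  expect_equal(tr$value, 1.2)       # step points outward, value unchanged
  expect_equal(tr$boundary_hits, 1L)
  for (k in 1:9) tr <- step_track(tr, 1L, sc)
  expect_true(tr$terminated)
  expect_identical(tr$terminated_by, "boundary")
  expect_error(step_track(tr, 1L, sc), "terminated")
})

test_that("recorded reversals equal a brute-force scan of the responses", {
  cfg <- experiment_config(1)
  obs <- simulated_observer(1.58, 0.09, 0.02)
  for (s in c(3, 14, 159)) {
    run <- run_staircase(obs, cfg, seed = s)
    scanned <- psycompare:::reversals_from_trials(run$trials)
    for (r in scanned) {
      expect_identical(run$tracks$reversal_values[[r$track_id]],
                       r$reversal_values)
    }
  }
})

test_that("the staircase always terminates within the 150-trial cap", {
  cfg <- experiment_config(1)
  random_obs <- simulated_observer(1.6, 50)  # p = 0.5 everywhere
  seeds <- psycompare:::derive_seeds(909, 500)
  for (s in seeds) {
    run <- run_staircase(random_obs, cfg, seed = s)
    expect_lte(nrow(run$trials), 150L)
    expect_identical(sum(run$tracks$n_trials), nrow(run$trials))
  }
})

test_that("fuzzed observers never exceed the cap and conserve trials", {
  cfg <- experiment_config(3)
  seeds <- psycompare:::derive_seeds(910, 1500)
  set.seed(911)
  ms <- runif(1500, -40, 40); sds <- runif(1500, 0.5, 80)
  for (i in seq_along(seeds)) {
    obs <- simulated_observer(ms[i], sds[i], runif(1, 0, 0.08))
    run <- run_staircase(obs, cfg, seed = seeds[i])
    expect_lte(nrow(run$trials), 150L)
    # every trial belongs to exactly one track
    expect_identical(sum(run$tracks$n_trials), nrow(run$trials))
    # non-boundary, non-cap terminations carry exactly 15 reversals
    done <- run$tracks$terminated_by == "reversals"
    expect_true(all(run$tracks$n_reversals[done] == 15L))
  }
})

test_that("a near-deterministic observer oscillates around its threshold", {
  cfg <- experiment_config(1)
  obs <- simulated_observer(1.57, 1e-6)  # step-function observer
  run <- run_staircase(obs, cfg, seed = 21)
  final_step <- min(cfg$staircase$step_schedule)
  last_values <- vapply(1:3, function(k) {
    tail(run$trials$stimulus[run$trials$track_id == k], 1)
  }, numeric(1))
  expect_true(all(abs(last_values - 1.57) <= 2 * final_step + 1e-9))
  thr <- suppressWarnings(as.numeric(conventional_threshold(run)))
  expect_equal(thr, 1.57, tolerance = final_step)
})

test_that("conventional threshold averages the last five reversals per track", {
  fake <- structure(list(tracks = tibble::tibble(
    track_id = 1:3,
    reversal_values = list(c(9, 9, rep(1.5, 5)), rep(1.6, 6), rep(1.7, 5))
  )), class = "staircase_run")
  expect_equal(as.numeric(conventional_threshold(fake)), 1.6, tolerance = 1e-12)

  short <- structure(list(tracks = tibble::tibble(
    track_id = 1:3,
    reversal_values = list(rep(1.5, 5), rep(1.6, 5), c(1.8, 1.6))
  )), class = "staircase_run")
  expect_warning(thr <- conventional_threshold(short), "fewer than")
  expect_equal(as.numeric(thr), mean(c(1.5, 1.6, 1.7)), tolerance = 1e-12)
})

test_that("conventional thresholds track the fitted thresholds across a cohort", {
  cfg <- experiment_config(1)
  coh <- sample_cohort(cohort_spec(cfg, 20, seed = 61))
  bounds <- psy_bounds(cfg)
  res <- t(vapply(seq_len(20), function(i) {
    obs <- simulated_observer(coh$m[i], coh$sd[i], coh$lapse[i])
    run <- run_staircase(obs, cfg, seed = coh$seed[i])
    c(suppressWarnings(as.numeric(conventional_threshold(run))),
      fit_psychometric(run$trials, bounds = bounds)$pse)
  }, numeric(2)))
  expect_gte(cor(res[, 1], res[, 2]), 0.86)
})

test_that("quantile binning matches a sort-and-split oracle and conserves counts", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(30:120, 1)
    trials <- tibble::tibble(stimulus = round(runif(n, 0, 10), 1),
                             response = rbinom(n, 1, 0.5))
    bins <- bin_for_fit(trials, n_bins = 9)
    expect_identical(sum(bins$n), n)
    expect_identical(sum(bins$n_yes), sum(trials$response))
    # oracle: sort values, split into 9 contiguous chunks, compare means
    srt <- sort(trials$stimulus)
    sizes <- rep(n %/% 9, 9); sizes[seq_len(n %% 9)] <- sizes[seq_len(n %% 9)] + 1
    idx <- rep(seq_len(9), times = sizes)
    oracle_means <- as.numeric(tapply(srt, idx, mean))
    expect_equal(bins$stimulus, oracle_means, tolerance = 1e-12)
  }
})

test_that("binned proportions of a noiseless observer are monotone", {
  cfg <- experiment_config(1)
  obs <- simulated_observer(1.6, 1e-6)
  run <- run_cs(obs, build_cs_design(cfg), seed = 5)
  bins <- bin_for_fit(run, n_bins = 5)
  expect_true(all(diff(bins$prop_yes) >= 0))
})

test_that("binning collapses gracefully below the distinct-value count", {
  trials <- tibble::tibble(stimulus = rep(c(1, 2, 3), each = 10),
                           response = rep(c(0L, 1L, 1L), each = 10))
  bins <- bin_for_fit(trials, n_bins = 9)
  expect_identical(nrow(bins), 3L)
  expect_true(attr(bins, "bins_merged"))
  expect_identical(sum(bins$n), 30L)
})
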