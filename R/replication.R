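# Full in-silico replication of one experiment: cohort generation,
# counterbalanced procedure order, the three procedures per observer,
# maximum-likelihood fits, exclusion flags, and the comparison analytics.

run_procedure <- function(observer, proc, config, seed, block) {
  switch(proc,
    questplus = run_questplus(observer, config, seed = seed, block = block),
    cs = run_cs(observer, config, seed = seed, block = block),
    staircase = run_staircase(observer, config, seed = seed, block = block),
    stop("unknown procedure: ", proc, call. = FALSE)
  )
}

#' Replicate one experiment on a simulated cohort
#'
#' For each observer in a seeded cohort: assigns a procedure order from the
#' six cycled permutations (the session's block 1-3 is the position of the
#' procedure in that order), runs QUEST+ (64 trials), the constant-stimuli
#' session (180/184 trials) and the interleaved staircase (at most 150
#' trials), and fits the psychometric function to every procedure's
#' per-trial records inside the experiment's parameter box. QUEST+ runs
#' whose sd estimate hits the grid ceiling are flagged (the participant
#' exclusion rule). Everything is reproducible from `seed`.
#'
#' @param config An [experiment_config()].
#' @param n_observers Cohort size (study scale is 21).
#' @param seed Master seed.
#' @param drift Length-3 per-block sd factors shared by the cohort
#'   (`c(1, 1, 1)` = stationary; `c(1, 0.8, 0.6)` emulates fast learning).
#' @param sampler Optional cohort sampler override (see [cohort_spec()]).
#' @param allow_negative_slope Passed to [fit_psychometric()].
#' @return An object of class `psy_replication`: `cohort` (true
#'   parameters), `trials` (all trial records in the shared schema, with
#'   `observer_id` and `experiment`), `estimates` (one row per observer x
#'   procedure: fitted `m`, `sd`, `lapse`, `pse`, `jnd`, `loglik`,
#'   `converged`, `ceiling`, `n_trials`, plus the staircase
#'   `conventional` threshold), `quest` (posterior summaries), `config`,
#'   `seed`.
#' @examples
#' \donttest{
#' rep1 <- run_replication(experiment_config(1), n_observers = 6, seed = 7)
#' rep1$estimates
#' }
#' @export
run_replication <- function(config, n_observers = 21, seed = 1,
                            drift = c(1, 1, 1), sampler = NULL,
                            allow_negative_slope = FALSE) {
  stopifnot(inherits(config, "psy_config"))
  seeds <- derive_seeds(seed, 1L + 3L * n_observers)
  spec <- cohort_spec(config, n_observers, seed = seeds[1], drift = drift,
                      sampler = sampler)
  cohort <- sample_cohort(spec)
  bounds <- psy_bounds(config)

  all_trials <- vector("list", n_observers)
  est_rows <- vector("list", n_observers)
  quest_summaries <- vector("list", n_observers)

  for (i in seq_len(n_observers)) {
    obs <- simulated_observer(cohort$m[i], cohort$sd[i], cohort$lapse[i],
                              drift = drift)
    order_i <- cohort$order[[i]]
    proc_seeds <- setNames(seeds[1L + 3L * (i - 1L) + 1:3],
                           c("questplus", "cs", "staircase"))
    obs_trials <- vector("list", 3L)
    obs_rows <- vector("list", 3L)
    for (blk in 1:3) {
      proc <- order_i[blk]
      run <- run_procedure(obs, proc, config, proc_seeds[[proc]], blk)
      trials <- if (is.data.frame(run)) run else run$trials
      fit <- fit_psychometric(trials, bounds = bounds,
                              allow_negative_slope = allow_negative_slope)
      ceiling <- FALSE
      conventional <- NA_real_
      if (proc == "questplus") {
        ceiling <- run$ceiling
        quest_summaries[[i]] <- run$summary
      } else if (proc == "staircase") {
        conventional <- suppressWarnings(as.numeric(conventional_threshold(run)))
      }
      obs_trials[[blk]] <- trials
      obs_rows[[blk]] <- tibble::tibble(
        observer_id = cohort$observer_id[i], procedure = proc,
        block = blk, n_trials = fit$n_trials,
        m = fit$m, sd = fit$sd, lapse = fit$lapse,
        pse = fit$pse, jnd = fit$jnd, loglik = fit$loglik,
        converged = fit$converged, ceiling = ceiling,
        conventional = conventional
      )
    }
    all_trials[[i]] <- dplyr::bind_rows(obs_trials) |>
      dplyr::mutate(observer_id = cohort$observer_id[i],
                    experiment = config$experiment, .before = 1L)
    est_rows[[i]] <- dplyr::bind_rows(obs_rows)
  }

  structure(list(
    config = config, seed = seed, drift = drift,
    cohort = cohort,
    trials = dplyr::bind_rows(all_trials),
    estimates = dplyr::bind_rows(est_rows),
    quest = quest_summaries
  ), class = "psy_replication")
}

#' @export
print.psy_replication <- function(x, ...) {
  cat(sprintf("Simulated replication of Experiment %d: %d observers, seed %s\n",
              x$config$experiment, nrow(x$cohort), format(x$seed)))
  cat(sprintf("  %d trials total; %d ceiling-flagged QUEST+ run(s)\n",
              nrow(x$trials), sum(x$estimates$ceiling)))
  invisible(x)
}

procedure_pairs <- function() {
  list(c("questplus", "cs"), c("questplus", "staircase"), c("cs", "staircase"))
}

#' Comparison analytics for a simulated replication
#'
#' Applies the study's analysis pipeline to a [run_replication()] result:
#' ceiling-flagged observers are excluded; PSE and JND outliers are
#' screened per procedure with the Sn rule (criterion 3) and flags are
#' unioned per observer; pairwise procedure correlations (normality-gated
#' Pearson/Spearman) and Bland-Altman agreement are computed for both
#' measures; block-wise repeated-measures analyses test for learning
#' (JNDs are log-transformed first); and one-sample t-tests compare each
#' procedure's mean PSE with the reference value.
#'
#' @param rep A `psy_replication`.
#' @param screen Apply the Sn outlier screen (default `TRUE`).
#' @param criterion Sn criterion (default 3).
#' @return An object of class `psy_analysis`: `correlations` (tibble:
#'   pair x measure), `agreement` (list of [bland_altman()] objects keyed
#'   `"measure: A vs B"`), `agreement_table` (tidy tibble), `blocks` (list
#'   with `pse` and `jnd` [block_analysis()] results), `bias` (one-sample
#'   t-tests of PSE against the reference), `excluded` (observer ids and
#'   reasons), `n_used`.
#' @export
analyze_replication <- function(rep, screen = TRUE, criterion = 3) {
  stopifnot(inherits(rep, "psy_replication"))
  est <- rep$estimates
  excluded <- tibble::tibble(observer_id = integer(0), reason = character(0))

  ceil_obs <- unique(est$observer_id[est$ceiling])
  if (length(ceil_obs) > 0L) {
    excluded <- dplyr::bind_rows(excluded,
      tibble::tibble(observer_id = ceil_obs, reason = "quest_sd_ceiling"))
  }
  est <- est[!est$observer_id %in% ceil_obs, ]

  if (screen && length(unique(est$observer_id)) >= 3L) {
    out_obs <- integer(0)
    for (proc in unique(est$procedure)) {
      for (measure in c("pse", "jnd")) {
        v <- est[est$procedure == proc, ]
        ok <- is.finite(v[[measure]])
        if (sum(ok) < 3L) next
        scr <- suppressWarnings(screen_outliers(v[[measure]][ok], criterion))
        out_obs <- c(out_obs, v$observer_id[ok][scr$flag])
      }
    }
    out_obs <- setdiff(unique(out_obs), excluded$observer_id)
    if (length(out_obs) > 0L) {
      excluded <- dplyr::bind_rows(excluded,
        tibble::tibble(observer_id = out_obs, reason = "sn_outlier"))
      est <- est[!est$observer_id %in% out_obs, ]
    }
  }

  wide <- function(measure) {
    est |>
      dplyr::select("observer_id", "procedure", dplyr::all_of(measure)) |>
      tidyr::pivot_wider(names_from = "procedure",
                         values_from = dplyr::all_of(measure))
  }

  correlations <- list()
  agreement <- list()
  for (measure in c("pse", "jnd")) {
    w <- wide(measure)
    for (pr in procedure_pairs()) {
      a <- w[[pr[1]]]; b <- w[[pr[2]]]
      keep <- is.finite(a) & is.finite(b)
      key <- sprintf("%s: %s vs %s", measure, pr[1], pr[2])
      if (sum(keep) >= 4L) {
        ct <- correlation_auto(a[keep], b[keep])
        correlations[[key]] <- tibble::tibble(
          measure = measure, pair = paste(pr, collapse = " vs "),
          method = ct$method, estimate = ct$estimate, p_value = ct$p_value,
          n = ct$n)
        agreement[[key]] <- bland_altman(a[keep], b[keep], pair = pr)
      }
    }
  }

  blocks <- list(
    pse = block_analysis(est, value = "pse"),
    jnd = {
      est_jnd <- est[is.finite(est$jnd), ]
      est_jnd$log_jnd <- suppressWarnings(as.numeric(transform_jnd(est_jnd$jnd)))
      block_analysis(est_jnd, value = "log_jnd")
    }
  )

  bias <- est |>
    dplyr::group_by(.data$procedure) |>
    dplyr::summarise(
      mean_pse = mean(.data$pse), sd_pse = stats::sd(.data$pse),
      n = dplyr::n(),
      t_statistic = (mean(.data$pse) - rep$config$reference) /
        (stats::sd(.data$pse) / sqrt(dplyr::n())),
      p_value = 2 * stats::pt(-abs(t_statistic), df = dplyr::n() - 1),
      .groups = "drop"
    )

  structure(list(
    correlations = dplyr::bind_rows(correlations),
    agreement = agreement,
    agreement_table = dplyr::bind_rows(lapply(agreement, tidy_agreement_row),
                                       .id = "comparison"),
    blocks = blocks, bias = bias, excluded = excluded,
    n_used = length(unique(est$observer_id)),
    estimates = est
  ), class = "psy_analysis")
}

tidy_agreement_row <- function(ba) {
  tibble::tibble(
    pair = paste(ba$pair, collapse = " vs "), n = ba$n, bias = ba$bias,
    loa_low = ba$loa_low, loa_high = ba$loa_high, span = ba$span,
    ci_bias_low = ba$ci_bias[1], ci_bias_high = ba$ci_bias[2],
    slope = ba$slope, slope_p = ba$slope_p
  )
}

#' @export
print.psy_analysis <- function(x, ...) {
  cat(sprintf("Procedure-comparison analysis (%d observers used, %d excluded)\n",
              x$n_used, nrow(x$excluded)))
  cat("\nPairwise correlations:\n")
  print(x$correlations)
  cat("\nBlock (learning) tests: PSE F = ",
      sprintf("%.2f (p = %.3g)", x$blocks$pse$f_statistic, x$blocks$pse$p_value),
      "; log-JND F = ",
      sprintf("%.2f (p = %.3g)", x$blocks$jnd$f_statistic, x$blocks$jnd$p_value),
      "\n", sep = "")
  invisible(x)
}

#' Write a replication and its analysis to disk
#'
#' Emits deterministic, re-generatable report files: `trials.csv`,
#' `estimates.csv`, `correlations.csv`, `agreement.json`, `blocks.json`,
#' and `provenance.json` (master seed, configuration hash, package
#' version). Re-running on the same bundle produces byte-identical files.
#'
#' @param rep A `psy_replication`.
#' @param dir Output directory (created if needed).
#' @param analysis Optional pre-computed [analyze_replication()] result.
#' @return Invisibly, the vector of files written.
#' @export
make_report <- function(rep, dir, analysis = NULL) {
  stopifnot(inherits(rep, "psy_replication"))
  if (nrow(rep$cohort) == 0L) stop("empty cohort: nothing to report", call. = FALSE)
  analysis <- analysis %||% analyze_replication(rep)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("trials.csv", "estimates.csv", "correlations.csv",
                            "agreement.json", "blocks.json", "provenance.json"))
  names(paths) <- c("trials", "estimates", "correlations", "agreement",
                    "blocks", "provenance")
  readr::write_csv(rep$trials, paths["trials"])
  readr::write_csv(rep$estimates, paths["estimates"])
  readr::write_csv(analysis$correlations, paths["correlations"])
  jsonlite::write_json(analysis$agreement_table, paths["agreement"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  blocks <- lapply(analysis$blocks, function(b) {
    list(f_statistic = b$f_statistic, df = b$df, p_value = b$p_value,
         summary = b$summary)
  })
  jsonlite::write_json(blocks, paths["blocks"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg <- rep$config
  provenance <- list(
    experiment = cfg$experiment, seed = rep$seed,
    n_observers = nrow(rep$cohort), drift = rep$drift,
    config_hash = config_hash(unclass(cfg)[c("experiment", "stim_domain",
                                             "grid", "cs", "staircase",
                                             "quest_n_trials", "reference")]),
    package = "psycompare",
    package_version = as.character(utils::packageVersion("psycompare"))
  )
  jsonlite::write_json(provenance, paths["provenance"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
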