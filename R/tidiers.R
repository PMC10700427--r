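# broom-style tidiers for the package's result objects.

#' Tidy a psychometric fit
#'
#' @param x A [fit_psychometric()] result.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.psyfit <- function(x, ...) {
  tibble::tibble(term = c("m", "sd", "lapse", "pse", "jnd"),
                 estimate = c(x$m, x$sd, x$lapse, x$pse, x$jnd))
}

#' Glance at a psychometric fit
#'
#' @param x A [fit_psychometric()] result.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `converged`, `degenerate`, `nobs`.
#' @exportS3Method generics::glance
glance.psyfit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 degenerate = x$degenerate, nobs = x$n_trials)
}

#' Tidy a Bland-Altman agreement analysis
#'
#' @param x A [bland_altman()] result.
#' @param ... Unused.
#' @return A one-row tibble with bias, limits of agreement, their
#'   confidence intervals, the proportional-bias slope, and `n`.
#' @exportS3Method generics::tidy
tidy.psy_agreement <- function(x, ...) {
  tibble::tibble(
    pair = paste(x$pair, collapse = " vs "), n = x$n,
    bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high, span = x$span,
    ci_bias_low = x$ci_bias[1], ci_bias_high = x$ci_bias[2],
    ci_loa_low_low = x$ci_loa_low[1], ci_loa_low_high = x$ci_loa_low[2],
    ci_loa_high_low = x$ci_loa_high[1], ci_loa_high_high = x$ci_loa_high[2],
    slope = x$slope, slope_p = x$slope_p
  )
}

#' Tidy a normality-gated correlation
#'
#' @param x A [correlation_auto()] result.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `estimate`, `p.value`, `n`.
#' @exportS3Method generics::tidy
tidy.psy_correlation <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$estimate,
                 p.value = x$p_value, n = x$n)
}

#' Tidy a block-wise repeated-measures analysis
#'
#' @param x A [block_analysis()] result.
#' @param ... Unused.
#' @return The per-block summary tibble (mean, sd, n, 95% CI).
#' @exportS3Method generics::tidy
tidy.psy_block_analysis <- function(x, ...) {
  x$summary
}

#' Glance at a block-wise repeated-measures analysis
#'
#' @param x A [block_analysis()] result.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p.value`, `nobs`.
#' @exportS3Method generics::glance
glance.psy_block_analysis <- function(x, ...) {
  tibble::tibble(statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
                 p.value = x$p_value, nobs = x$n_observers)
}

#' Tidy a QUEST+ run
#'
#' @param x A [run_questplus()] result.
#' @param ... Unused.
#' @return One row per parameter with posterior mean and MAP estimates.
#' @exportS3Method generics::tidy
tidy.quest_run <- function(x, ...) {
  tibble::tibble(term = c("m", "sd", "lapse"),
                 posterior_mean = unname(x$summary$mean),
                 map = unname(x$summary$map))
}

#' Glance at a QUEST+ run
#'
#' @param x A [run_questplus()] result.
#' @param ... Unused.
#' @return A one-row tibble: trial count, final posterior entropy, and the
#'   ceiling flag.
#' @exportS3Method generics::glance
glance.quest_run <- function(x, ...) {
  tibble::tibble(nobs = nrow(x$trials),
                 entropy = tail(x$summary$entropy, 1),
                 ceiling = x$ceiling)
}
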