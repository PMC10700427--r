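# ggplot2 figures for the main result types.

#' Bland-Altman plot
#'
#' Differences against pair means, with the bias line, the 1.96-SD limits
#' of agreement, and dashed 95% confidence bounds for each.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psy_agreement <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = c(object$ci_bias, object$ci_loa_low,
                                       object$ci_loa_high),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      title = sprintf("Agreement: %s vs %s", object$pair[1], object$pair[2]),
      x = "Mean of the two estimates", y = "Difference (A - B)"
    ) +
    ggplot2::theme_minimal()
}

#' Staircase trace plot
#'
#' Stimulus value against trial number for each interleaved track, with
#' reversals marked and the conventional threshold drawn as a horizontal
#' line.
#'
#' @param run A [run_staircase()] result.
#' @return A ggplot object.
#' @export
plot_staircase <- function(run) {
  stopifnot(inherits(run, "staircase_run"))
  trials <- run$trials
  rev_pts <- purrr::map_dfr(reversals_from_trials(trials), function(r) {
    df <- trials[trials$track_id == r$track_id, ]
    flips <- which(diff(df$response) != 0) + 1L
    df[flips, c("trial_index", "stimulus", "track_id")]
  })
  thr <- suppressWarnings(as.numeric(conventional_threshold(run)))
  ggplot2::ggplot(trials,
                  ggplot2::aes(x = .data$trial_index, y = .data$stimulus,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_hline(yintercept = thr, colour = "orange") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = rev_pts, shape = 1, size = 3) +
    ggplot2::labs(x = "Trial", y = "Stimulus value", colour = "Track",
                  title = sprintf("Interleaved staircase (threshold %.3g)", thr)) +
    ggplot2::theme_minimal()
}

#' Psychometric function plot
#'
#' Binned yes-proportions (point size proportional to bin count) with the
#' fitted lapse-corrected cumulative Gaussian overlaid.
#'
#' @param fit A [fit_psychometric()] result.
#' @param trials The trials the fit consumed.
#' @param n_bins Number of quantile bins for the points (default 9).
#' @return A ggplot object.
#' @export
plot_psychometric <- function(fit, trials, n_bins = 9) {
  stopifnot(inherits(fit, "psyfit"))
  bins <- bin_for_fit(trials, n_bins)
  xr <- range(trials$stimulus)
  curve <- tibble::tibble(
    stimulus = seq(xr[1], xr[2], length.out = 200),
    p = pf_yes(seq(xr[1], xr[2], length.out = 200), fit$m, fit$sd, fit$lapse)
  )
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$stimulus)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$prop_yes, size = .data$n),
                        alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = fit$pse, linetype = "dotted") +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "Stimulus value", y = "P(yes)", size = "Trials",
                  title = sprintf("PSE = %.3g, JND = %.3g", fit$pse, fit$jnd)) +
    ggplot2::theme_minimal()
}

#' Boxplots of estimates by procedure
#'
#' @param estimates The `estimates` tibble of a [run_replication()].
#' @param measure `"pse"` or `"jnd"`.
#' @return A ggplot object.
#' @export
plot_estimates <- function(estimates, measure = c("pse", "jnd")) {
  measure <- match.arg(measure)
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$procedure,
                               y = .data[[measure]])) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 15, size = 2) +
    ggplot2::labs(x = NULL, y = toupper(measure)) +
    ggplot2::theme_minimal()
}

#' Learning-curve plot: estimates by session block
#'
#' Per-block means with 95% confidence intervals, pooled over procedures
#' (the block factor is the procedure's position in the session).
#'
#' @param estimates The `estimates` tibble of a [run_replication()].
#' @param measure `"pse"` or `"jnd"`.
#' @return A ggplot object.
#' @export
plot_learning <- function(estimates, measure = c("pse", "jnd")) {
  measure <- match.arg(measure)
  smry <- estimates |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(mean = mean(.data[[measure]], na.rm = TRUE),
                     se = stats::sd(.data[[measure]], na.rm = TRUE) /
                       sqrt(sum(is.finite(.data[[measure]]))),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(ci = stats::qt(0.975, .data$n - 1) * .data$se)
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$block, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$ci,
                                        ymax = .data$mean + .data$ci),
                           width = 0.1) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = 1:3) +
    ggplot2::labs(x = "Session block", y = paste("Mean", toupper(measure))) +
    ggplot2::theme_minimal()
}
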