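# Method-comparison analytics: robust Sn outlier screening, normality-gated
# correlations, Bland-Altman agreement, JND transformation, and the
# block-wise (learning) repeated-measures analysis.

#' Rousseeuw-Croux Sn robust scale estimator
#'
#' \eqn{S_n = c \cdot c_n \cdot \mathrm{lomed}_i\, \mathrm{himed}_j\, |x_i - x_j|}
#' with consistency constant `c = 1.1926` and the usual finite-sample
#' correction factors `c_n` (tabulated for n = 2..9; `n/(n - 0.9)` for odd
#' and 1 for even n >= 10). The high median is the `floor(n/2) + 1`-th and
#' the low median the `floor((n+1)/2)`-th order statistic. Translation
#' invariant and scale equivariant, with a 50% breakdown point.
#'
#' @param x Numeric vector, length >= 2.
#' @return The Sn scale estimate.
#' @references Rousseeuw, P. J., & Croux, C. (1993). Alternatives to the
#'   median absolute deviation. JASA, 88(424), 1273-1283.
#' @export
sn_scale <- function(x) {
  n <- length(x)
  if (n < 2L) stop("`x` must have at least 2 values", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  amat <- abs(outer(x, x, "-"))
  himed <- apply(amat, 1L, function(row) sort(row)[n %/% 2L + 1L])
  lomed <- sort(himed)[(n + 1L) %/% 2L]
  1.1926 * sn_correction(n) * lomed
}

sn_correction <- function(n) {
  small <- c(0.743, 1.851, 0.954, 1.351, 0.993, 1.198, 1.005, 1.131)
  if (n <= 9L) small[n - 1L] else if (n %% 2L == 1L) n / (n - 0.9) else 1
}

#' Screen outliers with the Sn rule
#'
#' Flags value `i` when `|x_i - median(x)| > criterion * Sn(x)`; the
#' criterion of 3 is the recommendation for psychophysical threshold data.
#' When all values tie (`Sn = 0`) nothing is flagged and a degenerate-scale
#' warning is raised.
#'
#' @param x Numeric vector, length >= 3.
#' @param criterion Multiplier of the Sn scale (default 3).
#' @return An `outlier_screen` tibble with columns `value`, `distance`
#'   (robust z-score) and `flag`, plus attributes `median`, `sn` and
#'   `criterion`.
#' @export
screen_outliers <- function(x, criterion = 3) {
  if (length(x) < 3L) stop("`x` must have at least 3 values", call. = FALSE)
  med <- stats::median(x)
  sn <- sn_scale(x)
  if (sn == 0) {
    warning("degenerate scale: Sn = 0, no outliers flagged", call. = FALSE)
    dist <- rep(NA_real_, length(x))
    flag <- rep(FALSE, length(x))
  } else {
    dist <- abs(x - med) / sn
    flag <- dist > criterion
  }
  out <- tibble::tibble(value = x, distance = dist, flag = flag)
  attr(out, "median") <- med
  attr(out, "sn") <- sn
  attr(out, "criterion") <- criterion
  class(out) <- c("outlier_screen", class(out))
  out
}

#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between two paired measurements of the same
#' quantity (here, the same parameter estimated by two procedures): the
#' mean difference (`bias`), the limits of agreement at `bias +/- 1.96 *
#' SD` of the differences, t-based 95% confidence intervals for the bias
#' (`+/- t * SD / sqrt(n)`) and for each limit (`+/- t * SD * sqrt(3/n)`),
#' and the regression slope of the differences on the pair means (a
#' non-zero slope signals proportional bias).
#'
#' @param a,b Paired numeric vectors (same length, n >= 3). Differences
#'   are `a - b`, so swapping the arguments negates the bias and mirrors
#'   the limits.
#' @param pair Optional character length-2 labels for the two methods.
#' @param conf Confidence level for the intervals (default 0.95).
#' @return An object of class `psy_agreement` with [tidy()] and
#'   [autoplot()] methods; fields include `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `span`, `ci_bias`, `ci_loa_low`, `ci_loa_high`, `slope`,
#'   `slope_p`, `n`.
#' @export
bland_altman <- function(a, b, pair = c("A", "B"), conf = 0.95) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa_low <- bias - 1.96 * sdd
  loa_high <- bias + 1.96 * sdd
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  se_bias <- sdd / sqrt(n)
  se_loa <- sdd * sqrt(3 / n)
  means <- (a + b) / 2
  reg <- stats::lm(d ~ means)
  slope <- unname(stats::coef(reg)[2])
  slope_p <- if (stats::sd(means) == 0 || stats::sd(d) == 0) NA_real_ else {
    suppressWarnings(summary(reg)$coefficients[2, 4])
  }
  if (is.na(slope)) slope <- 0
  structure(list(
    pair = pair, n = n, bias = bias, sd_diff = sdd,
    loa_low = loa_low, loa_high = loa_high, span = loa_high - loa_low,
    ci_bias = bias + c(-1, 1) * tcrit * se_bias,
    ci_loa_low = loa_low + c(-1, 1) * tcrit * se_loa,
    ci_loa_high = loa_high + c(-1, 1) * tcrit * se_loa,
    slope = slope, slope_p = slope_p, conf = conf,
    data = tibble::tibble(mean = means, diff = d)
  ), class = "psy_agreement")
}

#' @export
print.psy_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement: %s vs %s (n = %d)\n",
              x$pair[1], x$pair[2], x$n))
  cat(sprintf("  bias = %.4g [%.4g, %.4g]\n", x$bias, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  limits of agreement: [%.4g, %.4g] (span %.4g)\n",
              x$loa_low, x$loa_high, x$span))
  cat(sprintf("  slope of diff on mean: %.3g (p = %.3g)\n", x$slope, x$slope_p))
  invisible(x)
}

#' Normality-gated pairwise correlation
#'
#' Pearson when a Shapiro-Wilk test (at `alpha`, per margin) rejects
#' non-normality for neither variable, Spearman otherwise -- the gate used
#' throughout the procedure-comparison tables. Two-sided p-value.
#'
#' @param a,b Paired numeric vectors, n >= 4, non-constant.
#' @param alpha Significance level of the normality gate.
#' @return An object of class `psy_correlation`: list with `method`
#'   (`"pearson"` or `"spearman"`), `estimate`, `p_value`, `n`, and the
#'   Shapiro-Wilk p-values `shapiro_p`.
#' @export
correlation_auto <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 4L) stop("need at least 4 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  sw <- c(a = stats::shapiro.test(a)$p.value, b = stats::shapiro.test(b)$p.value)
  method <- if (all(sw > alpha)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(a, b, method = method, exact = FALSE))
  structure(list(method = method, estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = length(a), shapiro_p = sw),
            class = "psy_correlation")
}

#' @export
print.psy_correlation <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, p = %.4g (n = %d)\n",
              tools::toTitleCase(x$method), x$estimate, x$p_value, x$n))
  invisible(x)
}

#' Log-transform JND values
#'
#' JND distributions are typically right-skewed, and a Box-Cox profile on
#' simulated JNDs supports a log transform. Because mirror-image fits can
#' produce negative JNDs, a shift is applied before the log when needed:
#' `log(jnd + shift)` with `shift = 0` when all values are positive, else
#' `shift = |min(jnd)| + epsilon` (with a warning).
#'
#' @param jnd Numeric vector of JNDs.
#' @param epsilon Offset added beyond `|min|` for non-positive inputs;
#'   defaults to 0.1% of the largest absolute value (scale-aware).
#' @return The transformed vector, with attribute `shift`.
#' @export
transform_jnd <- function(jnd, epsilon = NULL) {
  stopifnot(length(jnd) >= 1L, all(is.finite(jnd)))
  epsilon <- epsilon %||% max(1e-3 * max(abs(jnd)), .Machine$double.eps)
  shift <- if (all(jnd > 0)) 0 else {
    warning(sprintf("non-positive JNDs present; shifting by %.4g before log",
                    abs(min(jnd)) + epsilon), call. = FALSE)
    abs(min(jnd)) + epsilon
  }
  out <- log(jnd + shift)
  attr(out, "shift") <- shift
  out
}

#' Block-wise repeated-measures analysis (learning effect)
#'
#' One-way repeated-measures ANOVA of an estimate (PSE or transformed JND)
#' on session block (1-3), the desk-scale substitute for the study-scale
#' mixed-model analysis. The partition is the classical within-subject
#' one: total SS = block SS + observer SS + residual SS, with
#' `F = MS_block / MS_residual` on `(b - 1, (b - 1)(n - 1))` degrees of
#' freedom (defined as 0 when the between-block SS is exactly 0).
#' Observers with incomplete blocks are dropped with a warning. Pairwise
#' block mean differences are reported with unadjusted paired t-tests.
#'
#' @param data A data frame with one estimate per observer and block.
#' @param value Column name (string) of the estimate.
#' @param observer,block Column names of the observer and block ids.
#' @return An object of class `psy_block_analysis`: per-block summary
#'   tibble (`mean`, 95% CI), `f_statistic`, `df`, `p_value`, `pairwise`
#'   tibble, and `n_observers`.
#' @export
block_analysis <- function(data, value = "jnd", observer = "observer_id",
                           block = "block") {
  stopifnot(all(c(value, observer, block) %in% names(data)))
  df <- tibble::tibble(observer = data[[observer]],
                       block = as.integer(data[[block]]),
                       value = data[[value]])
  blocks <- sort(unique(df$block))
  b <- length(blocks)
  if (b < 2L) stop("need at least 2 blocks", call. = FALSE)
  counts <- table(df$observer)
  complete <- names(counts)[counts == b]
  if (length(complete) < length(counts)) {
    warning(sprintf("dropped %d observer(s) with incomplete blocks",
                    length(counts) - length(complete)), call. = FALSE)
    df <- df[df$observer %in% complete, ]
  }
  n <- length(unique(df$observer))
  if (n < 2L) stop("need at least 2 complete observers", call. = FALSE)

  grand <- mean(df$value)
  block_means <- tapply(df$value, df$block, mean)
  obs_means <- tapply(df$value, df$observer, mean)
  ss_block <- n * sum((block_means - grand)^2)
  ss_obs <- b * sum((obs_means - grand)^2)
  ss_tot <- sum((df$value - grand)^2)
  ss_err <- max(ss_tot - ss_block - ss_obs, 0)
  df1 <- b - 1L
  df2 <- (b - 1L) * (n - 1L)
  ms_block <- ss_block / df1
  ms_err <- ss_err / df2
  f_stat <- if (ss_block == 0) 0 else ms_block / ms_err
  p_value <- if (ss_block == 0) 1 else stats::pf(f_stat, df1, df2,
                                                 lower.tail = FALSE)

  summary_tbl <- df |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      ci_low = .data$mean - stats::qt(0.975, .data$n - 1) * .data$sd / sqrt(.data$n),
      ci_high = .data$mean + stats::qt(0.975, .data$n - 1) * .data$sd / sqrt(.data$n)
    )

  pairs <- utils::combn(blocks, 2L, simplify = FALSE)
  wide <- tidyr::pivot_wider(df, names_from = "block", values_from = "value",
                             names_prefix = "b")
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    v1 <- wide[[paste0("b", pr[1])]]
    v2 <- wide[[paste0("b", pr[2])]]
    diffs <- v2 - v1
    tt <- if (stats::sd(diffs) == 0) {
      list(p.value = if (mean(diffs) == 0) 1 else 0)
    } else stats::t.test(diffs)
    tibble::tibble(block_a = pr[1], block_b = pr[2],
                   mean_diff = mean(diffs), p_value = tt$p.value)
  })

  structure(list(summary = summary_tbl, f_statistic = f_stat,
                 df = c(df1, df2), p_value = p_value, pairwise = pairwise,
                 n_observers = n,
                 ss = c(block = ss_block, observer = ss_obs, error = ss_err)),
            class = "psy_block_analysis")
}

#' @export
print.psy_block_analysis <- function(x, ...) {
  cat(sprintf("Repeated-measures block analysis (n = %d observers)\n",
              x$n_observers))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$df[1], x$df[2],
              x$f_statistic, x$p_value))
  print(x$summary)
  invisible(x)
}

#' @importFrom stats t.test
NULL
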