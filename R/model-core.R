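#' Lapse-corrected cumulative-Gaussian psychometric function
#'
#' Probability of a "yes" response at stimulus level `x` under the
#' three-parameter model
#' \deqn{P_{yes}(x) = \lambda + (1 - 2\lambda)\,\Phi\!\left(\frac{x - m}{sd}\right)}
#' where `m` is the mean of the underlying normal (the 50% point, i.e. the
#' PSE), `sd` its standard deviation (inversely related to the slope) and
#' `lapse` (\eqn{\lambda}) a stimulus-independent error rate that compresses
#' both asymptotes to `[lapse, 1 - lapse]`. `P(m) = 0.5` for any lapse.
#'
#' A negative `sd` yields the mirror-image (decreasing) function; `sd = 0`
#' is an error.
#'
#' @param x Numeric vector of stimulus values.
#' @param m Mean of the fitted normal, in stimulus units.
#' @param sd Standard deviation of the fitted normal, in stimulus units.
#'   Must be non-zero; negative values flip the slope.
#' @param lapse Lapse rate in `[0, 0.5)`.
#' @return Numeric vector of response probabilities.
#' @seealso [pf_quantile()], [pf_jnd()], [fit_psychometric()]
#' @examples
#' pf_yes(1.6, m = 1.6, sd = 0.1)          # 0.5 at the PSE
#' pf_yes(10, m = 1.6, sd = 0.1, lapse = 0.06)  # upper asymptote 0.94
#' @export
pf_yes <- function(x, m, sd, lapse = 0) {
  check_params(m, sd, lapse)
  lapse + (1 - 2 * lapse) * stats::pnorm((x - m) / sd)
}

#' Invert the psychometric function
#'
#' Closed-form stimulus level at which the response probability equals `p`:
#' `x = m + sd * qnorm((p - lapse) / (1 - 2 * lapse))`. Only probabilities
#' strictly inside the attainable band `(lapse, 1 - lapse)` are reachable.
#'
#' @param p Probability (or vector of probabilities) to invert.
#' @inheritParams pf_yes
#' @return Stimulus value(s) such that `pf_yes(x, m, sd, lapse) == p`.
#' @export
pf_quantile <- function(p, m, sd, lapse = 0) {
  check_params(m, sd, lapse)
  if (any(p <= lapse | p >= 1 - lapse)) {
    stop("unreachable quantile: `p` must lie strictly inside (lapse, 1 - lapse)",
         call. = FALSE)
  }
  m + sd * stats::qnorm((p - lapse) / (1 - 2 * lapse))
}

#' Just-noticeable difference of a psychometric function
#'
#' `JND = (x_.75 - x_.25) / 2`, computed by exact inversion of the
#' lapse-corrected model (not the lapse-free shortcut `0.6745 * sd`), so
#' the value is defined on response probability, where the definition
#' lives. Requires `lapse < 0.25` for the 25%/75% points to be reachable.
#' Negative `sd` gives a negative JND (mirror-image function).
#'
#' @inheritParams pf_yes
#' @return The JND in stimulus units; independent of `m`.
#' @export
pf_jnd <- function(sd, lapse = 0, m = 0) {
  (pf_quantile(0.75, m, sd, lapse) - pf_quantile(0.25, m, sd, lapse)) / 2
}

check_params <- function(m, sd, lapse) {
  if (any(!is.finite(m)) || any(!is.finite(sd)) || any(!is.finite(lapse))) {
    stop("psychometric parameters must be finite", call. = FALSE)
  }
  if (any(sd == 0)) stop("invalid parameter: `sd` must be non-zero", call. = FALSE)
  if (any(lapse < 0 | lapse >= 0.5)) {
    stop("invalid parameter: `lapse` must lie in [0, 0.5)", call. = FALSE)
  }
  invisible(TRUE)
}

# Accepts either per-trial records (columns stimulus, response) or an
# aggregated table (stimulus, n, n_yes); returns the aggregated form.
aggregate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L) stop("`trials` must be non-empty", call. = FALSE)
  if (all(c("n", "n_yes") %in% names(trials))) {
    agg <- tibble::as_tibble(trials[, c("stimulus", "n", "n_yes")])
  } else {
    if (!all(c("stimulus", "response") %in% names(trials))) {
      stop("`trials` needs columns stimulus/response or stimulus/n/n_yes",
           call. = FALSE)
    }
    resp <- trials$response
    if (!all(resp %in% c(0, 1))) stop("responses must be binary 0/1", call. = FALSE)
    agg <- dplyr::summarise(dplyr::group_by(trials, .data$stimulus),
                            n = dplyr::n(), n_yes = sum(.data$response),
                            .groups = "drop")
  }
  if (any(agg$n_yes < 0 | agg$n_yes > agg$n)) {
    stop("invalid aggregated counts", call. = FALSE)
  }
  agg
}

#' Log-likelihood of psychometric parameters
#'
#' Bernoulli log-likelihood of `(m, sd, lapse)` for a set of yes/no trials,
#' in nats. Predicted probabilities are clipped to `[1e-9, 1 - 1e-9]` so
#' that lapse-free parameters never yield `-Inf`.
#'
#' @param trials Data frame of per-trial records (columns `stimulus`,
#'   `response` coded 0/1) or pre-aggregated counts (columns `stimulus`,
#'   `n`, `n_yes`).
#' @inheritParams pf_yes
#' @return Scalar log-likelihood in nats.
#' @export
pf_loglik <- function(trials, m, sd, lapse = 0) {
  agg <- aggregate_trials(trials)
  p <- clip_prob(pf_yes(agg$stimulus, m, sd, lapse))
  sum(agg$n_yes * log(p) + (agg$n - agg$n_yes) * log1p(-p))
}

#' Maximum-likelihood fit of the psychometric function
#'
#' Fits the lapse-corrected cumulative Gaussian to yes/no trial data by
#' maximising the Bernoulli likelihood with a derivative-free simplex
#' (Nelder-Mead) run from five deterministic starting points spread over
#' the parameter box (the first start is seeded by a probit GLM where the
#' data allow one); the best likelihood wins, with ties broken towards the
#' smallest `|sd|`. Parameters are optimised on a logistic transform of the
#' box so the constraints hold exactly.
#'
#' By default the slope is constrained positive (`sd` inside its box). With
#' `allow_negative_slope = TRUE` a mirror-image fit (negative `sd`, hence a
#' negative JND) is also attempted and returned when it attains a higher
#' likelihood — data that are mostly "yes" below threshold can then be
#' described as fitted rather than rejected.
#'
#' @param trials Per-trial records (`stimulus`, `response`) or aggregated
#'   counts (`stimulus`, `n`, `n_yes`).
#' @param bounds Parameter box: a list with numeric length-2 elements `m`,
#'   `sd` (both endpoints > 0) and `lapse`. Defaults to a data-driven box:
#'   `m` over the observed stimulus range, `sd` up to that range, `lapse`
#'   in `[0, 0.06]`. Pass [psy_bounds()] of an experiment configuration to
#'   use the QUEST+ parameter domain.
#' @param allow_negative_slope Also consider decreasing functions.
#' @param n_starts Number of deterministic multi-starts (default 5).
#' @param reltol Convergence tolerance passed to [stats::optim()].
#' @return An object of class `psyfit`: a list with elements `m`, `sd`,
#'   `lapse`, `pse` (`= m`), `jnd` (exact inversion, `NA` if unreachable),
#'   `loglik`, `converged`, `degenerate` (all responses identical),
#'   `n_trials`, and `bounds`. Has [tidy()] and [glance()] methods.
#' @examples
#' obs <- simulated_observer(m = 1.6, sd = 0.1, lapse = 0.02)
#' set.seed(1)
#' x <- runif(400, 1.2, 2.0)
#' trials <- tibble::tibble(stimulus = x, response = respond(obs, x))
#' fit <- fit_psychometric(trials)
#' tidy(fit)
#' @export
fit_psychometric <- function(trials, bounds = NULL,
                             allow_negative_slope = FALSE,
                             n_starts = 5, reltol = 1e-6) {
  agg <- aggregate_trials(trials)
  n_trials <- sum(agg$n)
  span <- diff(range(agg$stimulus))
  if (is.null(bounds)) {
    bounds <- list(
      m = range(agg$stimulus),
      sd = c(max(span, 1e-6) / 200, max(span, 1e-6)),
      lapse = c(0, 0.06)
    )
  }
  check_bounds(bounds)
  degenerate <- sum(agg$n_yes) == 0 || sum(agg$n_yes) == n_trials ||
    length(unique(agg$stimulus)) < 2L

  best <- optimise_box(agg, bounds, n_starts, reltol)
  if (isTRUE(allow_negative_slope)) {
    flipped <- agg
    flipped$n_yes <- flipped$n - flipped$n_yes
    alt <- optimise_box(flipped, bounds, n_starts, reltol)
    if (alt$loglik > best$loglik + 1e-9) {
      alt$par["sd"] <- -alt$par["sd"]
      best <- alt
    }
  }

  par <- best$par
  jnd <- if (par[["lapse"]] < 0.25) pf_jnd(par[["sd"]], par[["lapse"]]) else NA_real_
  structure(list(
    m = par[["m"]], sd = par[["sd"]], lapse = par[["lapse"]],
    pse = par[["m"]], jnd = jnd, loglik = best$loglik,
    converged = best$converged && !degenerate, degenerate = degenerate,
    n_trials = n_trials, bounds = bounds,
    allow_negative_slope = allow_negative_slope
  ), class = "psyfit")
}

check_bounds <- function(bounds) {
  stopifnot(is.list(bounds), all(c("m", "sd", "lapse") %in% names(bounds)))
  for (nm in c("m", "sd", "lapse")) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      stop("bounds$", nm, " must be a finite, increasing length-2 vector",
           call. = FALSE)
    }
  }
  if (bounds$sd[1] <= 0) stop("bounds$sd must be strictly positive", call. = FALSE)
  if (bounds$lapse[1] < 0 || bounds$lapse[2] >= 0.5) {
    stop("bounds$lapse must lie in [0, 0.5)", call. = FALSE)
  }
  invisible(TRUE)
}

# Box-constrained NM on the logistic transform of (m, sd, lapse).
optimise_box <- function(agg, bounds, n_starts, reltol) {
  lo <- c(bounds$m[1], bounds$sd[1], bounds$lapse[1])
  hi <- c(bounds$m[2], bounds$sd[2], bounds$lapse[2])
  to_par <- function(u) lo + (hi - lo) * stats::plogis(u)
  to_u <- function(par) {
    f <- pmin(pmax((par - lo) / (hi - lo), 1e-4), 1 - 1e-4)
    stats::qlogis(f)
  }
  nll <- function(u) {
    par <- to_par(u)
    p <- clip_prob(pf_yes(agg$stimulus, par[1], par[2], par[3]))
    -sum(agg$n_yes * log(p) + (agg$n - agg$n_yes) * log1p(-p))
  }

  starts <- fit_starts(agg, lo, hi, n_starts)
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(to_u(s), nll, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 2000)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    cand <- list(par = setNames(to_par(res$par), c("m", "sd", "lapse")),
                 loglik = -res$value, converged = res$convergence == 0L)
    if (is.null(best) || cand$loglik > best$loglik + 1e-9 ||
        (abs(cand$loglik - best$loglik) <= 1e-9 &&
         abs(cand$par[["sd"]]) < abs(best$par[["sd"]]))) {
      best <- cand
    }
  }
  best
}

# Deterministic multi-starts: a probit-GLM seed plus fixed fractions of the
# box (geometric spacing for sd).
fit_starts <- function(agg, lo, hi, n_starts) {
  frac <- list(
    c(0.50, 0.50, 0.25),
    c(0.25, 0.25, 0.50),
    c(0.75, 0.75, 0.10),
    c(0.40, 0.90, 0.40),
    c(0.60, 0.10, 0.60)
  )
  geom <- function(lo, hi, f) exp(log(lo) + f * (log(hi) - log(lo)))
  starts <- lapply(frac[seq_len(max(1, min(n_starts, length(frac))))],
                   function(f) {
                     c(lo[1] + f[1] * (hi[1] - lo[1]),
                       geom(lo[2], hi[2], f[2]),
                       lo[3] + f[3] * (hi[3] - lo[3]))
                   })
  glm_fit <- tryCatch({
    fit <- suppressWarnings(stats::glm(
      cbind(n_yes, n - n_yes) ~ stimulus,
      family = stats::binomial(link = "probit"), data = agg))
    b <- stats::coef(fit)
    if (is.finite(b[2]) && b[2] > 0) {
      c(-b[1] / b[2], 1 / b[2], lo[3] + 0.25 * (hi[3] - lo[3]))
    } else NULL
  }, error = function(e) NULL)
  if (!is.null(glm_fit)) {
    glm_fit <- pmin(pmax(glm_fit, lo + 1e-4 * (hi - lo)), hi - 1e-4 * (hi - lo))
    starts[[1]] <- glm_fit
  }
  starts
}

#' @export
print.psyfit <- function(x, ...) {
  cat("Psychometric fit (lapse-corrected cumulative Gaussian)\n")
  cat(sprintf("  m (PSE) = %.4g, sd = %.4g, lapse = %.4g\n", x$m, x$sd, x$lapse))
  cat(sprintf("  JND = %.4g, log-likelihood = %.2f (n = %d trials)\n",
              x$jnd, x$loglik, x$n_trials))
  if (x$degenerate) cat("  note: degenerate data (single response category)\n")
  if (!x$converged) cat("  note: optimiser did not converge\n")
  invisible(x)
}
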