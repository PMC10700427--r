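# Independent oracles used to freeze expected values. Each is written as a
# direct, brute-force computation, kept independent of the package's own
# code paths.

# Lapse-corrected cumulative Gaussian via Simpson quadrature of the
# standard-normal density (accurate to well below 1e-10).
oracle_p_yes <- function(x, m, sd, lapse = 0, h = 1e-3) {
  z <- (x - m) / sd
  lower <- -12
  if (z <= lower) return(lapse)
  n <- ceiling((z - lower) / h)
  if (n %% 2 == 1) n <- n + 1
  grid <- seq(lower, z, length.out = n + 1)
  f <- exp(-grid^2 / 2) / sqrt(2 * pi)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  phi <- sum(w * f) * (grid[2] - grid[1]) / 3
  lapse + (1 - 2 * lapse) * phi
}

# Invert the psychometric function by bisection on pf_yes.
oracle_quantile <- function(p, m, sd, lapse = 0, lo = m - 20 * abs(sd),
                            hi = m + 20 * abs(sd)) {
  stopifnot(sd > 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pf_yes(mid, m, sd, lapse) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Sn by explicit double loop (high median of each row of pairwise absolute
# differences, then low median across rows), with the same consistency
# constant and finite-sample factors.
oracle_sn <- function(x) {
  n <- length(x)
  himeds <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) d[j] <- abs(x[i] - x[j])
    d <- sort(d)
    himeds[i] <- d[floor(n / 2) + 1]
  }
  himeds <- sort(himeds)
  lomed <- himeds[floor((n + 1) / 2)]
  small <- c(0.743, 1.851, 0.954, 1.351, 0.993, 1.198, 1.005, 1.131)
  cn <- if (n <= 9) small[n - 1] else if (n %% 2 == 1) n / (n - 0.9) else 1
  1.1926 * cn * lomed
}

# Exhaustive expected-entropy stimulus selection on a quest state: two
# explicit loops over stimuli and outcomes, entropy computed directly from
# the normalised updated posterior.
oracle_quest_select <- function(state) {
  stim <- state$cache$stim
  post <- state$posterior
  g <- state$cache$grid
  eh <- numeric(length(stim))
  for (k in seq_along(stim)) {
    p1 <- pmin(pmax(g$lapse + (1 - 2 * g$lapse) *
                      pnorm((stim[k] - g$m) / g$sd), 1e-9), 1 - 1e-9)
    acc <- 0
    for (r in c(1L, 0L)) {
      lik <- if (r == 1L) p1 else 1 - p1
      w <- post * lik
      pr <- sum(w)
      if (pr > 0) {
        q <- w / pr
        nz <- q > 0
        acc <- acc + pr * (-sum(q[nz] * log(q[nz])))
      }
    }
    eh[k] <- acc
  }
  list(stimulus = stim[which.min(eh)], profile = eh)
}

# Direct normalised-product posterior over all grid cells for a fixed
# trial list.
oracle_quest_posterior <- function(config, trials) {
  g <- expand.grid(m = config$grid$m, sd = config$grid$sd,
                   lapse = config$grid$lapse, KEEP.OUT.ATTRS = FALSE)
  post <- rep(1, nrow(g))
  for (t in seq_len(nrow(trials))) {
    p1 <- pmin(pmax(g$lapse + (1 - 2 * g$lapse) *
                      pnorm((trials$stimulus[t] - g$m) / g$sd), 1e-9),
               1 - 1e-9)
    post <- post * if (trials$response[t] == 1) p1 else 1 - p1
  }
  post / sum(post)
}

# Box-Cox profile log-likelihood over a lambda grid.
oracle_boxcox_lambda <- function(x, lambdas = seq(-2, 2, by = 0.01)) {
  n <- length(x)
  ll <- vapply(lambdas, function(lam) {
    y <- if (abs(lam) < 1e-12) log(x) else (x^lam - 1) / lam
    -n / 2 * log(sum((y - mean(y))^2) / n) + (lam - 1) * sum(log(x))
  }, numeric(1))
  lambdas[which.max(ll)]
}

# Reduced quest configuration used by the selection-oracle tests: a 5 x 5
# x 2 parameter grid over 7 stimuli (sampler adjusted to stay inside).
reduced_quest_config <- function() {
  cfg <- experiment_config(1)
  cfg$stim_domain <- seq(1.3, 1.9, by = 0.1)
  cfg$grid <- list(m = seq(1.4, 1.8, by = 0.1),
                   sd = c(0.05, 0.1, 0.15, 0.2, 0.25),
                   lapse = c(0, 0.03))
  cfg$sampler <- list(m = c(1.45, 1.75), sd = c(0.06, 0.2),
                      lapse = c(0, 0.03))
  cfg
}

# Build a trials tibble from aggregated yes-counts (for noiseless fits).
trials_from_counts <- function(stimulus, n, n_yes) {
  tibble::tibble(stimulus = stimulus, n = n, n_yes = n_yes)
}
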