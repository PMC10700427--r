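#' Create a simulated observer
#'
#' A simulated observer answers yes/no discrimination trials by Bernoulli
#' draws from the lapse-corrected cumulative-Gaussian model ([pf_yes()])
#' with true parameters `(m, sd, lapse)`. Optional per-block `drift`
#' factors multiply `sd` in blocks 1-3, emulating the fast perceptual
#' learning seen in peripheral-vision tasks: `drift = c(1, 0.8, 0.6)`
#' means the observer's underlying spread shrinks over the session, so
#' later blocks yield smaller JNDs. `drift = c(1, 1, 1)` is a stationary
#' observer.
#'
#' @param m,sd,lapse True psychometric parameters (see [pf_yes()]).
#' @param drift Length-3 positive multiplicative factors applied to `sd`
#'   in blocks 1, 2 and 3.
#' @param response_mapping `"standard"` codes "yes" (stimulus judged
#'   greater / more clockwise / target-first) as 1; `"inverted"` flips the
#'   recorded coding, emulating a swapped key assignment.
#' @return An object of class `psy_observer`.
#' @export
simulated_observer <- function(m, sd, lapse = 0, drift = c(1, 1, 1),
                               response_mapping = c("standard", "inverted")) {
  check_params(m, sd, lapse)
  response_mapping <- match.arg(response_mapping)
  stopifnot(length(drift) == 3L, all(drift > 0))
  structure(list(m = m, sd = sd, lapse = lapse, drift = as.numeric(drift),
                 response_mapping = response_mapping),
            class = "psy_observer")
}

# True yes-probability of an observer at stimulus x in a given block.
observer_p_yes <- function(observer, x, block = 1L) {
  stopifnot(inherits(observer, "psy_observer"), block %in% 1:3)
  pf_yes(x, observer$m, observer$sd * observer$drift[block], observer$lapse)
}

#' Draw yes/no responses from a simulated observer
#'
#' Vectorised Bernoulli draws using the current R RNG stream; wrap in
#' `set.seed()` (or use the seeded procedure runners) for reproducibility.
#'
#' @param observer A [simulated_observer()].
#' @param x Stimulus value(s).
#' @param block Session block 1-3 (selects the drift factor).
#' @return Integer vector of 0/1 responses (1 = "yes" under the standard
#'   mapping).
#' @export
respond <- function(observer, x, block = 1L) {
  p <- observer_p_yes(observer, x, block)
  r <- as.integer(stats::runif(length(x)) < p)
  if (observer$response_mapping == "inverted") r <- 1L - r
  r
}

# Internal: deterministic responses from pre-drawn uniforms, used by the
# seeded procedure runners so stimulus-selection randomness and response
# randomness live on separate streams.
respond_u <- function(observer, x, block, u) {
  p <- observer_p_yes(observer, x, block)
  r <- as.integer(u < p)
  if (observer$response_mapping == "inverted") r <- 1L - r
  r
}

#' Cohort specification
#'
#' Describes a cohort of simulated observers for one experiment: how many,
#' how their true parameters are sampled, and the master seed. Observer
#' parameters are drawn from the configuration's default samplers (uniform
#' `m` over the central 60% of its domain, log-uniform `sd` over the middle
#' of its domain, uniform lapse) unless a custom `sampler` is supplied.
#' Procedure orders cycle deterministically through all six permutations of
#' (QUEST+, CS, staircase), emulating counterbalancing.
#'
#' @param config An [experiment_config()] object.
#' @param n_observers Cohort size (the study-scale default is 21).
#' @param seed Master seed for the cohort.
#' @param drift Length-3 drift factors shared by all observers.
#' @param sampler Optional list with length-2 ranges `m`, `sd`, `lapse`
#'   overriding the configuration's default sampler; must stay inside the
#'   parameter domain.
#' @return An object of class `psy_cohort_spec`.
#' @export
cohort_spec <- function(config, n_observers = 21, seed = 1,
                        drift = c(1, 1, 1), sampler = NULL) {
  stopifnot(inherits(config, "psy_config"), n_observers >= 1)
  sampler <- sampler %||% config$sampler
  g <- config$grid
  if (sampler$m[1] < min(g$m) || sampler$m[2] > max(g$m) ||
      sampler$sd[1] < min(g$sd) || sampler$sd[2] > max(g$sd) ||
      sampler$lapse[1] < min(g$lapse) || sampler$lapse[2] > max(g$lapse)) {
    stop("configuration error: sampler ranges escape the parameter domain",
         call. = FALSE)
  }
  structure(list(config = config, n_observers = as.integer(n_observers),
                 seed = seed, drift = drift, sampler = sampler),
            class = "psy_cohort_spec")
}

#' All six procedure orders
#'
#' The six permutations of `c("questplus", "cs", "staircase")`, in a fixed
#' order, used for cycling counterbalanced assignment across a cohort.
#'
#' @return A list of six character vectors of length 3.
#' @export
procedure_orders <- function() {
  procs <- c("questplus", "cs", "staircase")
  idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(idx, function(i) procs[i])
}

#' Sample a cohort of simulated observers
#'
#' Deterministic under the spec's master seed: two cohorts built from the
#' same spec are identical. Each observer also receives its own derived
#' response-stream seed, insulating response randomness from the
#' procedures' stimulus randomness.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per observer: `observer_id`, true
#'   parameters `m`, `sd`, `lapse`, `order_id` (1-6), `order` (list-column
#'   of procedure names by block) and `seed` (per-observer sub-seed).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "psy_cohort_spec"))
  n <- spec$n_observers
  s <- spec$sampler
  seeds <- derive_seeds(spec$seed, 4L)
  draw_unif <- function(seed, rng) {
    set.seed(seed)
    stats::runif(n, rng[1], rng[2])
  }
  m <- draw_unif(seeds[1], s$m)
  sd <- exp(draw_unif(seeds[2], log(s$sd)))
  lapse <- draw_unif(seeds[3], s$lapse)
  set.seed(seeds[4])
  obs_seeds <- sample.int(2147483646L, n)
  orders <- procedure_orders()
  order_id <- ((seq_len(n) - 1L) %% 6L) + 1L
  tibble::tibble(
    observer_id = seq_len(n),
    m = m, sd = sd, lapse = lapse,
    order_id = order_id,
    order = orders[order_id],
    seed = obs_seeds
  )
}

#' @export
print.psy_observer <- function(x, ...) {
  cat(sprintf("Simulated observer: m = %.4g, sd = %.4g, lapse = %.4g\n",
              x$m, x$sd, x$lapse))
  if (!all(x$drift == 1)) {
    cat(sprintf("  drift (sd factors by block): %s\n",
                paste(x$drift, collapse = ", ")))
  }
  invisible(x)
}
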