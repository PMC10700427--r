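#' Experiment configurations
#'
#' Bundles everything that defines one of the three simulated experiments:
#' the stimulus domain, the reference value, the QUEST+ parameter grid, the
#' constant-stimuli schedule, the staircase configuration, and the default
#' cohort samplers.
#'
#' The three experiments are:
#' \describe{
#'   \item{1 (size)}{Disk-diameter discrimination against a 1.6 dva
#'     reference; stimuli 1.2 to 2.0 dva in 0.01 steps.}
#'   \item{2 (orientation)}{Gabor tilt-difference discrimination against a
#'     reference orientation (0 difference); stimuli -24 to 24 degrees in
#'     2-degree steps.}
#'   \item{3 (temporal order)}{Stimulus-onset-asynchrony judgments in
#'     display frames; stimuli -60 to 60 frames, a null SOA meaning
#'     simultaneity.}
#' }
#'
#' @param experiment Integer 1, 2 or 3.
#' @return An object of class `psy_config`: a list with elements
#'   `experiment`, `units`, `reference`, `stim_domain`, `grid` (lists `m`,
#'   `sd`, `lapse` of grid values), `cs` (tibble `stimulus`, `n`),
#'   `staircase` (starts, step schedule, bounds, termination rules),
#'   `quest_n_trials`, and `sampler` (default cohort parameter ranges).
#' @examples
#' cfg <- experiment_config(1)
#' cfg$reference
#' psy_bounds(cfg)
#' @export
experiment_config <- function(experiment) {
  experiment <- match.arg(as.character(experiment), c("1", "2", "3"))
  cfg <- switch(experiment,
    "1" = list(
      experiment = 1L, units = "dva", reference = 1.6,
      stim_domain = seq(1.2, 2.0, by = 0.01),
      grid = list(m = seq(1.2, 2.0, by = 0.01),
                  sd = seq(0.02, 0.3, by = 0.01),
                  lapse = seq(0, 0.06, by = 0.01)),
      cs = tibble::tibble(stimulus = c(seq(1.3, 1.9, by = 0.1), 1.2, 2.0),
                          n = c(rep(24L, 7L), 8L, 8L)),
      staircase = list(starts = c(1.2, 1.6, 2.0),
                       step_schedule = c(0.2, 0.2, 0.1),
                       bounds = c(1.2, 2.0))
    ),
    "2" = list(
      experiment = 2L, units = "deg", reference = 0,
      stim_domain = seq(-24, 24, by = 2),
      grid = list(m = seq(-24, 24, by = 2),
                  sd = seq(1, 20, by = 0.1),
                  lapse = seq(0, 0.08, by = 0.01)),
      cs = tibble::tibble(stimulus = c(seq(-9, 9, by = 3), -15, 15),
                          n = c(rep(24L, 7L), 8L, 8L)),
      staircase = list(starts = c(-28, 0, 28),
                       step_schedule = c(4, 4, 2),
                       bounds = c(-24, 24))
    ),
    "3" = list(
      experiment = 3L, units = "frames", reference = 0,
      stim_domain = seq(-60, 60, by = 1),
      grid = list(m = seq(-40, 40, by = 1),
                  sd = seq(1, 50, by = 1),
                  lapse = seq(0, 0.08, by = 0.01)),
      cs = tibble::tibble(
        stimulus = c(c(3, 6, 9, 12, 15, 18), -c(3, 6, 9, 12, 15, 18),
                     0, 24, -24, 30, -30),
        n = c(rep(12L, 12L), 12L, 6L, 6L, 6L, 6L)),
      staircase = list(starts = c(-40, 0, 40),
                       step_schedule = c(4, 4, 3, 2),
                       bounds = c(-40, 40))
    )
  )
  cfg$staircase$max_reversals <- 15L
  cfg$staircase$max_boundary_hits <- 10L
  cfg$staircase$max_total_trials <- 150L
  cfg$staircase$reversals_for_threshold <- 5L
  cfg$quest_n_trials <- 64L
  cfg$sampler <- default_sampler(cfg$grid)
  class(cfg) <- "psy_config"
  validate_config(cfg)
  cfg
}

# Default cohort samplers: m uniform over the central 60% of its domain,
# sd log-uniform over the central half (log scale) of its domain, lapse
# uniform over the full lapse domain. Keeps simulated observers away from
# the grid boundaries that triggered participant exclusions.
default_sampler <- function(grid) {
  m_rng <- range(grid$m)
  sd_rng <- range(grid$sd)
  m_pad <- 0.2 * diff(m_rng)
  log_sd <- log(sd_rng)
  sd_pad <- 0.25 * diff(log_sd)
  list(
    m = c(m_rng[1] + m_pad, m_rng[2] - m_pad),
    sd = exp(c(log_sd[1] + sd_pad, log_sd[2] - sd_pad)),
    lapse = c(0, max(grid$lapse))
  )
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "psy_config"))
  with(cfg, {
    stopifnot(
      length(stim_domain) > 1L, !is.unsorted(stim_domain),
      all(lengths(grid) > 1L),
      all(grid$sd > 0), all(grid$lapse >= 0), all(grid$lapse < 0.5),
      all(cs$n > 0), nrow(cs) >= 1L,
      length(staircase$starts) == 3L,
      all(staircase$step_schedule > 0),
      staircase$bounds[1] < staircase$bounds[2],
      quest_n_trials > 0L
    )
  })
  # sampler ranges must stay inside the parameter domains
  s <- cfg$sampler
  g <- cfg$grid
  if (s$m[1] < min(g$m) || s$m[2] > max(g$m) ||
      s$sd[1] < min(g$sd) || s$sd[2] > max(g$sd) ||
      s$lapse[1] < min(g$lapse) || s$lapse[2] > max(g$lapse)) {
    stop("configuration error: sampler ranges escape the parameter domain",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Parameter box of an experiment configuration
#'
#' The (m, sd, lapse) box spanned by the QUEST+ parameter grid, in the form
#' [fit_psychometric()] expects, so that fits from all three procedures are
#' constrained to the same domain.
#'
#' @param config A [experiment_config()] object.
#' @return A list with length-2 elements `m`, `sd`, `lapse`.
#' @export
psy_bounds <- function(config) {
  stopifnot(inherits(config, "psy_config"))
  list(m = range(config$grid$m), sd = range(config$grid$sd),
       lapse = range(config$grid$lapse))
}

#' Read an experiment configuration from a YAML or JSON file
#'
#' The file must name the base `experiment` (1, 2 or 3); any other top-level
#' fields (for instance `quest_n_trials`, or `staircase` sub-fields) override
#' the corresponding defaults from [experiment_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `psy_config`.
#' @export
read_experiment_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw$experiment)) stop("config file must name `experiment`", call. = FALSE)
  cfg <- experiment_config(raw$experiment)
  for (nm in setdiff(names(raw), "experiment")) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]]) && !is.data.frame(cfg[[nm]])) {
      for (sub in names(raw[[nm]])) cfg[[nm]][[sub]] <- raw[[nm]][[sub]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_config(cfg)
  cfg
}

#' @export
print.psy_config <- function(x, ...) {
  cat(sprintf("Experiment %d configuration (%s)\n", x$experiment, x$units))
  cat(sprintf("  reference: %g %s; stimulus domain: %g to %g (%d values)\n",
              x$reference, x$units, min(x$stim_domain), max(x$stim_domain),
              length(x$stim_domain)))
  cat(sprintf("  QUEST+ grid: %d m x %d sd x %d lapse cells; %d trials\n",
              length(x$grid$m), length(x$grid$sd), length(x$grid$lapse),
              x$quest_n_trials))
  cat(sprintf("  CS schedule: %d trials over %d values\n",
              sum(x$cs$n), nrow(x$cs)))
  cat(sprintf("  staircase: starts %s; steps %s; bounds [%g, %g]\n",
              paste(x$staircase$starts, collapse = ", "),
              paste(x$staircase$step_schedule, collapse = "/"),
              x$staircase$bounds[1], x$staircase$bounds[2]))
  invisible(x)
}
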