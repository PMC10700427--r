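#' Build a method-of-constant-stimuli design
#'
#' The fixed stimulus schedules of the three experiments:
#' \itemize{
#'   \item Experiment 1 (size): diameters 1.3 to 1.9 dva in 0.1 steps, 24
#'     repetitions each, plus 1.2 and 2.0 dva eight times each -- 184
#'     trials.
#'   \item Experiment 2 (orientation): tilt differences -9 to 9 degrees in
#'     3-degree steps, 24 repetitions each, plus -15 and 15 degrees eight
#'     times each -- 184 trials.
#'   \item Experiment 3 (temporal order): signed SOAs of 3 to 18 frames in
#'     3-frame steps, 12 repetitions per sign, plus 0 frames twelve times
#'     and the signed extremes +/-24 and +/-30 six times each -- 180
#'     trials, sign-balanced (which stimulus leads).
#' }
#'
#' @param experiment Integer 1, 2 or 3, or an [experiment_config()].
#' @return An object of class `cs_design`: a tibble with columns
#'   `stimulus` and `n` (repetitions), with attributes `experiment` and
#'   `total`.
#' @export
build_cs_design <- function(experiment) {
  cfg <- if (inherits(experiment, "psy_config")) experiment else {
    experiment_config(experiment)
  }
  design <- cfg$cs
  attr(design, "experiment") <- cfg$experiment
  attr(design, "total") <- sum(design$n)
  class(design) <- c("cs_design", class(design))
  design
}

#' Administer a constant-stimuli session to a simulated observer
#'
#' Expands the design's trial multiset, shuffles it with a seeded uniform
#' permutation (stimulus-order randomness and response randomness use
#' separate derived sub-streams), and collects one response per trial.
#'
#' @param observer A [simulated_observer()].
#' @param design A [build_cs_design()] (or an `experiment_config`, whose
#'   design is then built).
#' @param seed Seed for the session.
#' @param block Session block 1-3.
#' @return A trials tibble in the shared schema (`trial_index`, `stimulus`,
#'   `response`, `procedure`, `track_id`, `block`, `valid`).
#' @export
run_cs <- function(observer, design, seed = 1, block = 1L) {
  stopifnot(inherits(observer, "psy_observer"))
  if (inherits(design, "psy_config")) design <- build_cs_design(design)
  stimuli <- rep(design$stimulus, design$n)
  n <- length(stimuli)
  seeds <- derive_seeds(seed, 2L)
  set.seed(seeds[1])
  stimuli <- stimuli[sample.int(n)]
  set.seed(seeds[2])
  u <- stats::runif(n)
  tibble::tibble(
    trial_index = seq_len(n),
    stimulus = stimuli,
    response = respond_u(observer, stimuli, block, u),
    procedure = "cs",
    track_id = NA_integer_,
    block = as.integer(block),
    valid = TRUE
  )
}
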