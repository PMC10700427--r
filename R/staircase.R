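# Randomly interleaved simple up-down staircase tracks.
#
# Each of three tracks starts far below, at, and far above the supposed
# threshold and moves one step against each response ("yes" = stimulus
# judged greater, so the value moves down), targeting the 50% point. The
# step size follows a reversal-indexed schedule; values are clamped to the
# domain bounds and presentations at a bound are counted (pooled over the
# two bounds within a track). A track stops after 15 response reversals or
# 10 boundary presentations; the whole procedure is capped at 150 trials.

# Step size given the number of reversals recorded so far: element k of the
# schedule applies when k - 1 reversals have occurred, the last element
# thereafter.
step_for <- function(schedule, n_reversals) {
  schedule[min(n_reversals + 1L, length(schedule))]
}

new_track_state <- function(start) {
  list(value = start, last_response = NA_integer_, n_reversals = 0L,
       reversal_values = numeric(0), boundary_hits = 0L,
       terminated = FALSE, terminated_by = NA_character_, n_trials = 0L)
}

#' Advance one staircase track by one response
#'
#' Applies the simple up-down rule to a single track: the current value is
#' presented, a boundary presentation is counted if it sits at (or beyond)
#' a domain bound, a reversal is recorded when the response category
#' changes, and the value moves one schedule step down after "yes" and up
#' after "no", clamped to the bounds. Termination flags are set when the
#' track reaches the reversal or boundary limits.
#'
#' This is the single-track micro-step; [run_staircase()] drives three such
#' tracks with random interleaving.
#'
#' @param track A track state as created internally (list with `value`,
#'   `last_response`, `n_reversals`, `reversal_values`, `boundary_hits`,
#'   `terminated`); pass the element of a previous call to continue.
#'   `NULL` (with `start`) creates a fresh track.
#' @param response Binary response to the currently presented value.
#' @param config A staircase configuration: list with `step_schedule`,
#'   `bounds`, `max_reversals`, `max_boundary_hits` (an
#'   [experiment_config()]'s `$staircase`).
#' @param start Starting value when `track` is `NULL`.
#' @return The updated track state; `$value` is the next value to present.
#' @export
step_track <- function(track = NULL, response, config, start = NULL) {
  if (is.null(track)) {
    stopifnot(!is.null(start))
    track <- new_track_state(start)
  }
  if (isTRUE(track$terminated)) {
    stop("track is terminated and receives no further trials", call. = FALSE)
  }
  bounds <- config$bounds
  x <- track$value
  track$n_trials <- track$n_trials + 1L
  if (x <= bounds[1] + 1e-12 || x >= bounds[2] - 1e-12) {
    track$boundary_hits <- track$boundary_hits + 1L
  }
  if (!is.na(track$last_response) && response != track$last_response) {
    track$n_reversals <- track$n_reversals + 1L
    track$reversal_values <- c(track$reversal_values, x)
  }
  track$last_response <- as.integer(response)
  step <- step_for(config$step_schedule, track$n_reversals)
  new_value <- if (response == 1) x - step else x + step
  track$value <- min(max(new_value, bounds[1]), bounds[2])
  if (track$n_reversals >= (config$max_reversals %||% 15L)) {
    track$terminated <- TRUE
    track$terminated_by <- "reversals"
  } else if (track$boundary_hits >= (config$max_boundary_hits %||% 10L)) {
    track$terminated <- TRUE
    track$terminated_by <- "boundary"
  }
  track
}

#' Run the interleaved staircase procedure on a simulated observer
#'
#' Three simple up-down tracks (starts from the configuration) are randomly
#' interleaved: each trial picks uniformly among the non-terminated tracks,
#' presents that track's current value, records the observer's response and
#' advances the track. The run stops when all tracks have terminated (15
#' reversals or 10 boundary presentations each) or at the global 150-trial
#' cap. Interleaving randomness and response randomness use separate
#' sub-streams derived from `seed`, so each is reproducible on its own.
#'
#' @inheritParams run_questplus
#' @return An object of class `staircase_run`: `trials` (shared tibble
#'   schema with `track_id` populated) and `tracks` (per-track tibble with
#'   reversal values as a list-column, boundary hits, and termination
#'   reason).
#' @export
run_staircase <- function(observer, config, seed = 1, block = 1L) {
  stopifnot(inherits(observer, "psy_observer"))
  sc <- if (inherits(config, "psy_config")) config$staircase else config
  seeds <- derive_seeds(seed, 2L)
  cap <- sc$max_total_trials %||% 150L
  set.seed(seeds[1])
  u_int <- stats::runif(cap)
  set.seed(seeds[2])
  u_resp <- stats::runif(cap)

  tracks <- lapply(sc$starts, new_track_state)
  xs <- numeric(cap); rs <- integer(cap); tid <- integer(cap)
  t <- 0L
  while (t < cap) {
    active <- which(!vapply(tracks, `[[`, logical(1), "terminated"))
    if (length(active) == 0L) break
    t <- t + 1L
    k <- active[min(floor(u_int[t] * length(active)) + 1, length(active))]
    x <- tracks[[k]]$value
    r <- respond_u(observer, x, block, u_resp[t])
    tracks[[k]] <- step_track(tracks[[k]], r, sc)
    xs[t] <- x; rs[t] <- r; tid[t] <- k
  }
  idx <- seq_len(t)
  trials <- tibble::tibble(
    trial_index = idx, stimulus = xs[idx], response = rs[idx],
    procedure = "staircase", track_id = tid[idx],
    block = as.integer(block), valid = TRUE
  )
  track_tbl <- tibble::tibble(
    track_id = seq_along(tracks),
    start = sc$starts,
    n_trials = vapply(tracks, `[[`, integer(1), "n_trials"),
    n_reversals = vapply(tracks, `[[`, integer(1), "n_reversals"),
    reversal_values = lapply(tracks, `[[`, "reversal_values"),
    boundary_hits = vapply(tracks, `[[`, integer(1), "boundary_hits"),
    terminated_by = vapply(tracks, function(tr) {
      if (is.na(tr$terminated_by)) "cap" else tr$terminated_by
    }, character(1))
  )
  structure(list(trials = trials, tracks = track_tbl, config = sc),
            class = "staircase_run")
}

# Recover per-track reversal stimulus values from raw trial records by
# scanning for response-category changes within each track.
reversals_from_trials <- function(trials) {
  trials |>
    dplyr::arrange(.data$track_id, .data$trial_index) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_map(function(df, key) {
      flips <- which(diff(df$response) != 0) + 1L
      list(track_id = key$track_id, reversal_values = df$stimulus[flips])
    })
}

#' Conventional staircase threshold
#'
#' The classical estimate: for each track, the mean of its last five
#' reversal stimulus values; the 50% threshold is the mean of the three
#' track means. Tracks with fewer than five reversals contribute the mean
#' of whatever reversals they have, with a warning.
#'
#' @param x A [run_staircase()] result, or a raw trials tibble with
#'   `track_id`, `trial_index`, `stimulus`, `response` columns (reversals
#'   are then recovered by scanning for response changes).
#' @param n_reversals Number of final reversals averaged per track
#'   (default 5).
#' @return The threshold estimate (stimulus units), with attributes
#'   `per_track` (per-track means) and `short_tracks` (ids of tracks with
#'   fewer reversals than requested).
#' @export
conventional_threshold <- function(x, n_reversals = 5) {
  revs <- if (inherits(x, "staircase_run")) {
    lapply(seq_len(nrow(x$tracks)), function(i) {
      list(track_id = x$tracks$track_id[i],
           reversal_values = x$tracks$reversal_values[[i]])
    })
  } else {
    reversals_from_trials(x)
  }
  short <- integer(0)
  per_track <- vapply(revs, function(r) {
    v <- r$reversal_values
    if (length(v) == 0L) return(NA_real_)
    if (length(v) < n_reversals) short <<- c(short, r$track_id)
    mean(tail(v, n_reversals))
  }, numeric(1))
  if (length(short) > 0L || anyNA(per_track)) {
    warning(sprintf(
      "track(s) %s had fewer than %d reversals; used all available reversals",
      paste(unique(c(short, which(is.na(per_track)))), collapse = ", "),
      n_reversals), call. = FALSE)
  }
  out <- mean(per_track, na.rm = TRUE)
  attr(out, "per_track") <- per_track
  attr(out, "short_tracks") <- short
  out
}

#' Bin staircase trials for plotting and CS-comparable summaries
#'
#' Rank-based quantile binning: trials are ordered by stimulus value and
#' split into `n_bins` contiguous, (near-)equal-count bins -- mirroring the
#' nine stimulus values of the constant-stimuli schedules. The psychometric
#' fit itself always consumes per-trial records; bins serve plots and
#' summaries only. When there are fewer distinct stimulus values than bins,
#' bins collapse and the result carries `attr(, "bins_merged") = TRUE`.
#'
#' @param trials Trials tibble (any procedure) with `stimulus`, `response`.
#' @param n_bins Number of bins (default 9).
#' @return Tibble with `bin`, `stimulus` (bin mean), `n`, `n_yes`,
#'   `prop_yes`.
#' @export
bin_for_fit <- function(trials, n_bins = 9) {
  stopifnot(nrow(trials) > 0L)
  n <- nrow(trials)
  n_distinct <- length(unique(trials$stimulus))
  merged <- n_distinct < n_bins
  if (merged) {
    # fewer distinct values than requested bins: one bin per value
    out <- tibble::tibble(stimulus = trials$stimulus,
                          response = trials$response) |>
      dplyr::group_by(.data$stimulus) |>
      dplyr::summarise(n = dplyr::n(), n_yes = sum(.data$response),
                       .groups = "drop") |>
      dplyr::arrange(.data$stimulus) |>
      dplyr::mutate(bin = dplyr::row_number(),
                    prop_yes = .data$n_yes / .data$n) |>
      dplyr::select("bin", "stimulus", "n", "n_yes", "prop_yes")
    attr(out, "bins_merged") <- TRUE
    return(out)
  }
  ord <- order(trials$stimulus)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_of_sorted <- rep(seq_len(n_bins), times = sizes)
  bin <- integer(n)
  bin[ord] <- bin_of_sorted
  out <- tibble::tibble(bin = bin, stimulus = trials$stimulus,
                        response = trials$response) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(stimulus = mean(.data$stimulus), n = dplyr::n(),
                     n_yes = sum(.data$response), .groups = "drop") |>
    dplyr::mutate(prop_yes = .data$n_yes / .data$n)
  attr(out, "bins_merged") <- FALSE
  out
}
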