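#' Configuration for a one-up three-down adaptive staircase
#'
#' Transformed up-down threshold tracking: an incorrect response raises the
#' stimulus amplitude on the next trial; three consecutive correct responses
#' lower it. Amplitude always changes by a fixed number of decibels (amplitude
#' dB, i.e. a factor of `10^(step_db/20)`, ~1.259 for 2 dB). The run ends at
#' the `stop_reversals`-th change of direction.
#'
#' @param start_amplitude Starting amplitude (mA).
#' @param step_db Step size in amplitude decibels (> 0); default 2 dB.
#' @param n_down Consecutive correct responses required before a decrease
#'   (default 3).
#' @param n_up Incorrect responses before an increase (default 1; only 1 is
#'   supported, the classical one-up rule).
#' @param stop_reversals Number of direction changes that terminates the run
#'   (default 5).
#' @param min_amplitude,max_amplitude Clipping bounds (mA); defaults 0 and 6,
#'   the stimulator output ceiling.
#' @param trial_cap Hard trial limit guarding non-termination (default 200).
#' @return A `staircase_config` object.
#' @export
staircase_config <- function(start_amplitude, step_db = 2, n_down = 3,
                             n_up = 1, stop_reversals = 5,
                             min_amplitude = 0, max_amplitude = 6,
                             trial_cap = 200) {
  if (step_db <= 0) abort("`step_db` must be positive.")
  if (n_down < 1) abort("`n_down` must be >= 1.")
  if (n_up != 1) abort("only the one-up rule (`n_up = 1`) is supported.")
  if (stop_reversals < 1) abort("`stop_reversals` must be >= 1.")
  if (min_amplitude < 0 || min_amplitude >= max_amplitude)
    abort("need 0 <= min_amplitude < max_amplitude.")
  if (start_amplitude <= 0) abort("`start_amplitude` must be positive.")
  structure(list(start_amplitude = start_amplitude, step_db = step_db,
                 n_down = n_down, n_up = n_up, stop_reversals = stop_reversals,
                 min_amplitude = min_amplitude, max_amplitude = max_amplitude,
                 trial_cap = trial_cap),
            class = "staircase_config")
}

#' Step an amplitude by a fixed number of decibels
#'
#' Amplitude (field-quantity) decibels: one step multiplies or divides the
#' amplitude by `10^(step_db/20)`.
#'
#' @param a Current amplitude (mA), positive.
#' @param direction `"up"` or `"down"`.
#' @param step_db Step size in dB (>= 0).
#' @param min_amplitude,max_amplitude Optional clipping bounds.
#' @return The stepped (and possibly clipped) amplitude.
#' @examples
#' step_amplitude(1, "up", 2) # 1.258925
#' @export
step_amplitude <- function(a, direction = c("up", "down"), step_db = 2,
                           min_amplitude = -Inf, max_amplitude = Inf) {
  direction <- match.arg(direction)
  if (any(a <= 0)) abort("`a` must be positive.")
  sgn <- if (direction == "up") 1 else -1
  pmin(pmax(a * 10^(sgn * step_db / 20), min_amplitude), max_amplitude)
}

#' Run a one-up three-down staircase against a responder
#'
#' The responder abstracts the subject: any function mapping an amplitude (mA)
#' to a logical correct/incorrect, e.g. a closure over [simulate_2afc()] or a
#' deterministic rule. The three-consecutive-correct counter resets after any
#' amplitude change and after an incorrect response. A reversal is an actual
#' flip in the sign of the applied amplitude step; a step clipped into a
#' no-change at the bounds creates no reversal.
#'
#' @param responder Function `amplitude -> logical(1)`.
#' @param cfg A [staircase_config()].
#' @return A `staircase_run`: list with `trials` (tibble: `trial`,
#'   `amplitude_mA`, `correct`, `reversal`), `reversal_indices`,
#'   `threshold_estimate` (mA, `NA` if the run did not terminate normally),
#'   `terminated_normally`, `estimate_n_trials`, and the config.
#' @examples
#' set.seed(1)
#' obs <- observer_params(2, 0.4)
#' run <- run_staircase(function(a) simulate_2afc(obs, a),
#'                      staircase_config(start_amplitude = 3))
#' run$threshold_estimate
#' @export
run_staircase <- function(responder, cfg) {
  stopifnot(is.function(responder), inherits(cfg, "staircase_config"))
  a <- pmin(pmax(cfg$start_amplitude, max(cfg$min_amplitude, 1e-12)),
            cfg$max_amplitude)
  amps <- numeric(0); corr <- logical(0); rev_idx <- integer(0)
  streak <- 0L
  last_dir <- 0L   # sign of the last applied (non-clipped) step
  aborted <- FALSE
  for (i in seq_len(cfg$trial_cap)) {
    resp <- tryCatch(isTRUE(responder(a)), error = function(e) NA)
    if (is.na(resp)) { aborted <- TRUE; break }
    amps[i] <- a; corr[i] <- resp
    if (!resp) {
      streak <- 0L
      dir <- 1L
    } else {
      streak <- streak + 1L
      dir <- if (streak >= cfg$n_down) -1L else 0L
    }
    if (dir != 0L) {
      streak <- 0L  # counter resets on any amplitude change
      new_a <- step_amplitude(a, if (dir > 0) "up" else "down", cfg$step_db,
                              min_amplitude = cfg$min_amplitude,
                              max_amplitude = cfg$max_amplitude)
      if (new_a != a) {
        if (last_dir != 0L && dir != last_dir) rev_idx <- c(rev_idx, i)
        last_dir <- dir
        a <- new_a
      }
      if (length(rev_idx) >= cfg$stop_reversals) break
    }
  }
  n <- length(amps)
  trials <- tibble::tibble(
    trial = seq_len(n), amplitude_mA = amps, correct = corr,
    reversal = seq_len(n) %in% rev_idx)
  run <- structure(
    list(trials = trials, reversal_indices = rev_idx,
         terminated_normally = !aborted &&
           length(rev_idx) >= cfg$stop_reversals,
         aborted = aborted, config = cfg,
         threshold_estimate = NA_real_, estimate_n_trials = NA_integer_),
    class = "staircase_run")
  if (run$terminated_normally) {
    est <- estimate_threshold(run)
    run$threshold_estimate <- est
    run$estimate_n_trials <- attr(est, "n_trials")
  }
  run
}

#' Threshold estimate from a completed staircase
#'
#' Arithmetic mean of the amplitudes of the 10 trials immediately preceding
#' (and including) the trial at which the final direction change occurred. If
#' fewer than 10 trials are available, all of them are averaged and a warning
#' is raised.
#'
#' @param run A `staircase_run` that terminated normally.
#' @return The threshold estimate (mA), with attribute `n_trials` giving the
#'   number of trials averaged.
#' @export
estimate_threshold <- function(run) {
  stopifnot(inherits(run, "staircase_run"))
  k_rev <- run$config$stop_reversals
  if (length(run$reversal_indices) < k_rev)
    abort("run did not reach the terminating reversal; no threshold defined.")
  k <- run$reversal_indices[k_rev]
  idx <- seq.int(max(1L, k - 9L), k)
  if (length(idx) < 10L)
    warn(sprintf("only %d trials precede the terminating reversal; averaging all of them.",
                 length(idx)))
  est <- mean(run$trials$amplitude_mA[idx])
  attr(est, "n_trials") <- length(idx)
  est
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf("<staircase_run> %d trials, %d reversals, %s\n",
              nrow(x$trials), length(x$reversal_indices),
              if (x$terminated_normally)
                sprintf("threshold %.3f mA", x$threshold_estimate)
              else "did not terminate normally"))
  invisible(x)
}

#' Simulate many staircases against a known observer
#'
#' Convenience wrapper used for convergence studies: runs `n_runs` independent
#' staircases against a simulated 2AFC observer and reports, per run, the
#' threshold estimate and the observer's true accuracy at that estimate.
#'
#' @param obs An [observer_params()].
#' @param cfg A [staircase_config()].
#' @param n_runs Number of runs.
#' @return Tibble: `run`, `threshold_mA`, `accuracy_at_threshold`,
#'   `n_trials`, `terminated`.
#' @export
simulate_staircases <- function(obs, cfg, n_runs = 500) {
  psi <- psi_fun(obs)
  purrr::map_dfr(seq_len(n_runs), function(r) {
    sr <- run_staircase(function(a) simulate_2afc(obs, a), cfg)
    tibble::tibble(
      run = r,
      threshold_mA = sr$threshold_estimate,
      accuracy_at_threshold = if (sr$terminated_normally)
        psi(sr$threshold_estimate) else NA_real_,
      n_trials = nrow(sr$trials),
      terminated = sr$terminated_normally)
  })
}

#' @describeIn run_staircase Plot the trial-by-trial amplitude track with
#'   reversals marked.
#' @param object A `staircase_run`.
#' @param ... Unused.
#' @method autoplot staircase_run
#' @export
autoplot.staircase_run <- function(object, ...) {
  tr <- object$trials
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$trial, y = .data$amplitude_mA)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$correct,
                                     colour = .data$reversal), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "black")) +
    ggplot2::labs(x = "Trial", y = "Amplitude (mA)",
                  shape = "Correct", colour = "Reversal") +
    ggplot2::theme_minimal()
}
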