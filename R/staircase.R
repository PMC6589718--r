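#' Transformed up-down staircase configuration
#'
#' Parameters of the adaptive 3-down/1-up staircase: the tracked temperature
#' change grows by `step` after every incorrect answer and shrinks by `step`
#' after `n_down` successive correct answers, over `n_trials` trials; the
#' threshold is the mean change over the trials after the first `n_discard`.
#'
#' In `"detection"` mode the comparison stimulus is constant at `base_temp`.
#' In `"discrimination"` mode both stimuli change in the same direction; the
#' smaller change is fixed at `reference_delta` (the participant's detection
#' threshold) on every trial and the staircase adapts the larger change, kept
#' strictly above the reference (lower bound `reference_delta + step`).
#'
#' The changing stimulus is never allowed beyond `ceiling` (50 degC) or below
#' `floor` (35 degC): the tracked change is clamped to the largest step-grid
#' value that respects the bound and the block is flagged, mirroring post-hoc
#' exclusion of participants whose staircase hit the stimulator limits.
#'
#' @param base_temp base (initial plateau) temperature, degC.
#' @param direction `"increase"` or `"decrease"`.
#' @param n_down correct answers required per down-step (3).
#' @param n_up incorrect answers per up-step (1; only 1 is supported).
#' @param step step size, degC (0.5).
#' @param initial_delta change presented on the first trial, degC (2.5).
#' @param n_trials trials per block (30).
#' @param n_discard initial trials excluded from the estimate (10).
#' @param ceiling,floor stimulus temperature bounds, degC.
#' @param mode `"detection"` or `"discrimination"`.
#' @param reference_delta fixed smaller change (discrimination only), degC.
#' @param initial_hold,ramp_rate,total_duration stimulus timing, s / degC/s / s.
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(base_temp, direction = c("increase", "decrease"),
                             n_down = 3L, n_up = 1L, step = 0.5,
                             initial_delta = 2.5, n_trials = 30L,
                             n_discard = 10L, ceiling = 50, floor = 35,
                             mode = c("detection", "discrimination"),
                             reference_delta = NULL,
                             initial_hold = 1, ramp_rate = 2,
                             total_duration = 6) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  if (step <= 0) stop_invalid("step must be > 0", "invalid_staircase_config")
  if (n_trials <= n_discard) stop_invalid("n_trials must exceed n_discard", "invalid_staircase_config")
  if (initial_delta < step) stop_invalid("initial_delta must be >= step", "invalid_staircase_config")
  if (n_up != 1L) stop_invalid("only 1-up rules are supported", "invalid_staircase_config")
  if (mode == "discrimination" && is.null(reference_delta)) {
    stop_invalid("discrimination mode needs reference_delta", "invalid_staircase_config")
  }
  structure(
    list(base_temp = base_temp, direction = direction, n_down = as.integer(n_down),
         n_up = as.integer(n_up), step = step, initial_delta = initial_delta,
         n_trials = as.integer(n_trials), n_discard = as.integer(n_discard),
         ceiling = ceiling, floor = floor, mode = mode,
         reference_delta = reference_delta, initial_hold = initial_hold,
         ramp_rate = ramp_rate, total_duration = total_duration),
    class = "staircase_config")
}

# delta bounds implied by stimulus temperature limits and (in discrimination)
# the reference, snapped onto the step grid anchored at the starting delta so
# that presented deltas stay multiples of `step` away from it
delta_bounds <- function(config) {
  start <- staircase_start_delta(config)
  headroom <- if (config$direction == "increase") {
    config$ceiling - config$base_temp
  } else {
    config$base_temp - config$floor
  }
  hi <- start + config$step * floor((headroom - start) / config$step + 1e-9)
  lo_raw <- if (config$mode == "discrimination") config$reference_delta + config$step else config$step
  lo <- start - config$step * floor((start - lo_raw) / config$step + 1e-9)
  if (hi < lo) stop_invalid("no admissible delta between bounds", "invalid_staircase_config")
  c(lo = lo, hi = hi)
}

# first-trial delta: in discrimination the larger change starts initial_delta
# above the fixed reference
staircase_start_delta <- function(config) {
  if (config$mode == "discrimination") {
    config$reference_delta + config$initial_delta
  } else {
    config$initial_delta
  }
}

#' Initialize staircase state
#'
#' @param config a [staircase_config()].
#' @return an object of class `staircase_state` with the first trial's delta.
#' @export
staircase_init <- function(config) {
  b <- delta_bounds(config)
  delta <- staircase_start_delta(config)
  hit_hi <- delta > b["hi"] + 1e-9
  if (hit_hi) delta <- unname(b["hi"])
  structure(
    list(trial_index = 0L,
         current_delta = delta,
         consecutive_correct = 0L,
         bound_violation = hit_hi,
         last_clamped = hit_hi),
    class = "staircase_state")
}

#' Apply the 3-down/1-up update rule
#'
#' After an incorrect answer the change grows by one step and the
#' correct-counter resets; after `n_down` successive correct answers the
#' change shrinks by one step and the counter resets (standard Levitt
#' convention: the counter also resets after every down-step). Step changes
#' take effect on the next trial. The updated delta is clamped to the bounds
#' implied by the temperature limits and (in discrimination) the reference;
#' a clamp at the temperature ceiling/floor sets the block's bound-violation
#' flag, while a clamp at the smallest admissible change does not.
#'
#' @param state a `staircase_state`.
#' @param correct logical: was the response on the just-presented trial
#'   correct?
#' @param config a [staircase_config()].
#' @return the updated `staircase_state`.
#' @export
staircase_update <- function(state, correct, config) {
  if (state$trial_index >= config$n_trials) {
    stop_invalid("staircase block already complete", "staircase_complete_error")
  }
  state$trial_index <- state$trial_index + 1L
  delta <- state$current_delta
  if (!correct) {
    delta <- delta + config$step
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= config$n_down) {
      delta <- delta - config$step
      state$consecutive_correct <- 0L
    }
  }
  b <- attr(config, "delta_bounds")
  if (is.null(b)) b <- delta_bounds(config)
  hit_lo <- delta < b["lo"] - 1e-9
  hit_hi <- delta > b["hi"] + 1e-9
  state$last_clamped <- hit_lo || hit_hi
  if (state$last_clamped) delta <- unname(clamp(delta, b["lo"], b["hi"]))
  # only the high clamp violates a stimulus temperature bound (ceiling for
  # increases, floor for decreases); the low clamp just means the observer
  # outran the smallest admissible change
  if (hit_hi) state$bound_violation <- TRUE
  state$current_delta <- delta
  state
}

#' Run one 30-trial staircase block against a simulated observer
#'
#' Each trial builds the stimulus pair, simulates a 2IFC response, and applies
#' the up-down rule. Uses the current RNG stream; seed with [set.seed()] or
#' [substream_seed()] for reproducibility.
#'
#' @param config a [staircase_config()].
#' @param obs an [observer_spec()].
#' @return a `block_log` data frame with `config$n_trials` rows and columns
#'   `trial`, `interval_of_change`, `delta_c`, `response_interval`, `correct`,
#'   `confidence`, `clamped`.
#' @export
run_block <- function(config, obs) {
  n <- config$n_trials
  state <- staircase_init(config)
  attr(config, "delta_bounds") <- delta_bounds(config) # memoized for the loop
  delta_c <- numeric(n); ioc <- integer(n); resp <- integer(n)
  corr <- logical(n); conf <- integer(n); clamped <- logical(n)
  ref <- if (config$mode == "discrimination") config$reference_delta else NULL
  for (i in seq_len(n)) {
    delta_c[i] <- state$current_delta
    trial <- make_2ifc_trial(state$current_delta, config$direction,
                             config$base_temp, config$initial_hold,
                             config$ramp_rate, config$total_duration,
                             reference_delta = ref)
    r <- simulate_2ifc_trial(trial, obs)
    ioc[i] <- trial$target_interval
    resp[i] <- r$chosen
    corr[i] <- r$correct
    conf[i] <- r$confidence
    state <- staircase_update(state, r$correct, config)
    clamped[i] <- state$last_clamped
  }
  log <- data.frame(trial = seq_len(n), interval_of_change = ioc,
                    delta_c = delta_c, response_interval = resp,
                    correct = corr, confidence = conf, clamped = clamped)
  attr(log, "config") <- config
  attr(log, "bound_violation") <- state$bound_violation
  class(log) <- c("block_log", "data.frame")
  log
}

#' Threshold estimate from a completed block
#'
#' Arithmetic mean of the presented changes on trials
#' `n_discard + 1, ..., n_trials` (the first `n_discard` trials, during which
#' the staircase is still converging, are dropped).
#'
#' @param log a `block_log` from [run_block()].
#' @param config the block's [staircase_config()]; defaults to the config
#'   stored on the log.
#' @return a list of class `threshold_estimate`: `value` (degC), `direction`,
#'   `base_temp`, `n_retained`, `bound_violation`.
#' @export
estimate_threshold <- function(log, config = attr(log, "config")) {
  stopifnot(inherits(log, "block_log") || is.data.frame(log))
  if (nrow(log) < config$n_trials) {
    stop_invalid("incomplete block log", "incomplete_block_error")
  }
  keep <- seq.int(config$n_discard + 1L, config$n_trials)
  structure(
    list(value = mean(log$delta_c[keep]),
         direction = config$direction,
         base_temp = config$base_temp,
         n_retained = length(keep),
         bound_violation = isTRUE(attr(log, "bound_violation"))),
    class = "threshold_estimate")
}

#' Convergence accuracy of a k-down/1-up staircase
#'
#' The asymptotic percent correct at which expected up- and down-steps
#' balance: the probability `p` solving `p^k = 0.5`, i.e. `0.5^(1/k)`. For the
#' 3-down/1-up rule this is 0.5^(1/3) = 0.7937, the 79.4% point of the
#' psychometric function.
#'
#' @param n_down number of successive correct answers per down-step.
#' @return probability in (0.5, 1\].
#' @export
#' @examples
#' convergence_accuracy(3) # 0.7937005
convergence_accuracy <- function(n_down) {
  stopifnot(n_down >= 1)
  0.5^(1 / n_down)
}

#' Theoretical threshold of an observer
#'
#' Inverts the observer's closed-form psychometric function at the staircase's
#' convergence accuracy (0.5^(1/3) for the default 3-down rule) by bisection
#' to 1e-4 degC. This is the value a bias-free staircase of infinite length
#' would converge to; finite 30-trial blocks estimate it with small bias.
#'
#' @param obs an [observer_spec()].
#' @param direction `"increase"` or `"decrease"`.
#' @param base_temp base temperature, degC.
#' @param mode `"detection"` or `"discrimination"`.
#' @param reference_delta fixed smaller change (discrimination only).
#' @param target_accuracy accuracy to invert at; default
#'   `convergence_accuracy(3)`.
#' @param ceiling,floor stimulus temperature bounds, degC.
#' @param tol bisection tolerance, degC.
#' @return the threshold in degC, or `NA_real_` (with a warning of class
#'   `no_solution_warning`) if the psychometric function never reaches the
#'   target accuracy within the temperature bounds (e.g. lapse too high or
#'   the transducer saturating at the floor).
#' @export
theoretical_threshold <- function(obs, direction = c("increase", "decrease"),
                                  base_temp, mode = c("detection", "discrimination"),
                                  reference_delta = NULL,
                                  target_accuracy = convergence_accuracy(3),
                                  ceiling = 50, floor = 35, tol = 1e-4) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  pfun <- if (mode == "detection") {
    function(d) prob_correct_detection(d, direction, base_temp, obs)
  } else {
    function(d) prob_correct_discrimination(reference_delta, d, direction, base_temp, obs)
  }
  lo <- if (mode == "discrimination") reference_delta else 0
  hi <- if (direction == "increase") ceiling - base_temp else base_temp - floor
  if (hi <= lo || pfun(hi) < target_accuracy) {
    warning(warningCondition(
      "target accuracy not attainable within temperature bounds",
      class = "no_solution_warning"))
    return(NA_real_)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pfun(mid) < target_accuracy) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Write / read a block log as CSV
#'
#' Columns: `trial`, `interval_of_change`, `delta_c`, `response_interval`,
#' `correct`, `confidence`, `clamped`.
#'
#' @param log a `block_log`.
#' @param path CSV file path.
#' @export
write_block_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_block_log
#' @export
read_block_log <- function(path) {
  log <- utils::read.csv(path, colClasses = c(
    trial = "integer", interval_of_change = "integer", delta_c = "numeric",
    response_interval = "integer", correct = "logical",
    confidence = "integer", clamped = "logical"))
  class(log) <- c("block_log", "data.frame")
  log
}
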