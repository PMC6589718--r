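#' Simulated observer specification
#'
#' One simulated participant is a signal-detection observer built on a
#' Stevens-type power-law transducer: perceived intensity of skin temperature
#' `T` is `gain * max(0, T - t0)^exponent`, zero at or below the transduction
#' threshold `t0`. With `exponent = 1` the transducer is linear; with
#' `exponent > 1` it is positively accelerating (convex) over the noxious
#' range, which is the mechanism that makes temperature decreases from a given
#' base harder to detect than equal-sized increases.
#'
#' In a 2IFC trial the observer computes, per interval, the absolute perceived
#' change between the stimulus's initial and final plateaus, adds independent
#' zero-mean Gaussian noise with SD `sigma` to each interval's change signal,
#' and chooses the interval with the larger noisy signal. With probability
#' `lapse` the choice is replaced by a coin flip (stimulus-independent lapse).
#' Confidence is the count of `confidence_criteria` exceeded by the absolute
#' difference between the two noisy signals (1 criterion for the binary
#' confident/guessing scale, 3 criteria for a 4-point scale).
#'
#' Intensity ratings on the 0-10 eVAS are a linear read-out of perceived
#' intensity at the probed moment: `clamp(b0 + b1 * perceived + noise, 0, 10)`
#' with rating noise SD `sigma_r`. The observer is memoryless: the rating
#' depends only on the temperature at the probe time, not on the preceding
#' time course.
#'
#' @param gain transducer gain, perceived-intensity units per degC^exponent.
#' @param exponent Stevens exponent, >= 1 (1 = linear).
#' @param t0 transduction threshold, degC; default 42 (bottom of the noxious
#'   range).
#' @param sigma decision noise SD per interval, perceived-intensity units > 0.
#' @param lapse lapse probability in \[0, 0.1\].
#' @param confidence_criteria strictly increasing non-negative cutoffs on the
#'   decision variable; length 1 (binary) or 3 (4-point scale).
#' @param b0,b1 intercept and slope mapping perceived intensity to the eVAS.
#' @param sigma_r rating noise SD, eVAS units >= 0.
#' @return an object of class `observer_spec`.
#' @export
#' @examples
#' obs <- observer_spec(gain = 1, exponent = 2, sigma = 7)
#' transduce(c(42, 45, 47), obs)
observer_spec <- function(gain = 1, exponent = 2, t0 = 42, sigma = 7,
                          lapse = 0.02, confidence_criteria = sigma,
                          b0 = 2, b1 = 0.14, sigma_r = 1) {
  if (gain <= 0) stop_invalid("gain must be > 0", "invalid_observer")
  if (exponent < 1) stop_invalid("exponent must be >= 1", "invalid_observer")
  if (sigma <= 0) stop_invalid("sigma must be > 0", "invalid_observer")
  if (lapse < 0 || lapse > 0.1) stop_invalid("lapse must be in [0, 0.1]", "invalid_observer")
  if (!length(confidence_criteria) %in% c(1L, 3L)) {
    stop_invalid("confidence_criteria must have length 1 or 3", "invalid_observer")
  }
  if (any(confidence_criteria < 0) || is.unsorted(confidence_criteria, strictly = TRUE)) {
    stop_invalid("confidence_criteria must be strictly increasing and >= 0", "invalid_observer")
  }
  if (sigma_r < 0) stop_invalid("sigma_r must be >= 0", "invalid_observer")
  structure(
    list(gain = gain, exponent = exponent, t0 = t0, sigma = sigma,
         lapse = lapse, confidence_criteria = as.numeric(confidence_criteria),
         b0 = b0, b1 = b1, sigma_r = sigma_r),
    class = "observer_spec")
}

#' Power-law transduction of temperature to perceived intensity
#'
#' @param temp temperature(s) in degC, within \[30, 50\].
#' @param obs an [observer_spec()].
#' @return perceived intensity, `gain * max(0, temp - t0)^exponent`.
#' @export
transduce <- function(temp, obs) {
  stopifnot(inherits(obs, "observer_spec"))
  if (any(temp < 30 | temp > 50)) {
    stop_invalid("temperature outside [30, 50] degC", "transduce_domain_error")
  }
  transduce_core(temp, obs)
}

# validation-free kernel for hot loops where the temperature domain is
# already guaranteed by profile construction
transduce_core <- function(temp, obs) {
  obs$gain * pmax(0, temp - obs$t0)^obs$exponent
}

# perceived-change signal of one stimulus: |f(end plateau) - f(start plateau)|
perceived_change <- function(base_temp, delta, obs) {
  abs(transduce(base_temp + delta, obs) - transduce(base_temp, obs))
}

check_final_temp <- function(base_temp, delta) {
  final <- base_temp + delta
  if (any(final < 35 - 1e-9 | final > 50 + 1e-9)) {
    stop_invalid("final temperature outside [35, 50] degC", "invalid_staircase_state")
  }
  invisible(final)
}

#' Closed-form 2IFC percent correct
#'
#' Probability of a correct 2IFC response for a change of unsigned size
#' `delta` in the stated direction against a constant comparison at
#' `base_temp`. With perceived-change signal `df` and independent Gaussian
#' noise per interval the correct-response probability is
#' `lapse/2 + (1 - lapse) * pnorm(df / (sigma * sqrt(2)))`.
#'
#' @param delta unsigned temperature change, degC >= 0.
#' @param direction `"increase"` or `"decrease"`.
#' @param base_temp initial plateau temperature, degC.
#' @param obs an [observer_spec()].
#' @return probability in `[0.5, 1)` (exactly 0.5 at `delta = 0`, lapse-free).
#' @export
#' @examples
#' prob_correct_detection(2.5, "decrease", 45, observer_spec())
prob_correct_detection <- function(delta, direction = c("increase", "decrease"),
                                   base_temp, obs) {
  direction <- match.arg(direction)
  stopifnot(all(delta >= 0))
  sgn <- if (direction == "increase") 1 else -1
  check_final_temp(base_temp, sgn * delta)
  df <- perceived_change(base_temp, sgn * delta, obs)
  obs$lapse / 2 + (1 - obs$lapse) * stats::pnorm(df / (obs$sigma * sqrt(2)))
}

#' Closed-form 2IFC discrimination percent correct
#'
#' Probability of correctly reporting which interval contained the larger of
#' two same-direction changes from a common base. The decision variable is the
#' difference of the two perceived-change signals.
#'
#' @param delta_small,delta_large unsigned changes, degC;
#'   `delta_large >= delta_small`.
#' @inheritParams prob_correct_detection
#' @return probability in `[0.5, 1)`.
#' @export
prob_correct_discrimination <- function(delta_small, delta_large,
                                        direction = c("increase", "decrease"),
                                        base_temp, obs) {
  direction <- match.arg(direction)
  if (any(delta_large < delta_small)) {
    stop_invalid("delta_large must be >= delta_small", "invalid_staircase_state")
  }
  sgn <- if (direction == "increase") 1 else -1
  check_final_temp(base_temp, sgn * delta_small)
  check_final_temp(base_temp, sgn * delta_large)
  df <- perceived_change(base_temp, sgn * delta_large, obs) -
    perceived_change(base_temp, sgn * delta_small, obs)
  obs$lapse / 2 + (1 - obs$lapse) * stats::pnorm(df / (obs$sigma * sqrt(2)))
}

#' Simulate one 2IFC trial
#'
#' The trial carries two stimulus profiles; exactly one contains the target
#' (the change, in detection; the larger change, in discrimination). The
#' target interval must have been assigned with probability 0.5 by the caller
#' (see [make_2ifc_trial()]). One noisy change signal is drawn per interval;
#' the observer chooses the interval with the larger signal, lapsing to a
#' uniform random choice with probability `lapse`.
#'
#' @param trial a list as returned by [make_2ifc_trial()]: profiles for the
#'   two intervals plus `target_interval` (1 or 2).
#' @param obs an [observer_spec()].
#' @return a list: `chosen` (1 or 2), `correct` (logical), `confidence`
#'   (integer level: 1 = lowest, scale length = highest), `lapsed` (logical).
#' @export
simulate_2ifc_trial <- function(trial, obs) {
  p1 <- trial$profiles[[1L]]; p2 <- trial$profiles[[2L]]
  ends <- c(p1$temp_c[length(p1$temp_c)], p2$temp_c[length(p2$temp_c)])
  starts <- c(p1$temp_c[1L], p2$temp_c[1L])
  df <- abs(transduce_core(ends, obs) - transduce_core(starts, obs))
  sig <- df + stats::rnorm(2L, 0, obs$sigma)
  chosen <- which.max(sig)
  lapsed <- stats::runif(1) < obs$lapse
  if (lapsed) chosen <- sample(1:2, 1L)
  conf <- sum(abs(sig[1L] - sig[2L]) > obs$confidence_criteria) + 1L
  list(chosen = chosen,
       correct = chosen == trial$target_interval,
       confidence = conf,
       lapsed = lapsed)
}

#' Construct a 2IFC trial from a staircase state
#'
#' Builds the pair of stimulus profiles for one trial and assigns the target
#' to interval 1 or 2 with equal probability (drawn from the current RNG
#' stream).
#'
#' @param delta unsigned change of the target stimulus, degC.
#' @param direction `"increase"` or `"decrease"`.
#' @param base_temp base (initial plateau) temperature, degC.
#' @param initial_hold,ramp_rate,total_duration stimulus timing parameters,
#'   passed to [profile_spec()].
#' @param reference_delta for discrimination trials, the fixed smaller change;
#'   `NULL` (detection) makes the comparison a constant stimulus.
#' @return a list with elements `profiles` (list of 2 `temperature_profile`s)
#'   and `target_interval`.
#' @export
make_2ifc_trial <- function(delta, direction, base_temp, initial_hold,
                            ramp_rate, total_duration, reference_delta = NULL) {
  sgn <- if (direction == "increase") 1 else -1
  target <- build_profile(profile_spec(base_temp, initial_hold, sgn * delta,
                                       ramp_rate, total_duration))
  ref_delta <- if (is.null(reference_delta)) 0 else sgn * reference_delta
  comparison <- build_profile(profile_spec(base_temp, initial_hold, ref_delta,
                                           ramp_rate, total_duration))
  target_interval <- if (stats::runif(1) < 0.5) 1L else 2L
  profiles <- if (target_interval == 1L) list(target, comparison) else list(comparison, target)
  list(profiles = profiles, target_interval = target_interval)
}

#' Simulate an eVAS intensity rating
#'
#' Rating of perceived intensity at `probe_time` (by design, 1 s before
#' stimulus end, after the final temperature has been reached). Memoryless:
#' depends only on the temperature at the probe.
#'
#' @param profile a `temperature_profile`.
#' @param obs an [observer_spec()].
#' @param probe_time probe time in s; default 1 s before stimulus end.
#' @return rating on the 0-10 eVAS.
#' @export
simulate_rating <- function(profile, obs, probe_time = profile_duration(profile) - 1) {
  temp <- sample_profile(profile, probe_time)
  raw <- obs$b0 + obs$b1 * transduce(temp, obs) + stats::rnorm(1L, 0, obs$sigma_r)
  clamp(raw, 0, 10)
}

#' Serialize observers to / from JSON
#'
#' A single `observer_spec` round-trips through `observer_to_json()` /
#' `observer_from_json()`; a cohort (list of specs) through
#' `cohort_to_json()` / `cohort_from_json()`, written as a JSON array.
#'
#' @param obs an [observer_spec()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
observer_to_json <- function(obs, path = NULL) {
  stopifnot(inherits(obs, "observer_spec"))
  txt <- jsonlite::toJSON(unclass(obs), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname observer_to_json
#' @param x JSON string or file path.
#' @export
observer_from_json <- function(x) {
  o <- jsonlite::fromJSON(x)
  observer_spec(gain = o$gain, exponent = o$exponent, t0 = o$t0,
                sigma = o$sigma, lapse = o$lapse,
                confidence_criteria = o$confidence_criteria,
                b0 = o$b0, b1 = o$b1, sigma_r = o$sigma_r)
}

#' @rdname observer_to_json
#' @param cohort a list of `observer_spec`s.
#' @export
cohort_to_json <- function(cohort, path = NULL) {
  stopifnot(all(vapply(cohort, inherits, logical(1), "observer_spec")))
  txt <- jsonlite::toJSON(lapply(cohort, unclass), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname observer_to_json
#' @export
cohort_from_json <- function(x) {
  lst <- jsonlite::fromJSON(x, simplifyDataFrame = FALSE)
  lapply(lst, function(o) {
    observer_spec(gain = o$gain, exponent = o$exponent, t0 = o$t0,
                  sigma = o$sigma, lapse = o$lapse,
                  confidence_criteria = unlist(o$confidence_criteria),
                  b0 = o$b0, b1 = o$b1, sigma_r = o$sigma_r)
  })
}
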