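#' Trapezoidal temperature stimulus profiles
#'
#' All stimuli in the simulated tasks are piecewise-linear temperature time
#' courses: an initial plateau, an optional linear ramp at a fixed rate, and a
#' final plateau that lasts until stimulus end. `profile_spec()` captures the
#' five numbers that define such a stimulus; `build_profile()` turns a spec
#' into an explicit breakpoint representation.
#'
#' Temperatures are bounded to the interval \[35, 50\] degC everywhere: 50 degC is
#' the safety ceiling of the stimulators and 35 degC the floor below which no
#' stimulus is allowed to fall.
#'
#' @param start_temp initial plateau temperature, degC.
#' @param initial_hold duration of the initial plateau, s.
#' @param delta signed temperature change, degC (0 for a constant stimulus).
#' @param ramp_rate absolute rate of temperature change, degC/s (> 0).
#' @param total_duration total stimulus duration, s.
#' @return an object of class `profile_spec`.
#' @export
#' @examples
#' profile_spec(45, 1, -2.5, 2, 6) # 45 degC for 1 s, down to 42.5 degC at 2 degC/s
profile_spec <- function(start_temp, initial_hold, delta, ramp_rate, total_duration) {
  if (!(is.numeric(start_temp) && is.numeric(initial_hold) && is.numeric(delta) &&
        is.numeric(ramp_rate) && is.numeric(total_duration))) {
    stop_invalid("all profile parameters must be numeric", "invalid_profile_spec")
  }
  if (ramp_rate <= 0) {
    stop_invalid("ramp_rate must be > 0", "invalid_profile_spec")
  }
  if (initial_hold < 0 || total_duration <= 0) {
    stop_invalid("durations must be non-negative (total > 0)", "invalid_profile_spec")
  }
  lo <- 35; hi <- 50
  if (start_temp < lo || start_temp > hi ||
      start_temp + delta < lo || start_temp + delta > hi) {
    stop_invalid(
      sprintf("temperatures must stay within [%g, %g] degC (start %g, end %g)",
              lo, hi, start_temp, start_temp + delta),
      "invalid_profile_spec")
  }
  if (initial_hold + abs(delta) / ramp_rate > total_duration + 1e-12) {
    stop_invalid("ramp does not fit inside total_duration", "invalid_profile_spec")
  }
  structure(
    list(start_temp = start_temp, initial_hold = initial_hold, delta = delta,
         ramp_rate = ramp_rate, total_duration = total_duration),
    class = "profile_spec")
}

#' Build the breakpoint representation of a stimulus
#'
#' For a changing stimulus (`delta != 0`) the profile has four breakpoints:
#' stimulus onset, ramp start, ramp end, and stimulus end; the final plateau
#' temperature is `start_temp + delta`. A constant stimulus has two
#' breakpoints. Times are continuous; no sampling grid is imposed.
#'
#' @param spec a [profile_spec()].
#' @return a `temperature_profile`: a data frame with columns `time_s`,
#'   `temp_c`, one row per breakpoint.
#' @export
#' @examples
#' build_profile(profile_spec(45, 1, -2.5, 2, 6))
build_profile <- function(spec) {
  if (!inherits(spec, "profile_spec")) {
    stop_invalid("spec must be a profile_spec", "invalid_profile_spec")
  }
  if (spec$delta == 0) {
    tt <- c(0, spec$total_duration)
    temps <- c(spec$start_temp, spec$start_temp)
  } else {
    ramp_end <- spec$initial_hold + abs(spec$delta) / spec$ramp_rate
    tt <- c(0, spec$initial_hold, ramp_end, spec$total_duration)
    temps <- c(spec$start_temp, spec$start_temp,
               spec$start_temp + spec$delta, spec$start_temp + spec$delta)
    # degenerate holds (hold = 0 or ramp ending exactly at stimulus end)
    # collapse duplicated times so breakpoint times stay strictly increasing
    keep <- !duplicated(tt)
    tt <- tt[keep]; temps <- temps[keep]
  }
  structure(list(time_s = tt, temp_c = temps),
            row.names = seq_along(tt),
            class = c("temperature_profile", "data.frame"))
}

#' Evaluate a profile at a time point
#'
#' Linear interpolation between breakpoints. `t` may be a vector.
#'
#' @param profile a `temperature_profile`.
#' @param t time(s) in seconds, each within `[0, stimulus end]`.
#' @return temperature(s) in degC.
#' @export
sample_profile <- function(profile, t) {
  stopifnot(inherits(profile, "temperature_profile"))
  if (any(t < 0 | t > max(profile$time_s) + 1e-12)) {
    stop_invalid("t outside profile domain", "profile_domain_error")
  }
  stats::approx(profile$time_s, profile$temp_c, xout = t, rule = 1)$y
}

# plateau temperatures of a profile (used by the 2IFC decision model)
profile_start_temp <- function(profile) profile$temp_c[1L]
profile_end_temp <- function(profile) profile$temp_c[nrow(profile)]
profile_duration <- function(profile) profile$time_s[nrow(profile)]

#' Export / import profiles as JSON
#'
#' Serializes the breakpoint list as `{"breakpoints": [[t, temp], ...]}`.
#'
#' @param profile a `temperature_profile`.
#' @param path file path; if `NULL`, `profile_to_json` returns the JSON string.
#' @return `profile_to_json`: the path (or JSON string); `profile_from_json`:
#'   a `temperature_profile`.
#' @export
profile_to_json <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "temperature_profile"))
  obj <- list(breakpoints = unname(as.matrix(profile)))
  txt <- jsonlite::toJSON(obj, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname profile_to_json
#' @param x JSON string or path to a JSON file.
#' @export
profile_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  bp <- obj$breakpoints
  stopifnot(is.matrix(bp), ncol(bp) == 2)
  structure(data.frame(time_s = bp[, 1], temp_c = bp[, 2]),
            class = c("temperature_profile", "data.frame"))
}

#' Sample a profile onto a regular grid for export or plotting
#'
#' @param profile a `temperature_profile`.
#' @param rate_hz sampling rate; 100 Hz default.
#' @return data frame with columns `time_s`, `temp_c`.
#' @export
discretize_profile <- function(profile, rate_hz = 100) {
  tt <- seq(0, profile_duration(profile), by = 1 / rate_hz)
  data.frame(time_s = tt, temp_c = sample_profile(profile, tt))
}
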