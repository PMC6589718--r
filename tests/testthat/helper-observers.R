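# shared observer fixtures, built in code

# linear transducer, lapse-free: increase/decrease symmetric from any base
# with headroom above t0
linear_obs <- function(sigma = 1.75, lapse = 0, t0 = 42, gain = 1) {
  observer_spec(gain = gain, exponent = 1, t0 = t0, sigma = sigma,
                lapse = lapse)
}

# convex (positively accelerating) transducer, the asymmetry mechanism
convex_obs <- function(sigma = 6, lapse = 0, exponent = 2, gain = 1) {
  observer_spec(gain = gain, exponent = exponent, t0 = 42, sigma = sigma,
                lapse = lapse)
}

# near-noiseless observer: answers follow the signal almost deterministically
sharp_obs <- function() observer_spec(gain = 1, exponent = 1, t0 = 42,
                                      sigma = 1e-9, lapse = 0)

# near-guessing observer: decision noise swamps any signal
guessing_obs <- function() observer_spec(gain = 1, exponent = 1, t0 = 42,
                                         sigma = 1e9, lapse = 0)

# empirical accuracy of the trial simulator on a fixed detection task
sim_accuracy <- function(n, delta, direction, base_temp, obs,
                         initial_hold = 1, ramp_rate = 2, total_duration = 6) {
  correct <- logical(n)
  for (i in seq_len(n)) {
    trial <- make_2ifc_trial(delta, direction, base_temp, initial_hold,
                             ramp_rate, total_duration)
    correct[i] <- simulate_2ifc_trial(trial, obs)$correct
  }
  mean(correct)
}
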