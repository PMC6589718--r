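#' Experiment design presets
#'
#' Configurations for the four simulated designs:
#'
#' * `"exp1"`: 2 degC/s ramps, 6-s stimuli with a 1-s initial hold, increases
#'   and decreases both from 45 degC, binary confidence, detection followed by
#'   discrimination blocks (the detection threshold becomes the fixed
#'   reference of the corresponding discrimination block).
#' * `"exp2"`: detection only, 4 degC/s ramps, 6-s stimuli with a 3-s hold.
#' * `"exp3"`: detection only, 4 degC/s ramps, 10-s stimuli with a 5-s hold;
#'   decreases start from 47 degC while increases still start from 45 degC
#'   (overlapping temperature ranges), 4-point confidence.
#' * `"rating"`: the intensity-rating task of the second design: single
#'   stimuli 46-46, 47-47, 46-47 and 47-46 degC (3-s hold, 4 degC/s ramp,
#'   2.75-s final plateau), each presented 14 times in randomized order, 56
#'   trials in 2 blocks of 28, rated on the 0-10 eVAS at a probe 1 s before
#'   stimulus end.
#'
#' @param preset one of `"exp1"`, `"exp2"`, `"exp3"`, `"rating"`.
#' @param modalities stimulus-modality labels to run (a label only; the
#'   simulated observer is modality-blind). Default `"radiant"`.
#' @param initial_delta starting change for every staircase, degC.
#' @param tasks optional subset of the preset's task list (e.g. run only the
#'   detection blocks of the first design).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("exp1", "exp2", "exp3", "rating"),
                              modalities = "radiant", initial_delta = 2.5,
                              tasks = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    exp1 = list(ramp_rate = 2, stimulus_duration = 6, initial_hold = 1,
                base_increase = 45, base_decrease = 45,
                confidence_scale = "binary",
                tasks = c("detection", "discrimination")),
    exp2 = list(ramp_rate = 4, stimulus_duration = 6, initial_hold = 3,
                base_increase = 45, base_decrease = 45,
                confidence_scale = "binary", tasks = "detection"),
    exp3 = list(ramp_rate = 4, stimulus_duration = 10, initial_hold = 5,
                base_increase = 45, base_decrease = 47,
                confidence_scale = "four_point", tasks = "detection"),
    rating = list(ramp_rate = 4, stimulus_duration = 6, initial_hold = 3,
                  base_increase = NA_real_, base_decrease = NA_real_,
                  confidence_scale = "binary", tasks = "rating"))
  if (!is.null(tasks)) {
    if (!all(tasks %in% base$tasks)) {
      stop_invalid("tasks must be a subset of the preset's task list", "invalid_preset")
    }
    base$tasks <- tasks
  }
  structure(
    c(list(experiment_id = preset, modalities = modalities,
           initial_delta = initial_delta,
           n_trials = 30L, n_discard = 10L, step = 0.5, n_down = 3L,
           ceiling = 50, floor = 35,
           counterbalance_scheme = "parity: even participant index runs increase blocks first"),
      base),
    class = "experiment_config")
}

# fixed RNG substream code per block identity, so a block's stream never
# depends on counterbalanced position or on other participants
block_code <- function(task, direction, modality_index) {
  (modality_index - 1L) * 10L +
    switch(task, detection = 0L, discrimination = 4L) +
    switch(direction, increase = 1L, decrease = 2L)
}

# adapt an observer's confidence criteria to the design's confidence scale
with_confidence_scale <- function(obs, scale) {
  k <- length(obs$confidence_criteria)
  if (scale == "binary" && k != 1L) {
    obs$confidence_criteria <- obs$confidence_criteria[2L]
  } else if (scale == "four_point" && k != 3L) {
    obs$confidence_criteria <- obs$confidence_criteria * c(0.5, 1, 1.5)
  }
  obs
}

staircase_config_for <- function(config, direction, mode, reference_delta = NULL) {
  staircase_config(
    base_temp = if (direction == "increase") config$base_increase else config$base_decrease,
    direction = direction, n_down = config$n_down, step = config$step,
    initial_delta = config$initial_delta, n_trials = config$n_trials,
    n_discard = config$n_discard, ceiling = config$ceiling,
    floor = config$floor, mode = mode, reference_delta = reference_delta,
    initial_hold = config$initial_hold, ramp_rate = config$ramp_rate,
    total_duration = config$stimulus_duration)
}

#' Run a threshold experiment on a synthetic cohort
#'
#' For each participant and modality, detection blocks are run first (their
#' threshold estimates become the fixed references of the discrimination
#' blocks, where the design includes them). Block order alternates with
#' participant parity (even index: increase first) as counterbalancing
#' metadata. Every block draws from its own RNG substream derived from
#' `seed`, the participant index and a fixed per-block code, so results for
#' one participant are unaffected by the presence of others.
#'
#' A block whose staircase hit the stimulus temperature bounds (or whose
#' discrimination staircase is infeasible because the reference leaves no
#' admissible larger change) is flagged `excluded`, mirroring post-hoc
#' exclusion of participants whose thresholds could not be estimated.
#'
#' @param config an [experiment_config()] (not the `"rating"` preset).
#' @param cohort list of [observer_spec()]s.
#' @param seed integer base seed.
#' @param keep_logs keep per-block trial logs in the result (default TRUE).
#' @return a list of class `cohort_result`: `results` (data frame with columns
#'   `participant_id`, `task`, `direction`, `modality`, `block_order`,
#'   `threshold_c`, `excluded`), `logs` (named list of `block_log`s), and
#'   `manifest` (config, seed, package version).
#' @export
run_experiment <- function(config, cohort, seed = 1L, keep_logs = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$experiment_id == "rating") {
    stop_invalid("use run_rating_task() for the rating preset", "invalid_preset")
  }
  if (length(cohort) == 0L) stop_invalid("cohort is empty", "empty_cohort")
  rows <- list(); logs <- list()
  for (i in seq_along(cohort)) {
    obs <- with_confidence_scale(cohort[[i]], config$confidence_scale)
    dir_order <- if (i %% 2L == 0L) c("increase", "decrease") else c("decrease", "increase")
    for (m in seq_along(config$modalities)) {
      modality <- config$modalities[m]
      det <- list()
      for (task in config$tasks) {
        for (pos in seq_along(dir_order)) {
          direction <- dir_order[pos]
          ref <- if (task == "discrimination") det[[direction]]$value else NULL
          set.seed(substream_seed(seed, i, block_code(task, direction, m)))
          res <- tryCatch({
            sc <- staircase_config_for(config, direction, mode = task,
                                       reference_delta = ref)
            log <- run_block(sc, obs)
            est <- estimate_threshold(log)
            list(est = est, log = log)
          }, noxithresh_error = function(e) NULL)
          if (task == "detection" && !is.null(res)) det[[direction]] <- res$est
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = i, task = task, direction = direction,
            modality = modality,
            block_order = paste(dir_order, collapse = "-"),
            threshold_c = if (is.null(res)) NA_real_ else res$est$value,
            excluded = is.null(res) || res$est$bound_violation)
          if (keep_logs && !is.null(res)) {
            logs[[sprintf("p%02d_%s_%s_%s", i, modality, task, direction)]] <- res$log
          }
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(
    list(results = results, logs = logs,
         manifest = list(config = unclass(config), seed = seed,
                         package = "noxithresh",
                         version = as.character(utils::packageVersion("noxithresh")))),
    class = "cohort_result")
}

# the four rating-task stimulus types: start temp and signed change
rating_stim_types <- function() {
  data.frame(
    stim_type = c("46-46", "47-47", "46-47", "47-46"),
    start_temp = c(46, 47, 46, 47),
    delta = c(0, 0, 1, -1),
    profile_kind = c("constant", "constant", "variable", "variable"),
    final_temp = c(46, 47, 47, 46))
}

#' Run the intensity-rating task on a synthetic cohort
#'
#' 56 trials per participant: the four stimulus types each presented 14 times
#' in randomized order, as 2 blocks of 28 trials (7 of each type per block,
#' shuffled within block). Ratings are produced by [simulate_rating()] at the
#' probe 1 s before stimulus end, after the final temperature is reached.
#'
#' @param config the `"rating"` [experiment_config()].
#' @param cohort list of [observer_spec()]s.
#' @param seed integer base seed.
#' @return data frame with columns `participant_id`, `block`, `trial`,
#'   `stim_type`, `profile_kind`, `final_temp`, `rating`.
#' @export
run_rating_task <- function(config, cohort, seed = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$experiment_id != "rating") {
    stop_invalid("config must be the 'rating' preset", "invalid_preset")
  }
  types <- rating_stim_types()
  profiles <- lapply(seq_len(nrow(types)), function(k) {
    build_profile(profile_spec(types$start_temp[k], config$initial_hold,
                               types$delta[k], config$ramp_rate,
                               config$stimulus_duration))
  })
  out <- list()
  for (i in seq_along(cohort)) {
    obs <- cohort[[i]]
    set.seed(substream_seed(seed, i, 100L))
    for (blk in 1:2) {
      order_k <- sample(rep(seq_len(nrow(types)), 7L))
      ratings <- vapply(order_k, function(k) {
        simulate_rating(profiles[[k]], obs)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        participant_id = i, block = blk, trial = seq_along(order_k),
        stim_type = types$stim_type[order_k],
        profile_kind = types$profile_kind[order_k],
        final_temp = types$final_temp[order_k],
        rating = ratings)
    }
  }
  do.call(rbind, out)
}

#' Pool per-trial logs of a cohort result into one data frame
#'
#' Adds `participant_id`, `modality`, `task` and `direction` columns parsed
#' from the block names, for use with [confidence_summary()].
#'
#' @param cohort_result a `cohort_result` from [run_experiment()].
#' @return data frame of pooled trial rows.
#' @export
pool_block_logs <- function(cohort_result) {
  stopifnot(inherits(cohort_result, "cohort_result"))
  nm <- names(cohort_result$logs)
  pooled <- lapply(seq_along(nm), function(j) {
    parts <- strsplit(nm[j], "_", fixed = TRUE)[[1]]
    df <- as.data.frame(cohort_result$logs[[j]])
    df$participant_id <- as.integer(sub("^p", "", parts[1]))
    df$modality <- parts[2]; df$task <- parts[3]; df$direction <- parts[4]
    df
  })
  do.call(rbind, pooled)
}
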