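#' Hyperparameters of a synthetic participant population
#'
#' Inter-individual variability is modelled with log-normal distributions for
#' the transducer gain, exponent and decision noise (all strictly positive,
#' right-skewed quantities), uniform ranges for lapse rate and the eVAS
#' mapping, and a fixed transduction threshold `t0`. The defaults are
#' calibrated so that a cohort run through the first experiment's design
#' yields detection thresholds in the 1-4 degC band typical of noxious-heat
#' 2IFC work, with decrease thresholds from 45 degC roughly 1.5-2 times the
#' increase thresholds (the convex-transducer asymmetry), and eVAS ratings
#' around 4-5.5 for 46-47 degC stimuli.
#'
#' @param n_participants cohort size; default 16.
#' @param gamma_median,gamma_logsd log-normal median and log-SD of the Stevens
#'   exponent; default median 2 (positively accelerating). `gamma_logsd = 0`
#'   makes every exponent equal the median; draws are truncated below at 1.
#' @param gain_median,gain_logsd log-normal parameters of the transducer gain.
#' @param sigma_median,sigma_logsd log-normal parameters of the decision noise
#'   SD (perceived-intensity units).
#' @param t0 transduction threshold, degC (fixed across the cohort).
#' @param lapse_range uniform range of the lapse rate.
#' @param b0_range,b1_range uniform ranges of the eVAS mapping intercept and
#'   slope.
#' @param sigma_r_range uniform range of the rating noise SD.
#' @param conf_range confidence criterion as a uniform multiple of each
#'   observer's own `sigma`.
#' @return an object of class `cohort_hyperparams`.
#' @export
cohort_hyperparams <- function(n_participants = 16L,
                               gamma_median = 2, gamma_logsd = 0.12,
                               gain_median = 1, gain_logsd = 0.08,
                               sigma_median = 6, sigma_logsd = 0.12,
                               t0 = 42,
                               lapse_range = c(0, 0.04),
                               b0_range = c(1.5, 2.5),
                               b1_range = c(0.10, 0.17),
                               sigma_r_range = c(0.6, 1.2),
                               conf_range = c(0.7, 1.3)) {
  stopifnot(n_participants >= 1, gamma_median >= 1, gamma_logsd >= 0,
            gain_median > 0, sigma_median > 0)
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!rng_ok(lapse_range) || lapse_range[1] < 0 || lapse_range[2] > 0.1) {
    stop_invalid("lapse_range must lie within [0, 0.1]", "invalid_hyperparams")
  }
  if (!all(vapply(list(b0_range, b1_range, sigma_r_range, conf_range),
                  rng_ok, logical(1)))) {
    stop_invalid("parameter ranges must be length-2 and ordered", "invalid_hyperparams")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         gamma_median = gamma_median, gamma_logsd = gamma_logsd,
         gain_median = gain_median, gain_logsd = gain_logsd,
         sigma_median = sigma_median, sigma_logsd = sigma_logsd,
         t0 = t0, lapse_range = lapse_range, b0_range = b0_range,
         b1_range = b1_range, sigma_r_range = sigma_r_range,
         conf_range = conf_range),
    class = "cohort_hyperparams")
}

#' Generate a synthetic cohort of observers
#'
#' Each participant's parameters are drawn from their own RNG substream
#' (`substream_seed(seed, i)`), so participant `i`'s spec is identical
#' whatever the cohort size: enlarging a cohort never perturbs existing
#' members.
#'
#' @param hp a [cohort_hyperparams()].
#' @param seed integer base seed.
#' @return list of [observer_spec()]s of length `hp$n_participants`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_hyperparams(n_participants = 4), seed = 7)
generate_cohort <- function(hp, seed = 1L) {
  stopifnot(inherits(hp, "cohort_hyperparams"))
  lapply(seq_len(hp$n_participants), function(i) {
    set.seed(substream_seed(seed, i))
    gamma <- max(1, hp$gamma_median * exp(stats::rnorm(1, 0, hp$gamma_logsd)))
    gain <- hp$gain_median * exp(stats::rnorm(1, 0, hp$gain_logsd))
    sigma <- hp$sigma_median * exp(stats::rnorm(1, 0, hp$sigma_logsd))
    observer_spec(
      gain = gain, exponent = gamma, t0 = hp$t0, sigma = sigma,
      lapse = stats::runif(1, hp$lapse_range[1], hp$lapse_range[2]),
      confidence_criteria = sigma * stats::runif(1, hp$conf_range[1], hp$conf_range[2]),
      b0 = stats::runif(1, hp$b0_range[1], hp$b0_range[2]),
      b1 = stats::runif(1, hp$b1_range[1], hp$b1_range[2]),
      sigma_r = stats::runif(1, hp$sigma_r_range[1], hp$sigma_r_range[2]))
  })
}

fixture_presets <- c("exp1_small", "exp2_small", "exp3_small",
                     "rating_small", "null_linear")

#' Hyperparameters of the linear (null) cohort
#'
#' A strictly linear cohort (`exponent = 1` for everyone) in which increases
#' and decreases from a common base are, by symmetry of the transducer,
#' equally detectable: the ground truth under which any direction effect is a
#' false positive. Decision noise is rescaled (`sigma_median = 1.75`) because
#' a linear transducer maps degC to perceived units one-to-one per unit gain;
#' the default gives theoretical thresholds near 2 degC, the middle of the
#' 1-4 degC band, for both directions.
#'
#' @param n_participants cohort size.
#' @param sigma_median log-normal median of the decision noise.
#' @param ... further arguments passed to [cohort_hyperparams()].
#' @return a [cohort_hyperparams()] object.
#' @export
null_linear_hyperparams <- function(n_participants = 16L, sigma_median = 1.75, ...) {
  cohort_hyperparams(n_participants = n_participants, gamma_median = 1,
                     gamma_logsd = 0, sigma_median = sigma_median,
                     b1_range = c(0.5, 0.9), ...)
}

#' Generate a miniature end-to-end fixture dataset
#'
#' Builds a small cohort (6 participants), runs the requested design on it,
#' and writes plain-text artifacts to `out_dir`: `cohort.json` (observer
#' specs), `results.csv` (thresholds or ratings), per-block trial logs
#' `log_*.csv` (threshold designs), and `manifest.json` (preset, seed,
#' version). Regenerating with the same preset and seed reproduces the files
#' byte-identically. The `null_linear` preset uses a strictly linear cohort
#' (exponent 1) run through the first design, for type-I-error checks
#' downstream.
#'
#' @param preset one of `"exp1_small"`, `"exp2_small"`, `"exp3_small"`,
#'   `"rating_small"`, `"null_linear"`.
#' @param seed integer base seed.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of paths written.
#' @export
make_fixture_dataset <- function(preset, seed = 1L, out_dir) {
  if (!preset %in% fixture_presets) {
    stop_invalid(sprintf("unknown preset '%s'", preset), "unknown_preset")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hp <- if (preset == "null_linear") {
    null_linear_hyperparams(n_participants = 6L)
  } else {
    cohort_hyperparams(n_participants = 6L)
  }
  cohort <- generate_cohort(hp, seed = seed)
  paths <- character(0)
  p_cohort <- file.path(out_dir, "cohort.json")
  cohort_to_json(cohort, p_cohort); paths <- c(paths, p_cohort)

  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  if (preset == "rating_small") {
    ratings <- run_rating_task(experiment_config("rating"), cohort, seed = seed)
    ratings$rating <- num(ratings$rating)
    p <- file.path(out_dir, "results.csv")
    utils::write.csv(ratings, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  } else {
    design <- switch(preset, exp1_small = "exp1", exp2_small = "exp2",
                     exp3_small = "exp3", null_linear = "exp1")
    res <- run_experiment(experiment_config(design), cohort, seed = seed)
    tab <- res$results
    tab$threshold_c <- num(tab$threshold_c)
    p <- file.path(out_dir, "results.csv")
    utils::write.csv(tab, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
    for (nm in names(res$logs)) {
      lp <- file.path(out_dir, paste0("log_", nm, ".csv"))
      write_block_log(res$logs[[nm]], lp)
      paths <- c(paths, lp)
    }
  }
  p_man <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(
    list(preset = preset, seed = seed, package = "noxithresh",
         version = as.character(utils::packageVersion("noxithresh"))),
    auto_unbox = TRUE), p_man)
  paths <- c(paths, p_man)
  invisible(paths)
}
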