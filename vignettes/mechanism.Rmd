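---
title: "Why decreases in noxious heat are harder to detect: model, staircase and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why decreases in noxious heat are harder to detect: model, staircase and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noxithresh)
```

## The observer model

Each simulated participant transduces skin temperature $T$ (°C) into
perceived intensity with a Stevens-type power law truncated at a
transduction threshold $T_0$:

$$f(T) = a \cdot \max(0,\, T - T_0)^{\gamma}, \qquad \gamma \ge 1 .$$

$T_0$ defaults to 42 °C, the conventional lower edge of the noxious range.
With $\gamma = 1$ the transducer is linear; with $\gamma > 1$ it is convex
("positively accelerating"). Convexity is the single mechanism this package
exists to exercise: from a 45 °C base, the temperatures traversed by a
*decrease* lie on the shallow part of $f$, so an equal-sized physical change
produces a smaller perceived change than an increase does. Decreases from
47 °C and increases from 45 °C traverse overlapping portions of $f$ and
produce comparable perceived changes.

In a two-interval forced-choice (2IFC) trial the observer computes, per
interval, the absolute perceived change between the stimulus's initial and
final plateaus, adds independent zero-mean Gaussian noise ($\sigma$ per
interval), and picks the interval with the larger noisy signal; with
probability $\lambda$ (a lapse) the choice is replaced by a coin flip. This
admits the closed form

$$P(\text{correct}) \;=\; \tfrac{\lambda}{2} + (1-\lambda)\,
\Phi\!\left(\frac{\Delta f}{\sigma\sqrt{2}}\right),$$

implemented in `prob_correct_detection()` / `prob_correct_discrimination()`
and cross-validated in the test suite against Monte-Carlo simulation of
`simulate_2ifc_trial()` (the two routes share no code beyond the
transducer).

**Assumptions worth stating.** Perceived change is read from the two
plateaus, not integrated over the ramp; the observer is memoryless across
the inter-stimulus gap and across trials (no adaptation or sensitization);
lapses are stimulus-independent; confidence is a static partition of the
decision variable by per-observer criteria (1 cutoff for the binary
confident/guessing report, 3 for the 4-point scale). Whether confidence
should carry direction information beyond the decision variable is left
unmodelled, deliberately. The memorylessness assumption is what turns the
rating-task null result (no effect of the preceding profile on ratings of
the same final temperature) into a derivable property rather than an
empirical accident.

## The staircase

`run_block()` implements the transformed up-down rule: the tracked change
grows one step after every error and shrinks one step after three successive
correct responses (3-down/1-up), 0.5 °C steps, 2.5 °C on the first trial,
30 trials; the threshold estimate is the mean presented change over trials
11–30. The rule converges on the accuracy $p^\*$ solving $p^{\*3} = 0.5$,
i.e. $0.5^{1/3} \approx 79.4\%$ (`convergence_accuracy(3)`).

Where the rule is under-specified we adopt the standard Levitt conventions
and record them here: the correct-response counter resets after every
down-step *and* after every error; step changes take effect on the next
trial; there is no step-size tapering. In discrimination blocks the smaller
change is pinned to the participant's previously measured detection
threshold, the adapted larger change starts 2.5 °C above it and is bounded
below by reference + step.

**Bounds.** The changing stimulus may never leave [35, 50] °C. Rather than
aborting, the staircase clamps the tracked change and keeps running;
a clamp at the ceiling/floor marks the block `bound_violation`, which
propagates to an `excluded` flag in experiment results — mirroring post-hoc
exclusion of participants whose thresholds could not be estimated. A clamp
at the *smallest* admissible change (0.5 °C) is not an exclusion: it simply
means the observer outran the staircase resolution. Bounds are snapped onto
the 0.5 °C grid anchored at the starting delta so that presented deltas are
always grid values.

**Known bias, measured rather than hidden.** A 30-trial block starting at
2.5 °C does not estimate the 79.4 % point without bias, and the test suite
quantifies this. Two regimes matter:

* *Saturating decreases.* With unit gain and $T_0 = 42$, the perceived
  decrease from 45 °C can never exceed $f(45)$, so the psychometric function
  for decreases flattens toward an asymptote. Above threshold the accuracy
  gain is small, down-pressure is weak, and the staircase sits too high:
  convex observers with decrease thresholds of 1.5–2.5 °C are overestimated
  by roughly +0.3 to +0.6 °C. An independent hand-rolled random walk on the
  closed-form psychometric function reproduces the same numbers, so this is
  a property of the procedure, not of the implementation. It *adds to* the
  transducer asymmetry in simulated group means.
* *Ceiling-adjacent increases.* Increases from 45 °C cannot exceed 5 °C, so
  thresholds approaching 4 °C are underestimated (≈ −0.2 to −0.5 °C).

In the well-conditioned middle of the range (thresholds ≈ 1–3.5 °C for
increases, ≈ 1–2.6 °C for linear decreases) recovery is within ±0.25 °C.
Relatedly, retained-trial accuracy matches 79.4 % within ±3 points only for
observers whose thresholds sit mid-grid; an observer whose threshold is near
the 0.5 °C floor spends retained trials above threshold and shows ≈ 82 %.

## Experiment designs

`experiment_config()` encodes four presets. Fixed numbers: 6-s stimuli with
1-s hold and 2 °C/s ramps (first design), 6-s stimuli with 3-s hold and
4 °C/s ramps (second), 10-s stimuli with 5-s hold, 4 °C/s, decreases from
47 °C and a 4-point confidence scale (third), and the rating task (46–46,
47–47, 46–47, 47–46 °C stimuli, 14 presentations each, 2 blocks of 28,
eVAS rating probed 1 s before stimulus end). Counterbalancing is by
participant parity (even index: increase blocks first) — an arbitrary but
reproducible assignment where only "counterbalanced" is specified. Stimulus
modality ("radiant"/"contact") is a label with no observer consequences; the
first design runs a single modality by default and both when asked
(`modalities = c("radiant", "contact")`), which the null-calibration test
uses for the direction × modality ANOVA. The starting delta of the
third design's 47 °C decrease staircase is unstated anywhere authoritative;
we use 2.5 °C (first decrease reaches 44.5 °C).

Every staircase block draws from its own RNG substream
(`substream_seed(seed, participant, block_code)`, a Lehmer-style fold modulo
$2^{31}-1$), so adding a participant or reordering blocks never perturbs
anyone else's data, and identical seeds reproduce results bit-for-bit.

## The synthetic cohort

`cohort_hyperparams()` states the population the simulations run on:
log-normal gain ($a$, median 1), exponent ($\gamma$, median 2, log-SD 0.12,
truncated at 1), and decision noise ($\sigma$, median 6 perceived units,
log-SD 0.12); lapse uniform on [0, 0.04]; eVAS mapping
$b_0 \in [1.5, 2.5]$, $b_1 \in [0.10, 0.17]$, rating noise
$\sigma_r \in [0.6, 1.2]$. These values were chosen once so that (a)
simulated detection thresholds fall in the 1–4 °C band typical of
noxious-heat 2IFC work, with median theoretical thresholds of ≈ 1.0 °C
(increase from 45), ≈ 1.6 °C (decrease from 45) and ≈ 0.8 °C (decrease from
47); (b) eVAS ratings of 46–47 °C stimuli land around 4–5.5; and (c) the
decrease/increase asymmetry has a paired effect size near 1, comparable to
what such experiments report. The linear null cohort
(`null_linear_hyperparams()`) sets $\gamma = 1$ for everyone and rescales
$\sigma$ to 1.75 — a linear transducer maps °C one-to-one per unit gain, so
the convex cohort's $\sigma$ would leave it with no attainable threshold —
giving direction-symmetric thresholds ≈ 2 °C.

What the generator emulates: stable inter-individual differences in
sensitivity, noise and scale use; seeded reproducibility; the fan of
individual thresholds around the group mean. What it does not: adaptation
and sensitization across trials, drift within a session, modality-specific
biophysics, criterion shifts, or any coupling between confidence and
accuracy beyond the decision variable. A green mechanism test therefore
establishes that the convex-transducer explanation *suffices* under these
idealizations — not that human observers lack temporal-contrast mechanisms,
and not that the effect sizes match any particular human dataset.

## Numerical choices

* `theoretical_threshold()` inverts the closed-form psychometric function by
  bisection to $10^{-4}$ °C; if the function never attains $0.5^{1/3}$
  within the temperature bounds (heavy lapse, or saturation) it returns `NA`
  with a `no_solution_warning` rather than a spurious number.
* Ties in the 2IFC decision (`which.max`) resolve to interval 1; with
  continuous noise this has probability zero.
* `paired_t()` treats zero-variance differences as a degenerate-sample
  error rather than reporting $t = 0$: silent zeros from constant data are
  more often a pipeline bug than a finding.
* `rm_anova_2x2()` reports $F = 0$, $p = 1$ when an effect's sum of squares
  is exactly zero (its own error stratum is then typically zero too).
* `required_sample_size()` evaluates exact noncentral-t power and scans
  upward from $n = 2$; two-sided $\alpha = 0.05$ is the assumed (and
  documented) default where the convention is not stated.
* Fixture CSVs format numbers with 15 significant digits via `format()` so
  regeneration under the same seed is byte-identical across runs.

## Limitations

The staircase biases above are the main one. Additionally, the confidence
model is deliberately minimal (no direction-specific confidence effects);
discrimination blocks inherit estimation error from the detection threshold
they use as reference; and the package makes no attempt to fit $a, \gamma,
\sigma$ to human group means — parameter recovery and qualitative pattern
reproduction, not curve fitting, are its acceptance surface.
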