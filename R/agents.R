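# Simulated agents: the two artificial "others" whose preferences participants
# learn, KT/KU-governed choosers, the Other-block learner, and correct-choice
# labeling/scoring.

#' Build the two simulated others from a baseline discount rate
#'
#' The others' log10 discount rates are the participant's baseline k plus one
#' (designed as *more impulsive*) and minus one (designed as *more patient*),
#' with no clipping to the task range. Their choices are softmax-noisy with
#' inverse temperature `10^t_sim` by default (`t_sim` read as log10 T; set
#' `t_is_log10 = FALSE` to use `T = t_sim` directly).
#'
#' @param baseline_k baseline log10 discount rate (typically the KT estimate
#'   from the first Self block).
#' @param t_sim softmax noise parameter for the others' simulated choices.
#' @param t_is_log10 if `TRUE` (default), `t_sim` is log10 of the inverse
#'   temperature.
#' @return Data frame with two rows: `k_other`, `design_label`
#'   (`"more_impulsive"`, `"more_patient"`), `t_sim` (log10 scale).
#' @export
make_others <- function(baseline_k, t_sim = 1, t_is_log10 = TRUE) {
  stopifnot(is.finite(baseline_k))
  t_log <- if (t_is_log10) t_sim else log10(t_sim)
  data.frame(
    k_other = c(baseline_k + 1, baseline_k - 1),
    design_label = c("more_impulsive", "more_patient"),
    t_sim = t_log
  )
}

#' Classify an other's preference direction relative to a reference
#'
#' Direction labels used in analysis are assigned by the sign of
#' `k_other - km_ref` (reference usually the fitted baseline km), which can
#' disagree with the design intent when the fitted baseline differs from the
#' online KT estimate by more than 1.
#'
#' @param k_other the other's log10 discount rate.
#' @param km_ref reference log10 discount-rate mean.
#' @return `"more_impulsive"`, `"more_patient"`, or `NA` on an exact tie.
#' @export
classify_other <- function(k_other, km_ref) {
  ifelse(k_other > km_ref, "more_impulsive",
         ifelse(k_other < km_ref, "more_patient", NA_character_))
}

#' Simulate one KT (point-preference) choice
#'
#' Bernoulli draw with `P(LL)` from the softmax rule applied to hyperbolic
#' values at `K = 10^k`. Uses the current R RNG stream.
#'
#' @param pair one-row data frame (`ss_amount`, `ll_amount`, `delay`);
#'   vectorized over rows.
#' @param k log10 discount rate.
#' @param t log10 inverse temperature.
#' @return Character vector of `"SS"`/`"LL"`.
#' @export
simulate_choice_kt <- function(pair, k, t) {
  v_ll <- hyperbolic_value(pair$ll_amount, pair$delay, 10^k)
  p <- kt_choice_prob(v_ll, pair$ss_amount, t)
  ifelse(stats::runif(nrow(pair)) < p, "LL", "SS")
}

#' Simulate one KU (preference-uncertainty) choice
#'
#' Equivalent to drawing `k ~ N(km, ku^2)` on each trial and choosing LL iff
#' the draw is below the pair's indifference log discount rate.
#'
#' @inheritParams simulate_choice_kt
#' @param km,ku KU parameters (mean and sd of the log10 discount-rate
#'   distribution).
#' @return Character vector of `"SS"`/`"LL"`.
#' @export
simulate_choice_ku <- function(pair, km, ku) {
  p <- ku_choice_prob(pair$ss_amount, pair$ll_amount, pair$delay, km, ku)
  ifelse(stats::runif(nrow(pair)) < p, "LL", "SS")
}

#' Correct choice for a pair given an other's discount rate
#'
#' The correct choice is the option with the greater hyperbolic value under
#' the other's discount rate: LL when `k_other` is below the pair's
#' indifference log discount rate, SS when above. Exact ties (measure zero)
#' are labeled LL for determinism.
#'
#' @inheritParams simulate_choice_kt
#' @param k_other the other's log10 discount rate.
#' @return Character vector of `"SS"`/`"LL"`.
#' @export
correct_choice <- function(pair, k_other) {
  x <- indifference_logk(pair$ss_amount, pair$ll_amount, pair$delay)
  ifelse(k_other <= x, "LL", "SS")
}

#' Simulate a learner completing one Other block
#'
#' Per trial the learner predicts the other's choice by the softmax rule at
#' the posterior mean of its belief grid (decision noise `10^learner_t`),
#' observes the other's stochastic softmax choice as feedback, and updates its
#' belief. Accuracy is scored against the deterministic value-maximizing
#' choice under the other's true discount rate.
#'
#' @param other one row of [make_others()] (fields `k_other`, `t_sim`).
#' @param pairs data frame of the block's choice pairs (one row per trial).
#' @param belief initial `belief_grid` over the other's k.
#' @param learner_t log10 inverse temperature of the learner's own decisions.
#'   The default (-0.2, i.e. T of about 0.63) calibrates simulated learning
#'   accuracy to the high-but-imperfect range observed in delegated
#'   intertemporal choice experiments (roughly 78-85% correct).
#' @return List with `decisions` (data frame: pair columns, `choice`,
#'   `other_choice`, `feedback_correct`, `correct`), `accuracy`, and the final
#'   `belief`.
#' @export
simulate_other_block <- function(other, pairs, belief, learner_t = -0.2) {
  n <- nrow(pairs)
  choice <- character(n); other_choice <- character(n)
  for (i in seq_len(n)) {
    pr <- pairs[i, , drop = FALSE]
    k_hat <- belief_mean(belief)
    choice[i] <- simulate_choice_kt(pr, k_hat, learner_t)
    other_choice[i] <- simulate_choice_kt(pr, other$k_other, other$t_sim)
    belief <- belief_update(belief, pr, other_choice[i])
  }
  correct <- correct_choice(pairs, other$k_other)
  dec <- data.frame(pairs, choice = choice, other_choice = other_choice,
                    feedback_correct = choice == other_choice, correct = correct,
                    row.names = NULL)
  list(decisions = dec, accuracy = mean(choice == correct), belief = belief)
}

#' One-sided exact binomial test of learning accuracy against chance
#'
#' Right-tailed exact binomial test of `n_correct` successes in `n_trials`
#' against the 50% chance level.
#'
#' @param n_correct number of correct predictions.
#' @param n_trials number of trials.
#' @return The exact one-sided p-value.
#' @export
accuracy_binomial_test <- function(n_correct, n_trials) {
  if (n_correct < 0 || n_trials < 1 || n_correct > n_trials || n_correct != round(n_correct))
    stop("invalid counts")
  stats::binom.test(n_correct, n_trials, p = 0.5, alternative = "greater")$p.value
}
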