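test_that("simulated others sit one log-unit either side of baseline, unclipped", {
  o <- make_others(-2)
  expect_equal(o$k_other, c(-1, -3))
  expect_equal(o$design_label, c("more_impulsive", "more_patient"))
  expect_equal(make_others(-0.2)$k_other, c(0.8, -1.2))  # no clipping
  expect_equal(make_others(-2, t_sim = 10, t_is_log10 = FALSE)$t_sim, c(1, 1))
  expect_equal(classify_other(-1, -2), "more_impulsive")
  expect_equal(classify_other(-3, -2), "more_patient")
})

test_that("direction labels track the reference, reproducing shared-label cases", {
  # with the reference at the design baseline, labels match design intent
  o <- make_others(-2)
  expect_equal(classify_other(o$k_other, -2), o$design_label)
  # a fitted baseline more than 1 away flips one label so both others share it
  expect_equal(classify_other(o$k_other, -3.5),
               c("more_impulsive", "more_impulsive"))
})

test_that("simulated choice frequencies converge to the model probabilities", {
  pair <- choice_pair(10, 20, 10)
  reps <- pair[rep(1, 10000), ]
  set.seed(5)
  # KU agent: P(LL) = pnorm(1) for km = -2, ku = 1 at threshold -1
  frac <- mean(simulate_choice_ku(reps, km = -2, ku = 1) == "LL")
  expect_equal(frac, pnorm(1), tolerance = 0.012)
  # KT agent at its exact indifference point: 50%
  frac2 <- mean(simulate_choice_kt(reps, k = -1, t = 0.5) == "LL")
  expect_equal(frac2, 0.5, tolerance = 0.02)
  # patient KT agent with high temperature: always delayed
  expect_true(all(simulate_choice_kt(reps[1:100, ], k = -3.5, t = 1) == "LL"))
  # seeded reproducibility
  set.seed(7); a <- simulate_choice_ku(reps[1:50, ], -2, 0.8)
  set.seed(7); b <- simulate_choice_ku(reps[1:50, ], -2, 0.8)
  expect_identical(a, b)
})

test_that("correct choice is the value-maximizing option under the other's rate", {
  pair <- choice_pair(10, 20, 10)  # indifference point at -1
  expect_equal(correct_choice(pair, 0), "SS")        # faster discounter
  expect_equal(correct_choice(pair, -3), "LL")       # slower discounter
  expect_equal(correct_choice(pair, -1), "LL")       # tie convention
  # consistency with the hyperbolic values themselves
  set.seed(6)
  pool <- enumerate_pairs()
  pick <- pool[sample.int(nrow(pool), 300), ]
  ks <- runif(300, -4, 0)
  v_ll <- hyperbolic_value(pick$ll_amount, pick$delay, 10^ks)
  expect_equal(correct_choice(pick, ks) == "LL", v_ll >= pick$ss_amount)
})

test_that("exact binomial learning test matches the tail-sum oracle", {
  expect_equal(accuracy_binomial_test(50, 50), 2^-50)
  expect_equal(accuracy_binomial_test(0, 50), 1)
  # manual tail sum as the independent oracle
  expect_equal(accuracy_binomial_test(25, 50), sum(dbinom(25:50, 50, 0.5)))
  expect_equal(accuracy_binomial_test(40, 50), sum(dbinom(40:50, 50, 0.5)))
  expect_error(accuracy_binomial_test(51, 50), "invalid")
})

test_that("other-block learner spans perfect, calibrated and chance regimes", {
  pairs <- generative_pairs(make_uniform_targets(50))
  other <- make_others(-2)[1, ]  # impulsive, k = -1
  # learner already knowing the other's k, noise-free: matches correct choice always
  set.seed(11)
  known <- belief_init(mean = other$k_other, sd = 1e-4)
  res <- simulate_other_block(other, pairs, known, learner_t = 3)
  expect_equal(res$accuracy, 1.0)
  # near-random learner (extremely noisy decisions): accuracy near chance
  set.seed(12)
  accs <- replicate(30, simulate_other_block(other, pairs, belief_init(),
                                             learner_t = -3)$accuracy)
  expect_equal(mean(accs), 0.5, tolerance = 0.05)
  # default learner: high but imperfect accuracy band
  set.seed(13)
  accs2 <- replicate(40, {
    o <- make_others(runif(1, -3, -1))[sample(1:2, 1), ]
    simulate_other_block(o, pairs, belief_init(mean = o$k_other +
                                                 ifelse(o$design_label == "more_impulsive", -1, 1),
                                               sd = 1))$accuracy
  })
  expect_gt(mean(accs2), 0.7)
  expect_lt(mean(accs2), 0.9)
  # feedback reflects the other's stochastic choice, not the deterministic label
  expect_true(all(res$decisions$feedback_correct ==
                    (res$decisions$choice == res$decisions$other_choice)))
})
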