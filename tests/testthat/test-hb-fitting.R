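test_that("split-chain R-hat detects convergence and its absence", {
  # identical constant chains are degenerate: 1 by convention
  expect_equal(rhat(matrix(2, 100, 4)), 1)
  # iid chains from the same distribution sit next to 1
  set.seed(20)
  expect_lt(rhat(matrix(rnorm(8000), 2000, 4)), 1.01)
  expect_gte(rhat(matrix(rnorm(8000), 2000, 4)), 0.999)
  # well-separated chains are flagged far above the 1.1 rule of thumb
  expect_gt(rhat(cbind(rnorm(500), rnorm(500, 10))), 1.1)
  expect_error(rhat(matrix(1, 10, 1)), "two chains")
  # agrees with the coda implementation on a common example
  set.seed(21)
  m <- matrix(rnorm(4000, sd = 2), 1000, 4); m[, 2] <- m[, 2] + 0.5
  cl <- coda::mcmc.list(lapply(1:4, function(i) coda::mcmc(m[, i])))
  expect_equal(rhat(m), unname(coda::gelman.diag(cl)$psrf[1, 1]),
               tolerance = 0.02)
})

test_that("hierarchical KU fit recovers a homogeneous cohort's parameters", {
  # 30 subjects sharing km = -2, ku = 0.5, 100 trials each
  sim <- sim_ku_cohort(30, 100, rep(-2, 30), rep(0.5, 30), seed = 30,
                       targets = make_uniform_targets(100))
  fit <- quick_fit(sim$decisions, seed = 1, chains = 2, warmup = 500, iter = 500)
  g <- apply(fit$draws$group, 3, mean)
  expect_equal(unname(g["mu_km"]), -2, tolerance = 0.2)
  expect_equal(nrow(coef(fit)), 30L)
  expect_true(all(coef(fit)[, "km"] < 0))
  expect_true(all(coef(fit)[, "ku"] > 0))
})

test_that("likelihood pushes always-SS choosers impulsive and always-LL patient", {
  pairs <- generative_pairs(make_uniform_targets(40))
  dec <- rbind(
    data.frame(subject_id = "all_ss", pairs[, 1:3], choice = "SS"),
    data.frame(subject_id = "all_ll", pairs[, 1:3], choice = "LL"),
    # two intermediate subjects keep the group posterior proper
    sim_ku_cohort(2, 40, c(-2.5, -1.5), c(0.5, 0.5), seed = 31,
                  targets = make_uniform_targets(40))$decisions
  )
  fit <- quick_fit(dec, seed = 2)
  cf <- coef(fit)
  expect_gt(cf["all_ss", "km"], cf["all_ll", "km"])
  expect_gt(cf["all_ss", "km"], -0.8)
  expect_lt(cf["all_ll", "km"], -3)
})

test_that("prior-only sampling reproduces the weakly-informative group prior", {
  fit <- suppressWarnings(ku_fit(NULL, n_subjects = 5, chains = 4,
                                 warmup = 1000, iter = 1500, seed = 4))
  mu_km <- as.vector(fit$draws$group[, , "mu_km"])
  mu_ku <- as.vector(fit$draws$group[, , "mu_ku"])
  expect_equal(mean(mu_km), 0, tolerance = 0.5)
  expect_equal(sd(mu_km), 3, tolerance = 0.5)
  expect_equal(mean(mu_ku), 0, tolerance = 0.6)
  expect_equal(sd(mu_ku), 3, tolerance = 0.5)
  # subject draws respect the constraints
  expect_true(all(fit$draws$km < 0))
  expect_true(all(fit$draws$ku > 0))
})

test_that("subject-level posteriors agree with an independent JAGS fit", {
  set.seed(31)
  S <- 10; ntr <- 40
  km <- -runif(S, 0.5, 3.5); ku <- runif(S, 0.3, 1.2)
  sim <- sim_ku_cohort(S, ntr, km, ku, seed = 31)
  fit <- suppressWarnings(ku_fit(sim$decisions, chains = 4, warmup = 1000,
                                 iter = 1000, seed = 2))
  cf <- coef(fit)
  x <- indifference_logk(sim$decisions$ss_amount, sim$decisions$ll_amount,
                         sim$decisions$delay)
  si <- as.integer(factor(sim$decisions$subject_id))
  mod <- "model {
    for (j in 1:N) { y[j] ~ dbern(max(1e-12, min(1 - 1e-12,
                       phi((x[j] - km[s[j]]) / ku[s[j]])))) }
    for (i in 1:S) { km[i] ~ dnorm(mu_km, tau_km) T(, 0)
                     ku[i] ~ dnorm(mu_ku, tau_ku) T(0, ) }
    mu_km ~ dnorm(0, 0.111111); mu_ku ~ dnorm(0, 0.111111)
    sd_km ~ dt(0, 0.25, 1) T(0, ); sd_ku ~ dt(0, 0.25, 1) T(0, )
    tau_km <- pow(sd_km, -2); tau_ku <- pow(sd_ku, -2)
  }"
  jm <- rjags::jags.model(
    textConnection(mod),
    data = list(y = as.integer(sim$decisions$choice == "LL"), x = x, s = si,
                N = length(x), S = S),
    n.chains = 2, n.adapt = 1000, quiet = TRUE,
    inits = list(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
                 list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 2)))
  update(jm, 1000)
  sm <- rjags::coda.samples(jm, c("km", "ku"), 2000)
  mm <- colMeans(as.matrix(sm))
  jkm <- mm[sprintf("km[%d]", seq_len(S))]
  jku <- mm[sprintf("ku[%d]", seq_len(S))]
  expect_gt(cor(cf[, "km"], jkm), 0.99)
  expect_gt(cor(cf[, "ku"], jku), 0.98)
  expect_lt(max(abs(cf[, "km"] - jkm)), 0.1)
  expect_lt(max(abs(cf[, "ku"] - jku)), 0.1)
})

test_that("KT grid fit recovers a point-preference agent's discount rate", {
  pairs <- generative_pairs(make_uniform_targets(50))
  errs <- vapply(1:50, function(r) {
    set.seed(500 + r)
    dec <- data.frame(pairs[, 1:3],
                      choice = simulate_choice_kt(pairs, k = -2, t = 0.5))
    kt_fit(dec)$k_mean - (-2)
  }, 0)
  expect_lt(median(abs(errs)), 0.3)
  # a single trial still yields a proper posterior inside the support
  one <- data.frame(pairs[1, 1:3], choice = "LL")
  f1 <- kt_fit(one)
  expect_true(f1$k_mean >= -4 && f1$k_mean <= 0)
  expect_equal(sum(f1$posterior), 1, tolerance = 1e-9)
  expect_error(kt_fit(one[0, ]), "no decisions")
})

test_that("posterior summaries and methods are coherent", {
  sim <- sim_ku_cohort(6, 30, runif(6, -3, -1), runif(6, 0.3, 1), seed = 33)
  fit <- quick_fit(sim$decisions, seed = 3)
  ps <- posterior_summary(fit)
  expect_equal(nrow(ps), 6L * 2L)  # one row per subject per parameter
  expect_true(all(ps$lower <= ps$mean & ps$mean <= ps$upper))
  expect_equal(fit$n_draws, 2L * 300L)
  # predictions are probabilities; simulation is seed-reproducible
  p <- predict(fit)
  expect_true(all(p > 0 & p < 1))
  s1 <- simulate(fit, nsim = 3, seed = 9)
  s2 <- simulate(fit, nsim = 3, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% c("SS", "LL")))
  expect_output(print(fit), "retained draws")
  expect_output(print(summary(fit)), "Group-level posterior")
  expect_error(ku_fit(sim$decisions[0, ]), "empty block")
})
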