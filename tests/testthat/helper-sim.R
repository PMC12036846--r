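# Simulation helpers shared across test files. All fixtures are generated in
# code; no data files.

# Simulate a KU cohort on one generative design; returns decisions + truth.
sim_ku_cohort <- function(n_subjects, n_trials, km, ku, seed,
                          targets = make_uniform_targets(n_trials)) {
  stopifnot(length(km) == n_subjects, length(ku) == n_subjects)
  pairs <- generative_pairs(targets)
  withr_seed <- function(expr) { set.seed(seed); expr }
  dec <- data.frame(
    subject_id = rep(sprintf("s%03d", seq_len(n_subjects)), each = n_trials),
    ss_amount = rep(pairs$ss_amount, n_subjects),
    ll_amount = rep(pairs$ll_amount, n_subjects),
    delay = rep(pairs$delay, n_subjects)
  )
  p <- stats::pnorm(rep(pairs$indiff_logk, n_subjects),
                    rep(km, each = n_trials), rep(ku, each = n_trials))
  set.seed(seed)
  dec$choice <- ifelse(stats::runif(nrow(dec)) < p, "LL", "SS")
  list(decisions = dec, km = km, ku = ku, pairs = pairs)
}

# Brute-force batch Bayes on a belief grid: prior mass times the product of
# per-decision KT likelihoods, renormalized in one step. Independent of
# belief_update's sequential path.
batch_bayes_oracle <- function(belief, pairs, choices) {
  lik <- rep(1, length(belief$grid))
  for (i in seq_len(nrow(pairs))) {
    v_ll <- pairs$ll_amount[i] / (1 + 10^belief$grid * pairs$delay[i])
    p_ll <- 1 / (1 + exp(-10^belief$t_fixed * (v_ll - pairs$ss_amount[i])))
    lik <- lik * (if (choices[i] == "LL") p_ll else 1 - p_ll)
  }
  m <- belief$mass * lik
  m / sum(m)
}

# Numerical quadrature of the base-10 KL integral between two normals,
# independent of the closed form.
kl_quadrature <- function(p_mean, p_sd, q_mean, q_sd) {
  f <- function(x) {
    lp <- stats::dnorm(x, p_mean, p_sd, log = TRUE)
    lq <- stats::dnorm(x, q_mean, q_sd, log = TRUE)
    exp(lp) * (lp - lq) / log(10)
  }
  # the integrand carries p's density as weight, so p's support is enough
  stats::integrate(f, p_mean - 14 * p_sd, p_mean + 14 * p_sd,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# A fast reduced MCMC configuration for module tests.
quick_fit <- function(dec, seed = 1, chains = 2, warmup = 300, iter = 300) {
  suppressWarnings(ku_fit(dec, chains = chains, warmup = warmup, iter = iter, seed = seed))
}
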