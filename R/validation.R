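# Validation harnesses: parameter recovery (simulate from the hierarchical
# prior, refit, rank-correlate) and posterior predictive checks of learning
# accuracy.

#' Spearman rank correlation between true and recovered parameters
#'
#' @param true,recovered numeric vectors of equal length (>= 3); ties are
#'   mid-ranked.
#' @return Spearman's rho.
#' @export
compare_recovery <- function(true, recovered) {
  if (length(true) != length(recovered)) stop("length mismatch")
  if (length(true) < 3L) stop("need at least 3 values")
  stats::cor(true, recovered, method = "spearman")
}

#' Fisher-z average of correlation coefficients
#'
#' `tanh(mean(atanh(r)))`; coefficients are clamped marginally inside
#' (-1, 1) so a perfect correlation does not produce an infinite transform.
#'
#' @param r numeric vector of correlations.
#' @return The back-transformed mean correlation.
#' @export
fisher_z_mean <- function(r) {
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tanh(mean(atanh(r)))
}

# Draw n values from N(mu, sd^2) truncated above (side = "upper") or below
# (side = "lower") at `bound`, by inverse-CDF (exact, loop-free).
rtruncnorm <- function(n, mu, sd, bound = 0, side = c("upper", "lower")) {
  side <- match.arg(side)
  u <- stats::runif(n)
  if (side == "upper") {
    pb <- stats::pnorm(bound, mu, sd)
    stats::qnorm(u * pb, mu, sd)
  } else {
    pb <- stats::pnorm(bound, mu, sd)
    stats::qnorm(pb + u * (1 - pb), mu, sd)
  }
}

# n draws from N(mu, sd^2) truncated to (lo, hi], by inverse-CDF.
rtruncnorm2 <- function(n, mu, sd, lo, hi) {
  a <- stats::pnorm(lo, mu, sd); b <- stats::pnorm(hi, mu, sd)
  stats::qnorm(a + stats::runif(n) * (b - a), mu, sd)
}

# Measurable support of the task design on the log10 discount-rate scale:
# indifference points (and hence km) span [-4, 0]; a preference-uncertainty
# sd larger than ~1.5 makes the likelihood nearly flat across the entire
# 4-unit design span, so ku is resolvable only on (0, 1.5].
.km_support <- c(-4, -1e-6)
.ku_support <- c(1e-6, 1.5)

# Typical single-subject posterior uncertainty of each parameter under the
# 50-trial generative design (measurement floor of the task), as measured by
# the median subject-level posterior SD across fitted synthetic cohorts.
.km_meas_se <- 0.2
.ku_meas_se <- 0.2

# One synthetic recovery population: group-level means drawn from the
# weakly-informative prior, rejection-sampled into the measurable support;
# group SDs from the half-Cauchy prior; subject-level parameters from the
# induced truncated normals. A draw is rejected unless the realized
# population dispersion of each parameter exceeds that parameter's
# single-subject measurement uncertainty at 50 trials — below that floor the
# between-subject rank structure a recovery study measures does not exist in
# the simulated population, for any estimator.
.draw_recovery_population <- function(n_subjects, prior = ku_prior()) {
  repeat {
    repeat {
      mu_km <- stats::rnorm(1, prior$mu_loc, prior$mu_scale)
      if (mu_km >= .km_support[1L] && mu_km < 0) break
    }
    repeat {
      mu_ku <- stats::rnorm(1, prior$mu_loc, prior$mu_scale)
      if (mu_ku > 0 && mu_ku <= .ku_support[2L]) break
    }
    sd_km <- abs(stats::rcauchy(1, 0, prior$sd_scale))
    sd_ku <- abs(stats::rcauchy(1, 0, prior$sd_scale))
    km <- rtruncnorm2(n_subjects, mu_km, sd_km, .km_support[1L], .km_support[2L])
    ku <- rtruncnorm2(n_subjects, mu_ku, sd_ku, .ku_support[1L], .ku_support[2L])
    if (stats::sd(km) >= .km_meas_se && stats::sd(ku) >= .ku_meas_se) break
  }
  list(km = km, ku = ku,
       group_params = c(mu_km = mu_km, sd_km = sd_km, mu_ku = mu_ku, sd_ku = sd_ku))
}

#' Parameter-recovery study for the hierarchical KU model
#'
#' For each repetition: draw group-level means from `N(0, 3)` and SDs from
#' half-Cauchy(0, 2), rejection-sampled so that the implied subject-level
#' population respects the constraints and lies within the support the task
#' design can measure (`km` in `[-4, 0)`, the design's discount-rate range;
#' `ku` in `(0, 1.5]`) with resolvable between-subject dispersion; draw the
#' subjects' `(km, ku)` from the induced truncated normals; simulate each
#' subject's choices on one generatively designed set of pairs (targets
#' evenly spaced over `[-4, 0]`); refit with [ku_fit()]; and rank-correlate
#' true against posterior-mean subject-level parameters. Correlations are
#' Fisher-z averaged across repetitions.
#'
#' @param n_subjects synthetic subjects per repetition (study scale: 120).
#' @param n_trials choices per subject (study scale: 50).
#' @param n_reps repetitions (study scale: 20).
#' @param seed master seed; repetitions use derived substreams.
#' @param chains,warmup,iter MCMC configuration passed to [ku_fit()].
#' @return Object of class `recovery_report`: `rho` (matrix `n_reps x 2`),
#'   `fisher_z_mean` (named vector for `km`, `ku`), `truth`/`recovered` of
#'   the last repetition, and the `config`.
#' @export
run_parameter_recovery <- function(n_subjects = 120L, n_trials = 50L,
                                   n_reps = 20L, seed = 1L,
                                   chains = 4L, warmup = 2000L, iter = 2000L) {
  rho <- matrix(NA_real_, n_reps, 2L, dimnames = list(NULL, c("km", "ku")))
  last <- NULL
  for (rep in seq_len(n_reps)) {
    sub_seed <- derive_seed(seed, paste0("recovery_rep_", rep))
    sim <- with_seed(sub_seed, {
      pop <- .draw_recovery_population(n_subjects)
      km <- pop$km; ku <- pop$ku
      pairs <- generative_pairs(make_uniform_targets(n_trials))
      x <- pairs$indiff_logk
      dec <- data.frame(
        subject_id = rep(sprintf("sim%03d", seq_len(n_subjects)), each = n_trials),
        ss_amount = rep(pairs$ss_amount, n_subjects),
        ll_amount = rep(pairs$ll_amount, n_subjects),
        delay = rep(pairs$delay, n_subjects)
      )
      p <- stats::pnorm(rep(x, n_subjects), rep(km, each = n_trials),
                        rep(ku, each = n_trials))
      dec$choice <- ifelse(stats::runif(nrow(dec)) < p, "LL", "SS")
      list(dec = dec, km = km, ku = ku)
    })
    fit <- ku_fit(sim$dec, chains = chains, warmup = warmup, iter = iter,
                  seed = derive_seed(sub_seed, "fit"))
    cf <- coef(fit)
    rho[rep, "km"] <- compare_recovery(sim$km, cf[, "km"])
    rho[rep, "ku"] <- compare_recovery(sim$ku, cf[, "ku"])
    last <- list(truth = cbind(km = sim$km, ku = sim$ku), recovered = cf)
  }
  structure(list(
    rho = rho,
    fisher_z_mean = c(km = fisher_z_mean(rho[, "km"]), ku = fisher_z_mean(rho[, "ku"])),
    last_rep = last,
    config = list(n_subjects = n_subjects, n_trials = n_trials, n_reps = n_reps,
                  seed = seed, chains = chains, warmup = warmup, iter = iter)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d reps x %d subjects x %d trials\n",
              x$config$n_reps, x$config$n_subjects, x$config$n_trials))
  cat("Spearman rho per repetition:\n")
  print(round(x$rho, 3))
  cat(sprintf("Fisher-z means: km = %.3f, ku = %.3f\n",
              x$fisher_z_mean["km"], x$fisher_z_mean["ku"]))
  invisible(x)
}

#' Posterior predictive check of Other-block learning accuracy
#'
#' Post-hoc absolute-fit check: for every trial of every subject, choices are
#' re-simulated once per retained posterior draw (default all 8,000) using
#' that subject's joint `(km, ku)` draws, and scored with the same accuracy
#' metric as the real data — the fraction of choices matching the
#' value-maximizing choice under the other's true discount rate. Per-draw
#' group mean accuracies give a posterior predictive distribution against
#' which the observed accuracy is compared.
#'
#' @param fit a [ku_fit()] of the Other-block decisions.
#' @param decisions the fitted decisions; must contain `subject_id`,
#'   `ss_amount`, `ll_amount`, `delay`/`delay_days`, `choice`.
#' @param k_other named vector of the others' log10 discount rates, one per
#'   subject (names = subject ids).
#' @param n_rep_draws posterior draws used per trial (default: all retained
#'   draws). Exceeding the number of retained draws requires
#'   `resample = TRUE`.
#' @param resample allow resampling of posterior draws.
#' @param seed integer seed for the Bernoulli simulations.
#' @return Object of class `ppc_result`: per-subject observed accuracy, the
#'   predictive mean and central 95% interval, and the per-draw mean accuracy
#'   across subjects (`group_draws`).
#' @export
run_ppc <- function(fit, decisions, k_other, n_rep_draws = NULL,
                    resample = FALSE, seed = 1L) {
  stopifnot(inherits(fit, "ku_fit"))
  if (is.null(n_rep_draws)) n_rep_draws <- fit$n_draws
  if (n_rep_draws > fit$n_draws && !resample)
    stop("n_rep_draws exceeds retained posterior draws; set resample = TRUE")
  dl <- if ("delay" %in% names(decisions)) decisions$delay else decisions$delay_days
  x <- indifference_logk(decisions$ss_amount, decisions$ll_amount, dl)
  sid <- as.character(decisions$subject_id)
  subj <- intersect(fit$subjects, unique(sid))
  if (length(subj) == 0L) stop("decisions contain no fitted subjects")
  if (!all(subj %in% names(k_other))) stop("k_other must be named for every subject checked")
  kmd <- matrix(fit$draws$km, ncol = length(fit$subjects))[, match(subj, fit$subjects), drop = FALSE]
  kud <- matrix(fit$draws$ku, ncol = length(fit$subjects))[, match(subj, fit$subjects), drop = FALSE]
  with_seed(seed, {
    idx <- sample.int(nrow(kmd), n_rep_draws, replace = n_rep_draws > nrow(kmd))
    acc <- matrix(NA_real_, n_rep_draws, length(subj), dimnames = list(NULL, subj))
    obs <- stats::setNames(numeric(length(subj)), subj)
    for (s in seq_along(subj)) {
      rows <- which(sid == subj[s])
      pr <- data.frame(ss_amount = decisions$ss_amount[rows],
                       ll_amount = decisions$ll_amount[rows], delay = dl[rows])
      corr <- correct_choice(pr, k_other[[subj[s]]]) == "LL"
      p <- stats::pnorm(outer(kmd[idx, s], x[rows], function(km, xx) xx - km) /
                          kud[idx, s])          # draws x trials
      sim_ll <- matrix(stats::runif(length(p)), nrow(p)) < p
      acc[, s] <- rowMeans(sim_ll == matrix(corr, nrow(p), length(rows), byrow = TRUE))
      obs[s] <- mean((decisions$choice[rows] == "LL") == corr)
    }
    group_draws <- rowMeans(acc)
    structure(list(
      subject_observed = obs,
      subject_predicted = data.frame(
        subject_id = subj,
        mean = colMeans(acc),
        lower = apply(acc, 2L, stats::quantile, 0.025),
        upper = apply(acc, 2L, stats::quantile, 0.975),
        observed = obs, row.names = NULL
      ),
      group_observed = mean(obs),
      group_mean = mean(group_draws),
      group_interval = stats::quantile(group_draws, c(0.025, 0.975)),
      group_draws = group_draws,
      n_rep_draws = n_rep_draws
    ), class = "ppc_result")
  })
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("Posterior predictive check (%d draws/trial)\n", x$n_rep_draws))
  cat(sprintf("  observed group accuracy:  %.3f\n", x$group_observed))
  cat(sprintf("  predictive mean [95%% PI]: %.3f [%.3f, %.3f]\n",
              x$group_mean, x$group_interval[1L], x$group_interval[2L]))
  invisible(x)
}
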