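# Hierarchical Bayesian estimation of the preference-uncertainty (KU) model.
#
# Model, for one group and one experimental block:
#   choice_j ~ Bernoulli( Phi( (x_j - km_{s(j)}) / ku_{s(j)} ) )
#   km_s ~ Normal(mu_km, sd_km^2) truncated to (-Inf, 0)
#   ku_s ~ Normal(mu_ku, sd_ku^2) truncated to (0, Inf)
#   mu_.  ~ Normal(0, 3);  sd_. ~ half-Cauchy(0, 2)
# with x_j the pair's indifference log10 discount rate. The subject-level
# truncated normals are properly normalized, so prior-only sampling returns
# the exact N(0, 3) marginal for the group means.
#
# The posterior is sampled by an adaptive Metropolis-within-Gibbs scheme:
# subject-level parameters are updated in vectorized blocks (random walk on km
# with rejection at the bound; random walk on log ku), group-level parameters
# by scalar random walks, plus joint translation/rescaling moves of
# (group mean, subject vector) that decorrelate the hierarchy. Proposal scales
# adapt toward 44% acceptance during warmup only, so retained draws come from
# a fixed-kernel Markov chain.

#' Weakly-informative prior specification for hierarchical fits
#'
#' Group-level means are `N(mu_loc, mu_scale^2)` (default `N(0, 3)` on the
#' log10 scale) and group-level standard deviations half-Cauchy with scale
#' `sd_scale` (default 2). Subject-level `km` is upper-truncated at 0 and
#' `ku` lower-truncated at 0.
#'
#' @param mu_loc,mu_scale location and scale of the group-mean prior.
#' @param sd_scale scale of the half-Cauchy prior on group SDs.
#' @return List of class `ku_prior`.
#' @export
ku_prior <- function(mu_loc = 0, mu_scale = 3, sd_scale = 2) {
  stopifnot(mu_scale > 0, sd_scale > 0)
  structure(list(mu_loc = mu_loc, mu_scale = mu_scale, sd_scale = sd_scale),
            class = "ku_prior")
}

# log density of the half-Cauchy(0, scale) prior
.lhc <- function(x, scale) ifelse(x > 0, log(2) + stats::dcauchy(x, 0, scale, log = TRUE), -Inf)

# per-subject Bernoulli log likelihood, vectorized over all trials
.subj_loglik <- function(km, ku, x, y_idx, n_idx, si, S) {
  z <- (x - km[si]) / ku[si]
  lp <- numeric(length(x))
  lp[y_idx] <- stats::pnorm(z[y_idx], log.p = TRUE)
  lp[n_idx] <- stats::pnorm(z[n_idx], lower.tail = FALSE, log.p = TRUE)
  ll <- numeric(S)
  agg <- rowsum(lp, si)
  ll[as.integer(rownames(agg))] <- agg[, 1L]
  ll
}

.run_ku_chain <- function(x, y, si, S, prior, warmup, iter, seed, init_jitter) {
  with_seed(seed, {
    n <- length(x)
    y_idx <- which(y); n_idx <- which(!y)
    have_data <- n > 0L

    # empirical initialization (moment-matched, then jittered per chain)
    if (have_data) {
      sf <- factor(si, levels = seq_len(S))
      cnt <- tabulate(si, S)
      nll <- tapply(y, sf, sum); nll[is.na(nll)] <- 0
      f <- (nll + 0.5) / (cnt + 1)
      mx <- tapply(x, sf, stats::median)
      mx[is.na(mx)] <- stats::median(x)
      km <- pmin(-0.05, pmax(-7, mx - stats::qnorm(f))) + stats::rnorm(S, 0, init_jitter)
      km <- as.numeric(pmin(km, -0.01))
    } else {
      km <- -abs(stats::rnorm(S, 2, 1))
    }
    ku <- exp(stats::rnorm(S, 0, init_jitter))
    mu_km <- min(mean(km), -0.1); sd_km <- max(stats::sd(km), 0.5)
    mu_ku <- max(mean(ku), 0.1); sd_ku <- max(stats::sd(ku), 0.5)
    if (S == 1L) { sd_km <- 1; sd_ku <- 1 }

    s_km <- rep(0.3, S); s_ku <- rep(0.3, S)          # subject proposal scales
    s_grp <- c(mu_km = 0.3, lsd_km = 0.3, mu_ku = 0.3, lsd_ku = 0.3,
               tr_km = 0.3, sc_km = 0.2, tr_ku = 0.2, sc_ku = 0.2)
    acc_km <- numeric(S); acc_ku <- numeric(S); acc_grp <- s_grp * 0
    batch <- 50L; nbatch <- 0L

    ll <- if (have_data) .subj_loglik(km, ku, x, y_idx, n_idx, si, S) else numeric(S)

    # group-level conditional log densities (include truncation normalizers)
    lp_km_grp <- function(mu, sd) {
      stats::dnorm(mu, prior$mu_loc, prior$mu_scale, log = TRUE) + .lhc(sd, prior$sd_scale) +
        sum(stats::dnorm(km, mu, sd, log = TRUE)) -
        S * stats::pnorm(0, mu, sd, log.p = TRUE)
    }
    lp_ku_grp <- function(mu, sd) {
      stats::dnorm(mu, prior$mu_loc, prior$mu_scale, log = TRUE) + .lhc(sd, prior$sd_scale) +
        sum(stats::dnorm(ku, mu, sd, log = TRUE)) -
        S * stats::pnorm(0, mu, sd, lower.tail = FALSE, log.p = TRUE)
    }

    total <- warmup + iter
    keep_km <- matrix(NA_real_, iter, S); keep_ku <- matrix(NA_real_, iter, S)
    keep_grp <- matrix(NA_real_, iter, 4L,
                       dimnames = list(NULL, c("mu_km", "sd_km", "mu_ku", "sd_ku")))

    for (it in seq_len(total)) {
      ## subject-level km
      prop <- km + s_km * stats::rnorm(S)
      ok <- prop < 0
      llp <- if (have_data) .subj_loglik(prop, ku, x, y_idx, n_idx, si, S) else numeric(S)
      logr <- llp - ll +
        stats::dnorm(prop, mu_km, sd_km, log = TRUE) - stats::dnorm(km, mu_km, sd_km, log = TRUE)
      acc <- ok & (log(stats::runif(S)) < logr)
      km[acc] <- prop[acc]; ll[acc] <- llp[acc]; acc_km <- acc_km + acc

      ## subject-level ku (random walk on log scale; Jacobian term)
      lprop <- log(ku) + s_ku * stats::rnorm(S)
      prop <- exp(lprop)
      llp <- if (have_data) .subj_loglik(km, prop, x, y_idx, n_idx, si, S) else numeric(S)
      logr <- llp - ll +
        stats::dnorm(prop, mu_ku, sd_ku, log = TRUE) - stats::dnorm(ku, mu_ku, sd_ku, log = TRUE) +
        lprop - log(ku)
      acc <- log(stats::runif(S)) < logr
      ku[acc] <- prop[acc]; ll[acc] <- llp[acc]; acc_ku <- acc_ku + acc

      ## group-level scalar updates (two sweeps)
      for (sw in 1:2) {
        p <- mu_km + s_grp["mu_km"] * stats::rnorm(1)
        if (log(stats::runif(1)) < lp_km_grp(p, sd_km) - lp_km_grp(mu_km, sd_km)) {
          mu_km <- p; acc_grp["mu_km"] <- acc_grp["mu_km"] + 0.5
        }
        p <- sd_km * exp(s_grp["lsd_km"] * stats::rnorm(1))
        if (log(stats::runif(1)) <
            lp_km_grp(mu_km, p) - lp_km_grp(mu_km, sd_km) + log(p) - log(sd_km)) {
          sd_km <- p; acc_grp["lsd_km"] <- acc_grp["lsd_km"] + 0.5
        }
        p <- mu_ku + s_grp["mu_ku"] * stats::rnorm(1)
        if (log(stats::runif(1)) < lp_ku_grp(p, sd_ku) - lp_ku_grp(mu_ku, sd_ku)) {
          mu_ku <- p; acc_grp["mu_ku"] <- acc_grp["mu_ku"] + 0.5
        }
        p <- sd_ku * exp(s_grp["lsd_ku"] * stats::rnorm(1))
        if (log(stats::runif(1)) <
            lp_ku_grp(mu_ku, p) - lp_ku_grp(mu_ku, sd_ku) + log(p) - log(sd_ku)) {
          sd_ku <- p; acc_grp["lsd_ku"] <- acc_grp["lsd_ku"] + 0.5
        }
      }

      ## joint translation move on the km hierarchy: (mu_km, km) -> + d
      d <- s_grp["tr_km"] * stats::rnorm(1)
      pk <- km + d; pm <- mu_km + d
      if (all(pk < 0)) {
        llp <- if (have_data) .subj_loglik(pk, ku, x, y_idx, n_idx, si, S) else numeric(S)
        logr <- sum(llp - ll) +
          stats::dnorm(pm, prior$mu_loc, prior$mu_scale, log = TRUE) -
          stats::dnorm(mu_km, prior$mu_loc, prior$mu_scale, log = TRUE) -
          S * (stats::pnorm(0, pm, sd_km, log.p = TRUE) -
               stats::pnorm(0, mu_km, sd_km, log.p = TRUE))
        if (log(stats::runif(1)) < logr) {
          km <- pk; mu_km <- pm; ll <- llp; acc_grp["tr_km"] <- acc_grp["tr_km"] + 1
        }
      }

      ## joint rescaling move on the km hierarchy: sd *= e, km centered on mu rescaled
      e <- exp(s_grp["sc_km"] * stats::rnorm(1))
      pk <- mu_km + (km - mu_km) * e; ps <- sd_km * e
      if (all(pk < 0)) {
        llp <- if (have_data) .subj_loglik(pk, ku, x, y_idx, n_idx, si, S) else numeric(S)
        # Normal terms in (km - mu)/sd cancel except the 1/sd factor; with the
        # Jacobian e^S for km and e for sd this reduces to prior + normalizer.
        logr <- sum(llp - ll) + .lhc(ps, prior$sd_scale) - .lhc(sd_km, prior$sd_scale) +
          log(e) -
          S * (stats::pnorm(0, mu_km, ps, log.p = TRUE) -
               stats::pnorm(0, mu_km, sd_km, log.p = TRUE))
        if (log(stats::runif(1)) < logr) {
          km <- pk; sd_km <- ps; ll <- llp; acc_grp["sc_km"] <- acc_grp["sc_km"] + 1
        }
      }

      ## joint translation on the ku hierarchy
      d <- s_grp["tr_ku"] * stats::rnorm(1)
      pk <- ku + d; pm <- mu_ku + d
      if (all(pk > 0)) {
        llp <- if (have_data) .subj_loglik(km, pk, x, y_idx, n_idx, si, S) else numeric(S)
        logr <- sum(llp - ll) +
          stats::dnorm(pm, prior$mu_loc, prior$mu_scale, log = TRUE) -
          stats::dnorm(mu_ku, prior$mu_loc, prior$mu_scale, log = TRUE) -
          S * (stats::pnorm(0, pm, sd_ku, lower.tail = FALSE, log.p = TRUE) -
               stats::pnorm(0, mu_ku, sd_ku, lower.tail = FALSE, log.p = TRUE))
        if (log(stats::runif(1)) < logr) {
          ku <- pk; mu_ku <- pm; ll <- llp; acc_grp["tr_ku"] <- acc_grp["tr_ku"] + 1
        }
      }

      ## joint rescaling on the ku hierarchy
      e <- exp(s_grp["sc_ku"] * stats::rnorm(1))
      pk <- mu_ku + (ku - mu_ku) * e; ps <- sd_ku * e
      if (all(pk > 0)) {
        llp <- if (have_data) .subj_loglik(km, pk, x, y_idx, n_idx, si, S) else numeric(S)
        logr <- sum(llp - ll) + .lhc(ps, prior$sd_scale) - .lhc(sd_ku, prior$sd_scale) +
          log(e) -
          S * (stats::pnorm(0, mu_ku, ps, lower.tail = FALSE, log.p = TRUE) -
               stats::pnorm(0, mu_ku, sd_ku, lower.tail = FALSE, log.p = TRUE))
        if (log(stats::runif(1)) < logr) {
          ku <- pk; sd_ku <- ps; ll <- llp; acc_grp["sc_ku"] <- acc_grp["sc_ku"] + 1
        }
      }

      ## warmup-only proposal-scale adaptation (Roberts-Rosenthal batching)
      if (it <= warmup && it %% batch == 0L) {
        nbatch <- nbatch + 1L
        delta <- min(0.25, 1 / sqrt(nbatch))
        s_km <- s_km * exp(ifelse(acc_km / batch > 0.44, delta, -delta))
        s_ku <- s_ku * exp(ifelse(acc_ku / batch > 0.44, delta, -delta))
        s_grp <- s_grp * exp(ifelse(acc_grp / batch > 0.3, delta, -delta))
        s_km <- pmin(pmax(s_km, 1e-3), 10); s_ku <- pmin(pmax(s_ku, 1e-3), 10)
        s_grp <- pmin(pmax(s_grp, 1e-3), 10)
        acc_km[] <- 0; acc_ku[] <- 0; acc_grp[] <- 0
      }

      if (it > warmup) {
        j <- it - warmup
        keep_km[j, ] <- km; keep_ku[j, ] <- ku
        keep_grp[j, ] <- c(mu_km, sd_km, mu_ku, sd_ku)
      }
    }
    list(km = keep_km, ku = keep_ku, group = keep_grp)
  })
}

#' Fit the hierarchical Bayesian KU model to one block of one group
#'
#' Estimates subject-level temporal impulsivity (`km`, the mean of the log10
#' discount-rate distribution, constrained negative) and preference
#' uncertainty (`ku`, its standard deviation, constrained positive), together
#' with group-level means and SDs, from trial-by-trial binary choices via
#' MCMC. Blocks are always fit independently with the priors reset, and each
#' group is fit separately with identical weakly-informative priors. The
#' default configuration retains `4 * 2000 = 8000` posterior draws after an
#' equal number of warm-up iterations per chain.
#'
#' @param decisions data frame with one row per trial: `subject_id`,
#'   `ss_amount`, `ll_amount`, `delay` (or `delay_days`), `choice`
#'   (`"SS"`/`"LL"`). Should contain a single block of a single group.
#' @param chains number of independent chains.
#' @param warmup warm-up (adaptation) iterations per chain, discarded.
#' @param iter retained iterations per chain.
#' @param seed master seed; each chain runs on a derived substream.
#' @param prior a [ku_prior()].
#' @param n_subjects prior-only mode: if `decisions` is `NULL`, sample the
#'   hierarchical prior for this many subjects (no likelihood).
#' @param rhat_warn warn when the maximum split-chain R-hat exceeds this
#'   threshold (default 1.05; values at or below 1.01 are considered
#'   converged).
#' @return Object of class `ku_fit` with elements `draws` (list of arrays
#'   `iter x chains x S` for `km` and `ku`, and `iter x chains x 4` for the
#'   group-level parameters), `subjects`, `n_draws`, `rhat`, `config`, and the
#'   fitted `decisions`.
#' @seealso [coef.ku_fit()], [posterior_summary()], [simulate.ku_fit()]
#' @export
ku_fit <- function(decisions, chains = 4L, warmup = 2000L, iter = 2000L,
                   seed = 1L, prior = ku_prior(), n_subjects = NULL,
                   rhat_warn = 1.05) {
  if (is.null(decisions)) {
    if (is.null(n_subjects)) stop("give decisions, or n_subjects for prior-only sampling")
    S <- as.integer(n_subjects)
    subjects <- paste0("prior_", seq_len(S))
    x <- numeric(0); y <- logical(0); si <- integer(0)
  } else {
    if (nrow(decisions) == 0L) stop("empty block: no decisions to fit")
    dl <- if ("delay" %in% names(decisions)) decisions$delay else decisions$delay_days
    if (is.null(dl)) stop("decisions need a 'delay' or 'delay_days' column")
    stopifnot(all(decisions$choice %in% c("SS", "LL")))
    x <- indifference_logk(decisions$ss_amount, decisions$ll_amount, dl)
    y <- decisions$choice == "LL"
    sid <- factor(decisions$subject_id)
    subjects <- levels(sid)
    si <- as.integer(sid)
    S <- length(subjects)
  }
  chains <- as.integer(chains)
  if (chains < 1L) stop("need at least one chain")

  res <- lapply(seq_len(chains), function(ch) {
    .run_ku_chain(x, y, si, S, prior, as.integer(warmup), as.integer(iter),
                  derive_seed(seed, paste0("ku_chain_", ch)), init_jitter = 0.2)
  })
  draws <- list(
    km = array(unlist(lapply(res, `[[`, "km")), dim = c(iter, S, chains)),
    ku = array(unlist(lapply(res, `[[`, "ku")), dim = c(iter, S, chains)),
    group = array(unlist(lapply(res, `[[`, "group")), dim = c(iter, 4L, chains),
                  dimnames = list(NULL, c("mu_km", "sd_km", "mu_ku", "sd_ku"), NULL))
  )
  # permute to iter x chains x param for a natural draws layout
  draws$km <- aperm(draws$km, c(1, 3, 2))
  draws$ku <- aperm(draws$ku, c(1, 3, 2))
  draws$group <- aperm(draws$group, c(1, 3, 2))
  dimnames(draws$group)[[3]] <- c("mu_km", "sd_km", "mu_ku", "sd_ku")

  rh <- c(
    stats::setNames(vapply(1:4, function(p) rhat(draws$group[, , p]), 0),
                    c("mu_km", "sd_km", "mu_ku", "sd_ku")),
    stats::setNames(vapply(seq_len(S), function(s) rhat(draws$km[, , s]), 0),
                    paste0("km[", subjects, "]")),
    stats::setNames(vapply(seq_len(S), function(s) rhat(draws$ku[, , s]), 0),
                    paste0("ku[", subjects, "]"))
  )
  if (chains >= 2L && max(rh) > rhat_warn)
    warning(sprintf("possible non-convergence: max split R-hat = %.3f (%s)",
                    max(rh), names(rh)[which.max(rh)]))

  structure(list(
    draws = draws, subjects = subjects, n_draws = chains * as.integer(iter),
    rhat = if (chains >= 2L) rh else NULL,
    config = list(chains = chains, warmup = as.integer(warmup),
                  iter = as.integer(iter), seed = seed, prior = prior),
    decisions = decisions
  ), class = "ku_fit")
}

#' Split-chain Gelman-Rubin potential scale reduction statistic
#'
#' Each chain is split in half and the classic potential-scale-reduction
#' factor is computed across the resulting half-chains. Values close to 1
#' indicate convergence. Identical constant chains are degenerate and return
#' 1 by convention.
#'
#' @param draws matrix of draws, iterations in rows, chains in columns.
#' @return The split-chain R-hat value.
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("rhat needs at least two chains")
  n <- nrow(draws)
  if (n < 4L) stop("rhat needs at least 4 draws per chain")
  half <- n %/% 2L
  sm <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[seq.int(n - half + 1L, n), , drop = FALSE])
  v <- apply(sm, 2L, stats::var)
  W <- mean(v)
  if (W == 0) return(1)
  B_over_n <- stats::var(colMeans(sm))
  sqrt((half - 1) / half + B_over_n / W)
}

#' Tidy per-subject posterior summary of a KU fit
#'
#' @param fit a [ku_fit()] object.
#' @param probs interval probabilities (default central 95%).
#' @return Data frame with one row per subject per parameter: `subject_id`,
#'   `parameter` (`"km"`/`"ku"`), `mean`, `sd`, `lower`, `upper`.
#' @export
posterior_summary <- function(fit, probs = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "ku_fit"))
  one <- function(par) {
    a <- fit$draws[[par]]
    m <- apply(a, 3L, mean); s <- apply(a, 3L, stats::sd)
    q <- apply(a, 3L, stats::quantile, probs = probs)
    data.frame(subject_id = fit$subjects, parameter = par, mean = m, sd = s,
               lower = q[1L, ], upper = q[2L, ], row.names = NULL)
  }
  rbind(one("km"), one("ku"))
}

#' @export
coef.ku_fit <- function(object, ...) {
  out <- cbind(km = apply(object$draws$km, 3L, mean),
               ku = apply(object$draws$ku, 3L, mean))
  rownames(out) <- object$subjects
  out
}

#' @export
print.ku_fit <- function(x, ...) {
  g <- apply(x$draws$group, 3L, mean)
  cat("Hierarchical Bayesian KU (preference-uncertainty) fit\n")
  cat(sprintf("  subjects: %d   retained draws: %d (%d chains x %d)\n",
              length(x$subjects), x$n_draws, x$config$chains, x$config$iter))
  cat(sprintf("  group posterior means: mu_km = %.3f, sd_km = %.3f, mu_ku = %.3f, sd_ku = %.3f\n",
              g["mu_km"], g["sd_km"], g["mu_ku"], g["sd_ku"]))
  if (!is.null(x$rhat))
    cat(sprintf("  max split R-hat: %.3f\n", max(x$rhat)))
  invisible(x)
}

#' @export
summary.ku_fit <- function(object, ...) {
  out <- list(group = apply(object$draws$group, 3L, function(d)
                c(mean = mean(d), sd = stats::sd(d),
                  `2.5%` = stats::quantile(d, 0.025, names = FALSE),
                  `97.5%` = stats::quantile(d, 0.975, names = FALSE))),
              subjects = posterior_summary(object),
              rhat_max = if (!is.null(object$rhat)) max(object$rhat) else NA_real_,
              n_draws = object$n_draws)
  class(out) <- "summary.ku_fit"
  out
}

#' @export
print.summary.ku_fit <- function(x, ...) {
  cat("Group-level posterior:\n")
  print(round(t(x$group), 3))
  cat(sprintf("\n%d retained draws; max split R-hat %.3f\n", x$n_draws, x$rhat_max))
  cat(sprintf("Subject-level summary: %d rows (use posterior_summary() for the table)\n",
              nrow(x$subjects)))
  invisible(x)
}

#' Posterior-mean choice probabilities
#'
#' @param object a `ku_fit`.
#' @param newdata data frame of pairs (`ss_amount`, `ll_amount`, `delay` or
#'   `delay_days`, `subject_id`); defaults to the fitted decisions.
#' @param ... unused.
#' @return Numeric vector of P(choose LL) per row of `newdata`.
#' @export
predict.ku_fit <- function(object, newdata = NULL, ...) {
  nd <- if (is.null(newdata)) object$decisions else newdata
  if (is.null(nd)) stop("no data to predict for")
  dl <- if ("delay" %in% names(nd)) nd$delay else nd$delay_days
  cf <- coef(object)
  i <- match(as.character(nd$subject_id), object$subjects)
  if (anyNA(i)) stop("newdata contains subjects absent from the fit")
  ku_choice_prob(nd$ss_amount, nd$ll_amount, dl, cf[i, "km"], cf[i, "ku"])
}

#' Simulate choices from the posterior of a KU fit
#'
#' Posterior-predictive simulation: for each requested replicate a joint
#' posterior draw of each subject's `(km, ku)` is selected and binary choices
#' are simulated for every row of `newdata`.
#'
#' @param object a `ku_fit`.
#' @param nsim number of replicated choice sets.
#' @param seed integer seed.
#' @param newdata as in [predict.ku_fit()].
#' @param ... unused.
#' @return Character matrix (`nrow(newdata)` x `nsim`) of `"SS"`/`"LL"`.
#' @export
simulate.ku_fit <- function(object, nsim = 1, seed = 1L, newdata = NULL, ...) {
  nd <- if (is.null(newdata)) object$decisions else newdata
  if (is.null(nd)) stop("no data to simulate for")
  dl <- if ("delay" %in% names(nd)) nd$delay else nd$delay_days
  x <- indifference_logk(nd$ss_amount, nd$ll_amount, dl)
  i <- match(as.character(nd$subject_id), object$subjects)
  if (anyNA(i)) stop("newdata contains subjects absent from the fit")
  km <- matrix(object$draws$km, ncol = dim(object$draws$km)[3L])
  ku <- matrix(object$draws$ku, ncol = dim(object$draws$ku)[3L])
  with_seed(seed, {
    idx <- sample.int(nrow(km), nsim, replace = nsim > nrow(km))
    out <- matrix("", length(x), nsim)
    for (r in seq_len(nsim)) {
      p <- stats::pnorm(x, km[idx[r], i], ku[idx[r], i])
      out[, r] <- ifelse(stats::runif(length(x)) < p, "LL", "SS")
    }
    out
  })
}

#' @export
plot.ku_fit <- function(x, ...) {
  cf <- coef(x)
  kk <- seq(min(cf[, "km"]) - 3 * max(cf[, "ku"]), 1, length.out = 400)
  dens <- sapply(seq_len(nrow(cf)), function(s) stats::dnorm(kk, cf[s, "km"], cf[s, "ku"]))
  graphics::matplot(kk, dens, type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.5),
                    xlab = "log10 discount rate k",
                    ylab = "density",
                    main = "Subject-level discounting distributions (posterior means)", ...)
  invisible(x)
}

#' Grid-posterior fit of the point-preference (KT) model for one subject
#'
#' Posterior over `(k, t)` on a uniform grid with a flat prior on
#' `k in [-4, 0]`, `t in [-1, 1]` and the softmax likelihood on hyperbolic
#' values. The posterior mean of `k` is the baseline discount rate used to
#' construct the simulated others.
#'
#' @param decisions one subject's trials (`ss_amount`, `ll_amount`, `delay` or
#'   `delay_days`, `choice`).
#' @param k_range,t_range grid ranges.
#' @param k_step,t_step grid resolutions.
#' @return Object of class `kt_fit` with `k_mean`, `t_mean`, marginal and
#'   joint grid posteriors.
#' @export
kt_fit <- function(decisions, k_range = c(-4, 0), t_range = c(-1, 1),
                   k_step = 0.05, t_step = 0.05) {
  if (is.null(decisions) || nrow(decisions) == 0L) stop("no decisions to fit")
  dl <- if ("delay" %in% names(decisions)) decisions$delay else decisions$delay_days
  kk <- seq(k_range[1L], k_range[2L], by = k_step)
  tt <- seq(t_range[1L], t_range[2L], by = t_step)
  y <- decisions$choice == "LL"
  # value difference per trial x k
  vd <- outer(seq_len(nrow(decisions)), kk, function(i, k)
    hyperbolic_value(decisions$ll_amount[i], dl[i], 10^k) - decisions$ss_amount[i])
  ll <- sapply(tt, function(t) {
    lp <- stats::plogis(10^t * vd, log.p = TRUE)
    lq <- stats::plogis(-10^t * vd, log.p = TRUE)
    colSums(lp * y + lq * (1 - y))
  })                                          # |kk| x |tt|
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  structure(list(
    k_mean = sum(rowSums(post) * kk), t_mean = sum(colSums(post) * tt),
    k_grid = kk, t_grid = tt, posterior = post,
    k_marginal = rowSums(post), t_marginal = colSums(post),
    n_trials = nrow(decisions)
  ), class = "kt_fit")
}

#' @export
print.kt_fit <- function(x, ...) {
  cat(sprintf("KT grid fit (%d trials): posterior mean k = %.3f, t = %.3f\n",
              x$n_trials, x$k_mean, x$t_mean))
  invisible(x)
}

#' @export
coef.kt_fit <- function(object, ...) c(k = object$k_mean, t = object$t_mean)
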