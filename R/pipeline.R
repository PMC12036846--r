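# End-to-end analysis pipeline: per-group, per-Self-block hierarchical fits
# feeding the signed-divergence influence table.

#' Others table of a synthetic cohort
#'
#' Expands the per-subject ground truth of [generate_cohort()] into the
#' exposure table consumed by [influence_table()]: one row per subject per
#' Other block with the discount rate of the other encountered there.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @return Data frame `subject_id`, `other_block` (2, 4), `k_other`.
#' @export
cohort_others <- function(truth) {
  imp_first <- truth$other_order == "impulsive_first"
  rbind(
    data.frame(subject_id = truth$subject_id, other_block = 2L,
               k_other = ifelse(imp_first, truth$k_other_impulsive, truth$k_other_patient)),
    data.frame(subject_id = truth$subject_id, other_block = 4L,
               k_other = ifelse(imp_first, truth$k_other_patient, truth$k_other_impulsive))
  )
}

#' Fit all Self blocks per group and compute the influence table
#'
#' Fits the hierarchical KU model independently to each Self block (1, 3, 5)
#' of each group in a trial log — priors reset per block, identical priors
#' across groups — and assembles the per-subject signed Kullback-Leibler
#' divergence table for both Other exposures.
#'
#' @param trials tidy trial log (see [validate_trial_log()] for the schema).
#' @param others data frame `subject_id`, `other_block`, `k_other` (for
#'   synthetic cohorts, [cohort_others()]).
#' @param chains,warmup,iter,seed MCMC configuration per block fit.
#' @param prior a [ku_prior()].
#' @return List with `influence` (the [influence_table()] result including
#'   group labels), `self_params` (per subject x Self block posterior means)
#'   and `fits` (named list of `ku_fit` objects, `"<group>/Self<block>"`).
#' @export
influence_pipeline <- function(trials, others, chains = 4L, warmup = 2000L,
                               iter = 2000L, seed = 1L, prior = ku_prior()) {
  groups <- unique(trials$group)
  fits <- list(); sp <- list()
  for (g in groups) {
    for (b in c(1L, 3L, 5L)) {
      dec <- trials[trials$group == g & trials$block == b, ]
      if (nrow(dec) == 0L) stop("no decisions for group ", g, ", block ", b)
      fit <- ku_fit(dec, chains = chains, warmup = warmup, iter = iter,
                    seed = derive_seed(seed, paste0("fit/", g, "/", b)),
                    prior = prior)
      fits[[paste0(g, "/Self", (b + 1L) %/% 2L)]] <- fit
      cf <- coef(fit)
      sp[[length(sp) + 1L]] <- data.frame(
        subject_id = rownames(cf), group = g, block = b,
        km = cf[, "km"], ku = cf[, "ku"], row.names = NULL)
    }
  }
  self_params <- do.call(rbind, sp)
  grp <- unique(self_params[, c("subject_id", "group")])
  infl <- influence_table(self_params, others, group = grp)
  list(influence = infl, self_params = self_params, fits = fits)
}
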