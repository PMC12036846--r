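# Synthetic study cohorts: group-structured generation of complete five-block
# delegated intertemporal choice sessions, with ground truth, so the whole
# pipeline is testable without any external data.

#' Specify a synthetic cohort
#'
#' @param groups data frame with one row per group and columns `label`,
#'   `n_subjects`, `km_mean`, `km_sd`, `ku_mean`, `ku_sd`,
#'   `susceptibility_impulsive`, `susceptibility_patient` (fractions in
#'   `[0, 1]` of the distance moved toward the other's discount rate after an
#'   exposure) and optionally `learner_noise` (log10 inverse temperature of
#'   the learner's own Other-block decisions; the default -0.2 calibrates
#'   learning accuracy to the observed 78-85% range).
#' @param seed master seed; every subject gets a derived substream.
#' @param t_sim log10 inverse temperature of the simulated others' choices.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, seed = 1L, t_sim = 1) {
  need <- c("label", "n_subjects", "km_mean", "km_sd", "ku_mean", "ku_sd",
            "susceptibility_impulsive", "susceptibility_patient")
  if (!all(need %in% names(groups)))
    stop("groups needs columns: ", paste(need, collapse = ", "))
  if (!"learner_noise" %in% names(groups)) groups$learner_noise <- -0.2
  stopifnot(all(groups$n_subjects >= 1), all(groups$km_sd > 0), all(groups$ku_sd > 0),
            all(groups$susceptibility_impulsive >= 0), all(groups$susceptibility_impulsive <= 1),
            all(groups$susceptibility_patient >= 0), all(groups$susceptibility_patient <= 1))
  structure(list(groups = groups, seed = as.integer(seed), t_sim = t_sim),
            class = "cohort_spec")
}

#' Default study-like cohort specification
#'
#' Three groups sized like the study cohort (71 healthy-control analogues, 33
#' medial-prefrontal lesion analogues, 17 lesion controls) with directional
#' effects matching the reported group differences: the mPFC analogue has a
#' higher mean temporal impulsivity (`km`) than the HC analogue and markedly
#' higher susceptibility to impulsive influence; the lesion-control analogue
#' has higher preference uncertainty (`ku`). Effect magnitudes are free
#' parameters of the generator, chosen once as plausible values on the log10
#' discount-rate scale.
#'
#' @param seed master seed.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L) {
  cohort_spec(data.frame(
    label = c("HC", "mPFC", "LC"),
    n_subjects = c(71L, 33L, 17L),
    km_mean = c(-3.0, -1.7, -1.8),
    km_sd = c(0.9, 0.9, 0.9),
    ku_mean = c(0.5, 0.6, 1.1),
    ku_sd = c(0.2, 0.2, 0.3),
    susceptibility_impulsive = c(0.25, 0.55, 0.15),
    susceptibility_patient = c(0.30, 0.35, 0.20),
    learner_noise = c(-0.2, -0.2, -0.2)
  ), seed = seed)
}

# Simulate one Self block: generative pairs from the schedule, adaptive pairs
# probed online from the designer's belief grid, KU choices throughout.
.sim_self_block <- function(sched_block, km, ku, pool) {
  belief <- belief_init()
  n <- nrow(sched_block)
  out <- sched_block[, c("block", "block_label", "trial", "design_tag", "agent")]
  out$ss_amount <- NA_integer_; out$ll_amount <- NA_integer_; out$delay_days <- NA_integer_
  out$choice <- NA_character_
  for (i in seq_len(n)) {
    if (sched_block$design_tag[i] == "adaptive") {
      pr <- adaptive_next_pair(belief, pool)
    } else {
      pr <- sched_block[i, c("ss_amount", "ll_amount", "delay")]
    }
    ch <- simulate_choice_ku(pr, km, ku)
    belief <- belief_update(belief, pr, ch)
    out$ss_amount[i] <- pr$ss_amount; out$ll_amount[i] <- pr$ll_amount
    out$delay_days[i] <- pr$delay; out$choice[i] <- ch
  }
  out$feedback_correct <- NA
  out
}

#' Generate a complete synthetic cohort
#'
#' For each subject: draw `(km, ku)` from the group distributions (truncated
#' to `km < 0`, `ku > 0`); simulate the Self1 block under the KU model with
#' the mixed generative/adaptive design; fit the KT grid model to Self1 to
#' obtain the baseline discount rate; construct the two others at baseline
#' k +/- 1; simulate both Other blocks with a belief-grid learner receiving
#' the others' softmax choices as feedback; after each exposure shift the
#' subject's `km` a group-specific fraction of the distance toward that
#' other's discount rate; simulate Self2 and Self3 with the shifted
#' preferences. The order of the two others alternates across subjects.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `cohort`: list with `trials` (tidy trial log, 250
#'   rows per subject) and `truth` (per-subject ground-truth parameters,
#'   simulated others, realized learning accuracies).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pool <- enumerate_pairs()
  trial_rows <- list(); truth_rows <- list()
  subj_no <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    grp <- spec$groups[g, ]
    for (s in seq_len(grp$n_subjects)) {
      subj_no <- subj_no + 1L
      sid <- sprintf("%s_%03d", grp$label, s)
      sseed <- derive_seed(spec$seed, paste0("subject/", sid))
      res <- with_seed(sseed, {
        km0 <- rtruncnorm(1, grp$km_mean, grp$km_sd, 0, "upper")
        ku0 <- rtruncnorm(1, grp$ku_mean, grp$ku_sd, 0, "lower")
        order <- if (subj_no %% 2L == 1L) "impulsive_first" else "patient_first"
        sched <- build_schedule(order, seed = sseed)

        self1 <- .sim_self_block(sched[sched$block == 1L, ], km0, ku0, pool)
        ktf <- kt_fit(data.frame(self1, delay = self1$delay_days))
        k_base <- ktf$k_mean
        others <- make_others(k_base, t_sim = spec$t_sim)
        # exposure order: row index of `others` per Other block
        ord_idx <- if (order == "impulsive_first") c(1L, 2L) else c(2L, 1L)

        km_cur <- km0
        km_after <- c(NA_real_, NA_real_); acc <- c(NA_real_, NA_real_)
        blocks <- list(self1)
        for (e in 1:2) {
          ob <- c(2L, 4L)[e]
          other <- others[ord_idx[e], ]
          sb <- sched[sched$block == ob, ]
          pairs <- sb[, c("ss_amount", "ll_amount", "delay")]
          lr <- simulate_other_block(other, pairs, belief_init(mean = k_base, sd = 1),
                                     learner_t = grp$learner_noise)
          obk <- sb[, c("block", "block_label", "trial", "design_tag", "agent")]
          obk$ss_amount <- pairs$ss_amount; obk$ll_amount <- pairs$ll_amount
          obk$delay_days <- pairs$delay
          obk$choice <- lr$decisions$choice
          obk$feedback_correct <- lr$decisions$feedback_correct
          acc[e] <- lr$accuracy
          blocks[[length(blocks) + 1L]] <- obk
          # social influence: fractional shift of km toward this other's k
          susc <- if (other$design_label == "more_impulsive")
            grp$susceptibility_impulsive else grp$susceptibility_patient
          km_cur <- km_cur + susc * (other$k_other - km_cur)
          km_after[e] <- km_cur
          blocks[[length(blocks) + 1L]] <-
            .sim_self_block(sched[sched$block == ob + 1L, ], km_cur, ku0, pool)
        }
        trials <- do.call(rbind, blocks)
        trials <- trials[order(trials$block, trials$trial), ]
        list(
          trials = data.frame(subject_id = sid, group = grp$label, trials,
                              rng_stream_id = sseed, row.names = NULL),
          truth = data.frame(
            subject_id = sid, group = grp$label, km = km0, ku = ku0,
            k_base_kt = k_base,
            k_other_impulsive = others$k_other[1L],
            k_other_patient = others$k_other[2L],
            other_order = order,
            susceptibility_impulsive = grp$susceptibility_impulsive,
            susceptibility_patient = grp$susceptibility_patient,
            km_self2 = km_after[1L], km_self3 = km_after[2L],
            accuracy_other1 = acc[1L], accuracy_other2 = acc[2L],
            learner_noise = grp$learner_noise
          )
        )
      })
      trial_rows[[subj_no]] <- res$trials
      truth_rows[[subj_no]] <- res$truth
    }
  }
  structure(list(trials = do.call(rbind, trial_rows),
                 truth = do.call(rbind, truth_rows), spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d trials\n",
              nrow(x$truth), nrow(x$trials)))
  print(table(x$truth$group))
  invisible(x)
}
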