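# Quantifying preference shifts after social exposure with signed base-10
# Kullback-Leibler divergence between KU discounting distributions.

#' Base-10 Kullback-Leibler divergence between two normal distributions
#'
#' `D_KL(P || Q) = integral p(x) log10(p(x)/q(x)) dx` for
#' `P = N(p_mean, p_sd^2)`, `Q = N(q_mean, q_sd^2)`, in closed form:
#' `[ln(q_sd/p_sd) + (p_sd^2 + (p_mean - q_mean)^2) / (2 q_sd^2) - 1/2] / ln(10)`.
#'
#' @param p_mean,p_sd parameters of P (the distribution whose expectation is
#'   taken).
#' @param q_mean,q_sd parameters of Q (the reference distribution).
#' @return Non-negative divergence in base-10 units.
#' @examples
#' kl_normal_base10(0, 1, 1, 1)  # 0.5 / log(10)
#' @export
kl_normal_base10 <- function(p_mean, p_sd, q_mean, q_sd) {
  if (any(p_sd <= 0) || any(q_sd <= 0)) stop("standard deviations must be > 0")
  (log(q_sd / p_sd) + (p_sd^2 + (p_mean - q_mean)^2) / (2 * q_sd^2) - 0.5) / log(10)
}

#' Signed Kullback-Leibler divergence for one social exposure
#'
#' Measures how far a subject's discounting distribution moved after learning
#' an other's preference, signed by direction: the magnitude is
#' `D_KL(after || baseline)` between the post-exposure and baseline (Self1) KU
#' distributions `N(km, ku^2)`, and the sign is positive when the ratio
#' `(km_other - km_self1) / (km_after - km_self1)` is positive, i.e. the shift
#' is toward the other's preference, negative when away. When `km` did not
#' move (`|km_after - km_self1| < eps`) the sign is 0 with a warning.
#'
#' @param km_self1,ku_self1 baseline KU parameters (first Self block).
#' @param km_after,ku_after KU parameters of the post-exposure Self block.
#' @param km_other the other's log10 discount rate.
#' @param other_block index of the Other block (2 or 4), carried through.
#' @param eps tolerance below which the km shift counts as zero.
#' @return One-row data frame: `d_kl`, `sign`, `signed_d_kl`, `other_block`,
#'   `other_label`, and the input parameters.
#' @export
signed_dkl <- function(km_self1, ku_self1, km_after, ku_after, km_other,
                       other_block = NA_integer_, eps = 1e-8) {
  d <- kl_normal_base10(km_after, ku_after, km_self1, ku_self1)
  delta <- km_after - km_self1
  if (abs(delta) < eps) {
    warning("km unchanged between blocks; signed divergence set to 0")
    sgn <- 0
  } else {
    sgn <- sign((km_other - km_self1) / delta)
  }
  data.frame(
    d_kl = d, sign = sgn, signed_d_kl = sgn * d,
    other_block = other_block,
    other_label = classify_other(km_other, km_self1),
    km_self1 = km_self1, ku_self1 = ku_self1,
    km_after = km_after, ku_after = ku_after, km_other = km_other
  )
}

#' Per-subject table of signed divergences across both exposures
#'
#' Combines per-block posterior summaries with the others' discount rates
#' into the analysis-ready table: one row per subject per Other exposure
#' (block 2 compared as Self2 vs Self1, block 4 as Self3 vs Self1). Others
#' are labeled by the sign of `km_other - km_self1` (the fitted baseline), so
#' a subject's two others can share a label; such subjects are flagged and
#' contribute rows only for that label, mirroring the data-availability rule
#' for adaptive designs.
#'
#' @param self_params data frame with columns `subject_id`, `block`
#'   (1, 3, 5), `km`, `ku` — e.g. stacked [coef.ku_fit()] results of the
#'   three Self-block fits.
#' @param others data frame with columns `subject_id`, `other_block` (2, 4),
#'   `k_other`.
#' @param group optional data frame `subject_id`, `group` merged into the
#'   output.
#' @return Data frame: `subject_id`, `group` (if given), `other_block`,
#'   `other_label`, `d_kl`, `sign`, `signed_d_kl`, the km/ku columns, and
#'   `both_same_label`.
#' @export
influence_table <- function(self_params, others, group = NULL) {
  need <- c("subject_id", "block", "km", "ku")
  if (!all(need %in% names(self_params))) stop("self_params needs columns: ",
                                               paste(need, collapse = ", "))
  if (!all(c("subject_id", "other_block", "k_other") %in% names(others)))
    stop("others needs columns: subject_id, other_block, k_other")
  after_block <- c(`2` = 3L, `4` = 5L)
  rows <- lapply(unique(as.character(others$subject_id)), function(sj) {
    sp <- self_params[as.character(self_params$subject_id) == sj, ]
    base <- sp[sp$block == 1L, ]
    if (nrow(base) != 1L) stop("missing or duplicated Self1 baseline fit for subject ", sj)
    ot <- others[as.character(others$subject_id) == sj, ]
    sub <- lapply(seq_len(nrow(ot)), function(r) {
      ab <- after_block[as.character(ot$other_block[r])]
      af <- sp[sp$block == ab, ]
      if (nrow(af) != 1L) stop("missing post-exposure fit (block ", ab, ") for subject ", sj)
      out <- signed_dkl(base$km, base$ku, af$km, af$ku, ot$k_other[r],
                        other_block = ot$other_block[r])
      cbind(subject_id = sj, out)
    })
    sub <- do.call(rbind, sub)
    sub$both_same_label <- length(unique(sub$other_label)) == 1L && nrow(sub) > 1L
    sub
  })
  out <- do.call(rbind, rows)
  if (!is.null(group)) out <- merge(group, out, by = "subject_id")
  rownames(out) <- NULL
  out
}
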