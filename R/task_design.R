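# Choice-pair design: exhaustive pair enumeration, generative targeting of
# evenly spaced indifference points, and the adaptive Bayesian designer that
# tracks a grid posterior over k and probes its current posterior mean.

.tdc_cache <- new.env(parent = emptyenv())

#' Enumerate every admissible choice pair
#'
#' All pairs with integer amounts `1 <= ss < ll <= 20` pounds and integer
#' delays 1-90 days: `choose(20, 2) * 90 = 17100` pairs, each carrying its
#' indifference log10 discount rate. The result is deterministic, ordered by
#' `ss_amount`, `ll_amount`, `delay`, and cached after the first call.
#'
#' @return Data frame with columns `ss_amount`, `ll_amount`, `delay`,
#'   `indiff_logk` (17,100 rows).
#' @export
enumerate_pairs <- function() {
  if (!is.null(.tdc_cache$pairs)) return(.tdc_cache$pairs)
  cmb <- utils::combn(1:20, 2)
  ss <- rep(cmb[1L, ], each = 90L)
  ll <- rep(cmb[2L, ], each = 90L)
  d <- rep.int(1:90, ncol(cmb))
  pairs <- data.frame(
    ss_amount = as.integer(ss), ll_amount = as.integer(ll), delay = as.integer(d),
    indiff_logk = indifference_logk(ss, ll, d)
  )
  pairs <- pairs[order(pairs$ss_amount, pairs$ll_amount, pairs$delay), ]
  rownames(pairs) <- NULL
  .tdc_cache$pairs <- pairs
  # pool sorted by (indiff_logk, delay, ll_amount): within equal indifference
  # the first row in sorted order is the deterministic tie-break winner
  .tdc_cache$pairs_sorted <-
    pairs[order(pairs$indiff_logk, pairs$delay, pairs$ll_amount), ]
  pairs
}

# Lookup structure for nearest-indifference search: pool sorted by
# (indiff_logk, delay, ll_amount), unique indifference values, and the first
# row per value (= deterministic tie-break winner within a value). Cached for
# the default pool.
.nearest_lookup <- function(pool) {
  if (identical(pool, .tdc_cache$pairs)) {
    if (is.null(.tdc_cache$lookup)) {
      sp <- .tdc_cache$pairs_sorted
      u <- unique(sp$indiff_logk)
      .tdc_cache$lookup <- list(sp = sp, u = u, first = match(u, sp$indiff_logk))
    }
    return(.tdc_cache$lookup)
  }
  sp <- pool[order(pool$indiff_logk, pool$delay, pool$ll_amount), ]
  u <- unique(sp$indiff_logk)
  list(sp = sp, u = u, first = match(u, sp$indiff_logk))
}

#' Nearest choice pair(s) to target indifference points
#'
#' For each target log10 discount rate, returns the pool pair whose
#' indifference point is closest in absolute log10 distance. Ties are broken
#' deterministically: smallest delay, then smallest larger-later amount.
#'
#' @param targets numeric vector of target log10 discount rates.
#' @param pool data frame of candidate pairs as from [enumerate_pairs()].
#' @return Data frame with one row per target (columns of `pool` plus
#'   `target`).
#' @export
nearest_pairs <- function(targets, pool = enumerate_pairs()) {
  if (is.null(pool) || nrow(pool) == 0L) stop("empty pair pool")
  lk <- .nearest_lookup(pool)
  j <- findInterval(targets, lk$u)
  pick <- vapply(seq_along(targets), function(i) {
    lo <- max(j[i], 1L)
    hi <- min(j[i] + 1L, length(lk$u))
    cand <- unique(c(lo, hi))
    gap <- abs(lk$u[cand] - targets[i])
    win <- cand[gap <= min(gap) + 1e-15]
    rows <- lk$first[win]
    if (length(rows) > 1L)
      rows <- rows[order(lk$sp$delay[rows], lk$sp$ll_amount[rows])]
    rows[1L]
  }, integer(1L))
  out <- lk$sp[pick, , drop = FALSE]
  out$target <- targets
  rownames(out) <- NULL
  out
}

#' Evenly spaced target log10 discount rates
#'
#' @param n number of targets (>= 2).
#' @param lo,hi range endpoints on the log10 discount-rate scale.
#' @return Numeric vector of length `n` from `lo` to `hi` with constant step.
#' @export
make_uniform_targets <- function(n, lo = -4, hi = 0) {
  if (n < 2) stop("n must be >= 2")
  seq(lo, hi, length.out = n)
}

#' Generatively designed choice pairs
#'
#' Implements the generative design method: each target indifference point
#' (typically evenly spaced over `[-4, 0]`) is matched by the admissible pair
#' whose indifference log10 discount rate is closest.
#'
#' @param k_targets numeric vector of target log10 discount rates in `[-4, 0]`.
#' @param pool candidate pool, by default the full enumeration.
#' @return Data frame of pairs, one per target.
#' @export
generative_pairs <- function(k_targets, pool = enumerate_pairs()) {
  nearest_pairs(k_targets, pool)
}

#' Initialize the adaptive designer's belief grid over k
#'
#' Discretized prior over the participant's log10 discount rate, used both by
#' the adaptive trial designer and by the simulated Other-block learner. The
#' default prior is `N(-2, 1)` with the softmax log10 inverse temperature of
#' the update likelihood fixed at 0.3, on an 801-point grid spanning
#' `[-6, 2]`.
#'
#' @param mean,sd prior mean and standard deviation on the log10 k scale.
#' @param t_fixed log10 inverse temperature used in the update likelihood.
#' @param grid support points (strictly increasing).
#' @return Object of class `belief_grid`: list with `grid`, `mass`, `t_fixed`.
#' @export
belief_init <- function(mean = -2, sd = 1, t_fixed = 0.3,
                        grid = seq(-6, 2, length.out = 801L)) {
  if (sd <= 0) stop("sd must be > 0")
  mass <- stats::dnorm(grid, mean, sd)
  structure(list(grid = grid, mass = mass / sum(mass), t_fixed = t_fixed),
            class = "belief_grid")
}

#' Posterior mean of a belief grid
#' @param belief a `belief_grid`.
#' @return Expected log10 discount rate under the current belief.
#' @export
belief_mean <- function(belief) sum(belief$grid * belief$mass)

#' Bayesian update of the belief grid after one observed choice
#'
#' Multiplies the current mass by the softmax (KT) likelihood of the observed
#' choice at every grid value of k (inverse temperature `10^t_fixed`) and
#' renormalizes. An LL choice moves mass toward more patient (lower) k, an SS
#' choice toward more impulsive (higher) k.
#'
#' @param belief a `belief_grid`.
#' @param pair one-row data frame with `ss_amount`, `ll_amount`, `delay`.
#' @param choice `"LL"` or `"SS"`.
#' @return Updated `belief_grid`.
#' @export
belief_update <- function(belief, pair, choice) {
  stopifnot(inherits(belief, "belief_grid"), choice %in% c("SS", "LL"))
  v_ll <- hyperbolic_value(pair$ll_amount, pair$delay, 10^belief$grid)
  p_ll <- kt_choice_prob(v_ll, pair$ss_amount, belief$t_fixed)
  lik <- if (choice == "LL") p_ll else 1 - p_ll
  m <- belief$mass * lik
  tot <- sum(m)
  if (!is.finite(tot) || tot <= 0) stop("belief update produced zero total mass")
  belief$mass <- m / tot
  belief
}

#' Adaptive choice of the next pair
#'
#' Probes the current estimate of the participant's indifference point: the
#' pool pair whose indifference log10 discount rate is nearest the posterior
#' mean of the belief grid. Deterministic given the belief (ties broken by
#' smallest delay, then smallest larger-later amount).
#'
#' @param belief a `belief_grid`.
#' @param pool candidate pool.
#' @return One-row data frame (the chosen pair).
#' @export
adaptive_next_pair <- function(belief, pool = enumerate_pairs()) {
  nearest_pairs(belief_mean(belief), pool)[, c("ss_amount", "ll_amount", "delay", "indiff_logk")]
}

#' Build a five-block session schedule
#'
#' The session comprises five blocks of 50 trials (Self1, Other1, Self2,
#' Other2, Self3; 250 trials in total) with a self-paced break after trial 25
#' of each block. Self blocks mix 25 generatively designed trials (targets
#' evenly spaced over `[-4, 0]`) with 25 adaptive trials in seeded-random
#' order; Other blocks use 50 generative targets in seeded-random order. The
#' order of the two others' preferences is counterbalanced via `other_order`.
#'
#' @param other_order `"impulsive_first"` or `"patient_first"`.
#' @param seed integer seed controlling the within-block interleaving.
#' @return Data frame of 250 rows: `block`, `block_label`, `trial`,
#'   `design_tag`, `agent`, `break_after`, `target`, and pair columns
#'   (`ss_amount`, `ll_amount`, `delay`, `indiff_logk`) filled for generative
#'   slots, `NA` for adaptive slots (chosen online from responses).
#' @export
build_schedule <- function(other_order = c("impulsive_first", "patient_first"),
                           seed = 1L) {
  other_order <- match.arg(other_order)
  labels <- c("Self1", "Other1", "Self2", "Other2", "Self3")
  agents <- if (other_order == "impulsive_first")
    c("self", "other_impulsive", "self", "other_patient", "self")
  else c("self", "other_patient", "self", "other_impulsive", "self")
  self_targets <- make_uniform_targets(25L)
  other_targets <- make_uniform_targets(50L)
  with_seed(derive_seed(seed, "schedule"), {
    rows <- lapply(seq_along(labels), function(b) {
      is_self <- b %in% c(1L, 3L, 5L)
      if (is_self) {
        tags <- sample(rep(c("generative", "adaptive"), each = 25L))
        tgt <- rep(NA_real_, 50L)
        tgt[tags == "generative"] <- sample(self_targets)
      } else {
        tags <- rep("generative", 50L)
        tgt <- sample(other_targets)
      }
      out <- data.frame(
        block = b, block_label = labels[b], trial = 1:50, design_tag = tags,
        agent = agents[b], break_after = seq_len(50L) == 25L, target = tgt
      )
      gen <- !is.na(tgt)
      pr <- generative_pairs(tgt[gen])
      out$ss_amount <- NA_integer_; out$ll_amount <- NA_integer_
      out$delay <- NA_integer_; out$indiff_logk <- NA_real_
      out$ss_amount[gen] <- pr$ss_amount; out$ll_amount[gen] <- pr$ll_amount
      out$delay[gen] <- pr$delay; out$indiff_logk[gen] <- pr$indiff_logk
      out
    })
    do.call(rbind, rows)
  })
}
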