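# Valuation and choice rules for smaller-sooner (SS) vs larger-later (LL)
# intertemporal choices. Amounts are integer pounds in [1, 20]; delays integer
# days, SS always delivered today (delay 0), LL delayed by 1-90 days. All log
# discount rates are base-10: k = log10(K), t = log10(T).

#' Hyperbolic subjective value
#'
#' Discounted value of a delayed reward under hyperbolic discounting,
#' `V = M / (1 + K * D)`, with `M` the objective amount in pounds, `D` the
#' delay in days and `K >= 0` the per-day discount rate. A reward delivered
#' today (`delay = 0`) is worth its face value.
#'
#' @param amount reward magnitude in pounds.
#' @param delay delay in days.
#' @param K hyperbolic discount rate per day (linear scale, not log10).
#' @return Subjective value in pounds, same length as the longest argument.
#' @examples
#' hyperbolic_value(20, 90, 0.01)  # 20 / 1.9
#' @export
hyperbolic_value <- function(amount, delay, K) {
  if (any(!is.finite(K)) || any(K < 0)) stop("discount rate K must be finite and >= 0")
  if (any(delay < 0)) stop("delay must be >= 0")
  if (any(amount <= 0)) stop("amount must be positive")
  amount / (1 + K * delay)
}

#' Softmax (KT) probability of choosing the larger-later option
#'
#' Logistic choice rule `P(LL) = 1 / (1 + exp(-T * (v_ll - v_ss)))` with
#' inverse temperature `T = 10^t`. Computed via [stats::plogis()] so extreme
#' temperatures do not underflow.
#'
#' @param v_ll subjective value of the larger-later option (pounds).
#' @param v_ss subjective value of the smaller-sooner option (pounds).
#' @param t log10 inverse temperature.
#' @return Probability of choosing LL, in (0, 1).
#' @export
kt_choice_prob <- function(v_ll, v_ss, t) {
  if (any(!is.finite(t))) stop("t must be finite")
  stats::plogis(10^t * (v_ll - v_ss))
}

#' Log10 discount rate at indifference for a choice pair
#'
#' The log10 discount rate at which the two options of a pair are valued
#' equally: `log10((ll_amount/ss_amount - 1) / delay)`. An agent with a lower
#' (more patient) log discount rate prefers the delayed option.
#'
#' @param ss_amount smaller-sooner amount in pounds (delivered today).
#' @param ll_amount larger-later amount in pounds; must exceed `ss_amount`.
#' @param delay delay of the larger-later option in days (>= 1).
#' @return log10 discount rate at indifference (dimensionless).
#' @examples
#' indifference_logk(10, 20, 10)  # -1
#' @export
indifference_logk <- function(ss_amount, ll_amount, delay) {
  if (any(ll_amount <= ss_amount))
    stop("indifference undefined: ll_amount must exceed ss_amount")
  if (any(delay < 1)) stop("delay of the delayed option must be >= 1")
  log10((ll_amount / ss_amount - 1) / delay)
}

#' Preference-uncertainty (KU) probability of choosing the larger-later option
#'
#' Under the KU model the agent's log discount rate is drawn each trial from
#' `N(km, ku^2)`; the delayed option is chosen exactly when the draw falls
#' below the pair's indifference log discount rate, so
#' `P(LL) = Phi(indifference_logk; km, ku^2)`.
#'
#' @inheritParams indifference_logk
#' @param km mean of the agent's log10 discount-rate distribution (< 0).
#' @param ku standard deviation of that distribution (> 0).
#' @return Probability of choosing LL, in (0, 1).
#' @examples
#' ku_choice_prob(10, 20, 10, km = -2, ku = 1)  # pnorm(1) = 0.8413
#' @export
ku_choice_prob <- function(ss_amount, ll_amount, delay, km, ku) {
  if (any(ku <= 0)) stop("ku must be > 0")
  x <- indifference_logk(ss_amount, ll_amount, delay)
  stats::pnorm(x, mean = km, sd = ku)
}

#' Construct a validated choice pair
#'
#' @inheritParams indifference_logk
#' @return One-row data frame with columns `ss_amount`, `ll_amount`, `delay`
#'   and the derived `indiff_logk`.
#' @export
choice_pair <- function(ss_amount, ll_amount, delay) {
  stopifnot(
    length(ss_amount) == length(ll_amount), length(ll_amount) == length(delay),
    all(ss_amount == round(ss_amount)), all(ll_amount == round(ll_amount)),
    all(delay == round(delay)),
    all(ss_amount >= 1), all(ll_amount <= 20), all(delay >= 1), all(delay <= 90)
  )
  data.frame(
    ss_amount = as.integer(ss_amount), ll_amount = as.integer(ll_amount),
    delay = as.integer(delay),
    indiff_logk = indifference_logk(ss_amount, ll_amount, delay)
  )
}
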