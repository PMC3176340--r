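# Sequencing-error calibration of the detection threshold.
#
# At an error-free site the C reads are (correct, b1, b2, b3) ~
# Multinomial(C; 1 - e, e/3, e/3, e/3): an erred base becomes each of the
# three other bases with probability e/3. A false variant call happens when
# ANY wrong base reaches the threshold, so the mis-detection statistic is
# M = max(b1, b2, b3); the three counts are negatively dependent through
# the shared total, which a per-base Poisson model ignores.

assert_error_rate <- function(e) {
  if (length(e) != 1L || !is.numeric(e) || is.na(e) || e < 0 || e >= 1)
    pd_stop("error rate e must be in [0, 1)")
  as.numeric(e)
}

#' Mis-detection probability under the multinomial error model
#'
#' Exact `P(max(b1, b2, b3) >= T)` by inclusion-exclusion:
#' `3 P(b1 >= T) - 3 P(b1 >= T, b2 >= T) + P(b1 >= T, b2 >= T, b3 >= T)`.
#' The marginal count is `Binomial(C, e/3)`; the joint terms are nested
#' sums over conditional binomials (given `b1 = x`, `b2` is
#' `Binomial(C - x, (e/3) / (1 - e/3))`, and so on).
#'
#' @param C Coverage depth.
#' @param e Overall per-base sequencing error rate, in `[0, 1)`.
#' @param T Detection threshold.
#' @return Probability that sequencing errors alone produce at least `T`
#'   reads of some single incorrect base.
#' @examples
#' misdetection_prob_multinomial(C = 50, e = 0.01, T = 3)  # about 0.002
#' @export
misdetection_prob_multinomial <- function(C, e, T) {
  C <- assert_count(C, "C")
  T <- assert_count(T, "T")
  e <- assert_error_rate(e)
  if (T > C) pd_stop("threshold T must satisfy 1 <= T <= C")
  if (e == 0) return(0)
  q <- e / 3
  P1 <- stats::pbinom(T - 1L, C, q, lower.tail = FALSE)
  x <- T:C
  q2 <- q / (1 - q)
  P12 <- sum(stats::dbinom(x, C, q) *
               stats::pbinom(T - 1L, C - x, q2, lower.tail = FALSE))
  q3 <- q / (1 - 2 * q)
  P123 <- 0
  for (xi in x) {
    y_max <- C - xi
    if (y_max < T) break
    y <- T:y_max
    P123 <- P123 + stats::dbinom(xi, C, q) *
      sum(stats::dbinom(y, C - xi, q2) *
            stats::pbinom(T - 1L, C - xi - y, q3, lower.tail = FALSE))
  }
  min(max(3 * P1 - 3 * P12 + P123, 0), 1)
}

#' Mis-detection probability under the independent-error Poisson model
#'
#' Comparator that models the error count at a site as `Poisson(C * e)` and
#' returns its upper tail at `T`. It pools all three wrong bases into one
#' count and ignores the dependency among them, so it overstates the
#' mis-detection probability of the maximum-count statistic; it is exposed
#' for comparison only and never used for design.
#'
#' @inheritParams misdetection_prob_multinomial
#' @return `P(Poisson(C * e) >= T)`.
#' @export
misdetection_prob_poisson <- function(C, e, T) {
  C <- assert_count(C, "C")
  T <- assert_count(T, "T")
  e <- assert_error_rate(e)
  stats::ppois(T - 1L, C * e, lower.tail = FALSE)
}

#' Smallest threshold controlling the mis-detection probability
#'
#' @inheritParams misdetection_prob_multinomial
#' @param max_fpr Maximum tolerated mis-detection probability, in `(0, 1)`.
#' @return Smallest integer `T` with
#'   `misdetection_prob_multinomial(C, e, T) <= max_fpr`; falls back to `C`
#'   with a warning if no threshold satisfies the bound.
#' @examples
#' min_threshold_for_fpr(C = 50, e = 0.01, max_fpr = 0.002)  # 3
#' @export
min_threshold_for_fpr <- function(C, e, max_fpr) {
  C <- assert_count(C, "C")
  e <- assert_error_rate(e)
  max_fpr <- assert_prob(max_fpr, "max_fpr", open_lo = TRUE)
  for (T in 1:C) {
    if (misdetection_prob_multinomial(C, e, T) <= max_fpr) return(T)
  }
  warning("no threshold up to C controls the mis-detection probability; returning C")
  C
}

#' Randomized threshold with exact mis-detection probability
#'
#' On the integer statistic `M = max(b1, b2, b3)` no deterministic
#' threshold generally achieves a prescribed false-call rate exactly. The
#' standard randomized construction does: with survival function
#' `S(t) = P(M >= t)`, find the threshold `T` with
#' `S(T) <= target < S(T - 1)` and call with probability 1 when `M >= T`
#' and with probability `gamma = (target - S(T)) / (S(T - 1) - S(T))` when
#' `M = T - 1`. The achieved size is then exactly the target.
#'
#' @inheritParams misdetection_prob_multinomial
#' @param target_fpr Desired exact mis-detection probability, in `(0, 1)`.
#' @return List with `T` (integer threshold), `gamma` (randomization
#'   probability at count `T - 1`), and `achieved_size` (analytic size of
#'   the randomized rule, equal to `target_fpr` up to machine precision).
#' @examples
#' randomized_threshold(C = 50, e = 0.01, target_fpr = 0.002)
#' @export
randomized_threshold <- function(C, e, target_fpr) {
  C <- assert_count(C, "C")
  e <- assert_error_rate(e)
  target_fpr <- assert_prob(target_fpr, "target_fpr", open_lo = TRUE, open_hi = TRUE)
  if (e == 0)
    pd_stop("e = 0 gives a degenerate (all-zero) error-count distribution; ",
            "no randomized threshold exists", class = "pooldesign_degenerate_error")
  surv <- function(t) {
    if (t <= 0) 1 else if (t > C) 0 else misdetection_prob_multinomial(C, e, t)
  }
  T <- 1L
  while (surv(T) > target_fpr) T <- T + 1L
  s_T <- surv(T); s_Tm1 <- surv(T - 1L)
  gamma <- if (s_Tm1 > s_T) (target_fpr - s_T) / (s_Tm1 - s_T) else 0
  list(T = T, gamma = gamma, achieved_size = s_T + gamma * (s_Tm1 - s_T))
}

#' Table of mis-detection probabilities over coverages and thresholds
#'
#' @param C_list Coverage depths (rows).
#' @param e Per-base sequencing error rate.
#' @param T_list Thresholds (columns).
#' @return Numeric matrix with `misdetection_prob_multinomial(C, e, T)` in
#'   each cell, dimnames `C_list` x `T_list`.
#' @examples
#' threshold_table(C_list = c(20, 30, 40, 50), e = 0.01, T_list = 2:5)
#' @export
threshold_table <- function(C_list, e, T_list) {
  if (length(C_list) < 1L || length(T_list) < 1L)
    pd_stop("C_list and T_list must be nonempty")
  out <- outer(C_list, T_list,
               Vectorize(function(C, T) misdetection_prob_multinomial(C, e, T)))
  dimnames(out) <- list(C = C_list, T = T_list)
  out
}
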