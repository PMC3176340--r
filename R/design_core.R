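#' Distribution of the variant-carrier count in a pool
#'
#' A pool of `k` diploid individuals holds `2k` chromosomes. When every
#' chromosome independently carries a variant of minor allele frequency `p`,
#' the number `N` of carrier chromosomes in the pool is `Binomial(2k, p)`.
#'
#' @param k Number of individuals in the pool (positive integer).
#' @param p Minor allele frequency, in `[0, 0.5]`.
#' @return Numeric vector of length `2k + 1` with `P(N = n)` for
#'   `n = 0, ..., 2k`; entries sum to 1.
#' @examples
#' sum(variant_count_pmf(30, 0.01)[1:3])  # P(N <= 2) for k = 30, p = 0.01
#' @export
variant_count_pmf <- function(k, p) {
  k <- assert_count(k, "k")
  p <- assert_maf(p)
  stats::dbinom(0:(2L * k), size = 2L * k, prob = p)
}

#' Detection probability given the number of carrier chromosomes
#'
#' With equal individual contributions, each of the `C` reads covering the
#' site originates from a carrier chromosome with probability `n / (2k)`.
#' The variant is called when at least `T` reads carry it, so the
#' conditional detection probability is the upper tail of
#' `Binomial(C, n / (2k))` at `T`.
#'
#' @param n Number of carrier chromosomes, `0 <= n <= 2k`.
#' @inheritParams variant_count_pmf
#' @param C Coverage depth at the site (reads per lane).
#' @param T Detection threshold (minimum variant reads to call).
#' @return `P(X >= T)` with `X ~ Binomial(C, n / (2k))`.
#' @examples
#' conditional_detection_equal(1, k = 3, C = 20, T = 3)   # ~0.67
#' conditional_detection_equal(1, k = 30, C = 20, T = 3)  # ~0.004
#' @export
conditional_detection_equal <- function(n, k, C, T) {
  spec <- assert_pool_spec(k, C, T)
  n <- assert_count(n, "n", min = 0L)
  if (n > 2L * spec$k)
    pd_stop("n must be at most 2k = ", 2L * spec$k, " (got ", n, ")")
  stats::pbinom(spec$T - 1L, size = spec$C, prob = n / (2 * spec$k),
                lower.tail = FALSE)
}

#' Per-lane detection probability under equal contributions
#'
#' Mixes the carrier-count distribution with the conditional read-level
#' detection probability:
#' `P(detect) = sum_n P(N = n) * P(Binomial(C, n/(2k)) >= T)`.
#' This combines the sampling variation (whether carriers enter the pool at
#' all) with the read sampling at the sequenced site.
#'
#' @inheritParams conditional_detection_equal
#' @return Detection probability in `[0, 1]`.
#' @examples
#' detection_prob_equal(k = 3, p = 0.005, C = 20, T = 3)  # 0.0200
#' @export
detection_prob_equal <- function(k, p, C, T) {
  spec <- assert_pool_spec(k, C, T)
  p <- assert_maf(p)
  n <- 0:(2L * spec$k)
  sum(stats::dbinom(n, 2L * spec$k, p) *
        stats::pbinom(spec$T - 1L, spec$C, n / (2 * spec$k), lower.tail = FALSE))
}

#' Single-carrier approximation of the detection probability
#'
#' For rare variants most detectable pools carry the variant on exactly one
#' chromosome, so the full mixture is well approximated by its `n = 1` term,
#' `P(N = 1) * P(Binomial(C, 1/(2k)) >= T)`. Always a lower bound on
#' [detection_prob_equal()].
#'
#' @inheritParams detection_prob_equal
#' @return The `n = 1` term of the detection-probability mixture.
#' @export
rare_variant_approx <- function(k, p, C, T) {
  spec <- assert_pool_spec(k, C, T)
  p <- assert_maf(p)
  stats::dbinom(1L, 2L * spec$k, p) *
    stats::pbinom(spec$T - 1L, spec$C, 1 / (2 * spec$k), lower.tail = FALSE)
}

#' Power of a multi-lane design
#'
#' `L` lanes sequence `L` independent pools, so the variant is detected in
#' at least one lane with probability `1 - (1 - P)^L` where `P` is the
#' per-lane detection probability.
#'
#' @param p_single Per-lane detection probability.
#' @param L Number of independent lanes.
#' @return Overall detection power.
#' @export
power_with_lanes <- function(p_single, L) {
  p_single <- assert_prob(p_single, "p_single")
  L <- assert_count(L, "L")
  1 - (1 - p_single)^L
}

#' Minimum number of lanes for a target power
#'
#' Smallest integer `L` with `1 - (1 - P)^L >= target`. Computed from the
#' ceiling of `log(1 - target) / log(1 - P)` and then corrected at the
#' boundary: the candidate is decremented while the smaller lane count still
#' meets the target within 1e-12, so floating-point rounding can never
#' inflate the printed lane count by one.
#'
#' @inheritParams power_with_lanes
#' @param target Target power, in `(0, 1)`; default 0.8.
#' @return Integer lane count.
#' @examples
#' lanes_for_power(0.0200, target = 0.8)  # 80
#' @export
lanes_for_power <- function(p_single, target = 0.8) {
  p_single <- assert_prob(p_single, "p_single")
  target <- assert_prob(target, "target", open_lo = TRUE, open_hi = TRUE)
  if (p_single == 0)
    pd_stop("target power is unreachable with a per-lane detection probability of 0")
  if (p_single == 1) return(1L)
  L <- as.integer(ceiling(log1p(-target) / log1p(-p_single)))
  L <- max(L, 1L)
  while (L > 1L && power_with_lanes(p_single, L - 1L) >= target - 1e-12)
    L <- L - 1L
  while (power_with_lanes(p_single, L) < target - 1e-12)
    L <- L + 1L
  L
}

#' Optimal pool size under equal contributions
#'
#' The detection probability first rises with the pool size (more chromosomes
#' that may carry the variant) and then falls (each carrier chromosome
#' contributes a smaller fraction of reads, so the threshold bites), giving
#' an interior optimum. This searches `k` over an integer range; ties are
#' broken towards the smallest `k`, the cheaper design.
#'
#' @inheritParams detection_prob_equal
#' @param k_min,k_max Inclusive search range for the pool size.
#' @return List with `k_opt` and `prob`, the maximizing pool size and its
#'   per-lane detection probability.
#' @examples
#' optimal_pool_size(p = 0.005, C = 20, T = 3)$k_opt  # 3
#' @export
optimal_pool_size <- function(p, C, T, k_min = 1L, k_max = 50L) {
  k_min <- assert_count(k_min, "k_min")
  k_max <- assert_count(k_max, "k_max")
  if (k_min > k_max) pd_stop("empty pool-size range: k_min > k_max")
  ks <- k_min:k_max
  probs <- vapply(ks, function(k) detection_prob_equal(k, p, C, T), numeric(1))
  i <- which.max(probs)   # which.max returns the first maximizer: smallest k
  list(k_opt = ks[i], prob = probs[i])
}

#' Design table for equal contributions
#'
#' For every combination of coverage depth and minor allele frequency,
#' finds the optimal pool size, its per-lane detection probability, the
#' minimum number of lanes for the target power, and the total number of
#' individuals `k_opt * lanes`. The lane search uses the full-precision
#' probability, not the 4-decimal value printed in the table.
#'
#' @param C_list Coverage depths to tabulate.
#' @param p_list Minor allele frequencies to tabulate.
#' @inheritParams detection_prob_equal
#' @inheritParams lanes_for_power
#' @inheritParams optimal_pool_size
#' @return A `data.frame` with columns `C`, `p`, `k_opt`, `prob`, `lanes`,
#'   `total`.
#' @examples
#' design_table(C_list = c(20, 30), p_list = c(0.005, 0.01), T = 3)
#' @export
design_table <- function(C_list, p_list, T = 3L, target = 0.8,
                         k_min = 1L, k_max = 50L) {
  if (length(C_list) < 1L || length(p_list) < 1L)
    pd_stop("C_list and p_list must be nonempty")
  grid <- expand.grid(p = p_list, C = C_list)[, c("C", "p")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    C <- grid$C[i]; p <- grid$p[i]
    opt <- optimal_pool_size(p, C, T, k_min, k_max)
    lanes <- lanes_for_power(opt$prob, target)
    data.frame(C = C, p = p, k_opt = opt$k_opt, prob = opt$prob,
               lanes = lanes, total = opt$k_opt * lanes)
  })
  do.call(rbind, rows)
}
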