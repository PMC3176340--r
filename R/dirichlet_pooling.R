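# Detection probability under unequal individual contributions.
#
# The contribution vector w lives on the k-simplex: w_i is the fraction of
# reads originating from individual i, assumed constant across genome
# positions. Individual genotypes g_i in {0, 1, 2} count minor-allele
# copies; a read drawn from individual i carries the variant with
# probability g_i / 2, so the per-read variant fraction is q = sum w_i g_i / 2.

#' Per-read variant fraction for a fixed contribution vector
#'
#' @param w Contribution vector on the simplex (length `k`).
#' @param g Integer genotype vector in `{0, 1, 2}` (length `k`).
#' @return `q = sum(w * g / 2)`, the probability that a single read carries
#'   the variant.
#' @export
read_variant_fraction <- function(w, g) {
  w <- assert_contribution(w)
  if (length(g) != length(w))
    pd_stop("w and g must have the same length (", length(w), " vs ", length(g), ")")
  if (!is.numeric(g) || anyNA(g) || any(g != as.integer(g)) || any(g < 0 | g > 2))
    pd_stop("genotypes g must be integers in {0, 1, 2}")
  sum(w * g / 2)
}

# Smallest carrier count n_max whose excluded upper tail P(N > n_max) is
# below `mass` for N ~ Binomial(2k, p).
carrier_truncation <- function(k, p, mass = 1e-8) {
  if (p == 0) return(0L)
  n_max <- stats::qbinom(mass, 2L * k, p, lower.tail = FALSE)
  min(as.integer(n_max), 2L * k)
}

# Enumerate genotype configurations by (heterozygote set, homozygote set)
# with total carrier count <= n_max. Returns the exact expectation over
# configurations of tail(q); excluded configurations contribute at most
# P(N > n_max) <= trunc_mass.
detection_prob_exact_w <- function(w, p, C, T, n_max, config_budget = 2e6) {
  k <- length(w)
  total_configs <- 0
  for (h in 0:min(n_max, k)) for (m in 0:min((n_max - h) %/% 2L, k - h))
    total_configs <- total_configs + choose(k, h) * choose(k - h, m)
  if (total_configs > config_budget)
    pd_stop("exact enumeration needs ", format(total_configs, big.mark = ","),
            " genotype configurations (budget ", format(config_budget, big.mark = ","),
            "); use mode = \"mc\"", class = "pooldesign_budget_error")
  p_het <- 2 * p * (1 - p); p_hom <- p^2; p_non <- (1 - p)^2
  qs <- numeric(0); wt <- numeric(0)
  idx <- seq_len(k)
  for (h in 0:min(n_max, k)) {
    het_sets <- if (h == 0) list(integer(0)) else
      asplit(utils::combn(k, h), 2)
    for (het in het_sets) {
      rest <- setdiff(idx, het)
      s_het <- sum(w[het])
      for (m in 0:min((n_max - h) %/% 2L, k - h)) {
        hom_sets <- if (m == 0) list(integer(0)) else
          asplit(utils::combn(length(rest), m), 2)
        for (hom_i in hom_sets) {
          hom <- rest[hom_i]
          if (h + m == 0) next   # no carriers: detection probability 0
          qs <- c(qs, s_het / 2 + sum(w[hom]))
          wt <- c(wt, p_het^h * p_hom^m * p_non^(k - h - m))
        }
      }
    }
  }
  if (length(qs) == 0) return(0)
  sum(wt * stats::pbinom(T - 1L, C, pmin(qs, 1), lower.tail = FALSE))
}

#' Detection probability for a fixed contribution vector
#'
#' Expectation over genotype configurations — each individual carries
#' `g_i ~ Binomial(2, p)` minor-allele copies independently — of the read
#' tail `P(Binomial(C, q) >= T)` with `q = sum(w_i g_i / 2)`.
#'
#' Exact mode enumerates genotype configurations. By default the
#' enumeration is complete (all carrier counts up to `2k`) when it fits a
#' configuration budget; for larger pools it is truncated at the smallest
#' carrier count retaining all but `1e-8` of the carrier-count probability
#' mass, and errors with advice to use Monte-Carlo mode when even the
#' truncated enumeration is too large. MC mode averages the read tail over
#' `reps` sampled genotype configurations.
#'
#' @inheritParams read_variant_fraction
#' @inheritParams detection_prob_equal
#' @param mode `"exact"` (enumeration) or `"mc"` (genotype sampling).
#' @param reps Number of genotype draws in MC mode.
#' @param seed Seed for MC mode (required there, ignored in exact mode).
#' @param n_max Optional cap on the enumerated total carrier count;
#'   `NULL` chooses it automatically as described above.
#' @return Detection probability in `[0, 1]`.
#' @examples
#' # uniform contributions reduce to the equal-contribution closed form
#' detection_prob_given_w(rep(1/4, 4), p = 0.01, C = 30, T = 3)
#' detection_prob_equal(k = 4, p = 0.01, C = 30, T = 3)
#' @export
detection_prob_given_w <- function(w, p, C, T, mode = c("exact", "mc"),
                                   reps = 10000L, seed = NULL, n_max = NULL) {
  w <- assert_contribution(w)
  p <- assert_maf(p)
  spec <- assert_pool_spec(length(w), C, T)
  mode <- match.arg(mode)
  if (p == 0) return(0)
  k <- length(w)
  if (mode == "exact") {
    if (is.null(n_max)) {
      # prefer the complete enumeration when affordable so that the uniform-w
      # case reproduces detection_prob_equal to machine precision
      n_max <- if (3^k <= 2e4) 2L * k else carrier_truncation(k, p)
    } else {
      n_max <- assert_count(n_max, "n_max", min = 0L)
    }
    detection_prob_exact_w(w, p, spec$C, spec$T, n_max)
  } else {
    reps <- assert_count(reps, "reps")
    seed <- assert_seed(seed)
    withr::with_seed(seed, {
      g <- matrix(stats::rbinom(reps * k, 2L, p), reps, k)
      q <- as.vector(g %*% w) / 2
      mean(stats::pbinom(spec$T - 1L, spec$C, q, lower.tail = FALSE))
    })
  }
}

# Genotype strata (h heterozygotes, m homozygotes) with h + 2m <= n_max and
# their multinomial probabilities over k individuals.
genotype_strata <- function(k, p, n_max) {
  p_het <- 2 * p * (1 - p); p_hom <- p^2; p_non <- (1 - p)^2
  out <- list()
  for (h in 0:min(n_max, k)) for (m in 0:min((n_max - h) %/% 2L, k - h)) {
    if (h + m == 0) next
    out[[length(out) + 1L]] <- list(
      h = h, m = m,
      prob = choose(k, h) * choose(k - h, m) * p_het^h * p_hom^m * p_non^(k - h - m))
  }
  out
}

#' Average detection probability under a symmetric Dirichlet prior
#'
#' Averages the fixed-`w` detection probability over contribution vectors
#' `w ~ Dirichlet(alpha, ..., alpha)` by Monte Carlo. For each draw the
#' inner genotype expectation is computed exactly: genotype configurations
#' are grouped into strata of `h` heterozygotes and `m` homozygotes
#' (truncated at total carrier count with excluded mass `< 1e-8`), and —
#' because the symmetric Dirichlet is exchangeable — the read fraction of a
#' stratum depends on the draw only through the aggregate contribution of
#' `h + m` of its coordinates, so each stratum uses the draw's leading
#' coordinates. The estimator is an unbiased per-draw deterministic
#' function of the draw; its Monte-Carlo standard error is reported.
#'
#' @inheritParams detection_prob_equal
#' @param alpha Symmetric Dirichlet concentration, `> 0`. Large `alpha`
#'   concentrates contributions near equality and recovers
#'   [detection_prob_equal()].
#' @param n_w Number of Dirichlet draws (at least 100; default 20000 keeps
#'   the standard error below about 1e-3 on all tabulated designs).
#' @param seed Seed for the Dirichlet draws (required).
#' @return List with `prob` (Monte-Carlo mean), `se` (standard error of the
#'   mean), `n_w`, and `alpha`.
#' @examples
#' average_detection_prob(k = 3, p = 0.005, C = 20, T = 3,
#'                        alpha = 2.89, n_w = 5000, seed = 1)
#' @export
average_detection_prob <- function(k, p, C, T, alpha, n_w = 20000L, seed) {
  spec <- assert_pool_spec(k, C, T)
  p <- assert_maf(p)
  if (length(alpha) != 1L || !is.numeric(alpha) || is.na(alpha) || alpha <= 0)
    pd_stop("alpha must be a single positive number")
  n_w <- assert_count(n_w, "n_w", min = 100L)
  seed <- assert_seed(seed)
  k <- spec$k
  if (p == 0) return(list(prob = 0, se = 0, n_w = n_w, alpha = alpha))
  strata <- genotype_strata(k, p, carrier_truncation(k, p))
  withr::with_seed(seed, {
    G <- matrix(stats::rgamma(n_w * k, shape = alpha), n_w, k)
    # numerical underflow at very small alpha can zero a whole row; clamp
    G[G < 1e-12] <- 1e-12
    tot <- rowSums(G)
    f <- numeric(n_w)
    for (s in strata) {
      U <- if (s$h > 0) rowSums(G[, seq_len(s$h), drop = FALSE]) else 0
      V <- if (s$m > 0) rowSums(G[, s$h + seq_len(s$m), drop = FALSE]) else 0
      q <- (U / 2 + V) / tot
      f <- f + s$prob * stats::pbinom(spec$T - 1L, spec$C, q, lower.tail = FALSE)
    }
    list(prob = mean(f), se = stats::sd(f) / sqrt(n_w), n_w = n_w, alpha = alpha)
  })
}

#' Optimal pool size under a symmetric Dirichlet contribution prior
#'
#' Searches the pool size maximizing [average_detection_prob()]. Every
#' candidate `k` is evaluated with the same seed (common random numbers), so
#' the comparison across `k` is not blurred by independent Monte-Carlo
#' noise; ties break towards the smallest `k`.
#'
#' @inheritParams average_detection_prob
#' @inheritParams optimal_pool_size
#' @param k_min,k_max Inclusive search range (default 2..25).
#' @return List with `k_opt`, `prob`, and `se` at the optimum.
#' @export
optimal_pool_size_dirichlet <- function(p, C, T, alpha, k_min = 2L, k_max = 25L,
                                        n_w = 20000L, seed) {
  k_min <- assert_count(k_min, "k_min")
  k_max <- assert_count(k_max, "k_max")
  if (k_min > k_max) pd_stop("empty pool-size range: k_min > k_max")
  fits <- lapply(k_min:k_max, function(k)
    average_detection_prob(k, p, C, T, alpha, n_w = n_w, seed = seed))
  probs <- vapply(fits, `[[`, numeric(1), "prob")
  i <- which.max(probs)
  list(k_opt = (k_min:k_max)[i], prob = probs[i], se = fits[[i]]$se)
}

#' Design table under a symmetric Dirichlet contribution prior
#'
#' Dirichlet-prior analogue of [design_table()]: per (coverage, MAF) cell it
#' reports the optimal pool size, the average detection probability with its
#' Monte-Carlo standard error, the minimum lanes for the target power, and
#' the total number of individuals.
#'
#' @inheritParams design_table
#' @inheritParams optimal_pool_size_dirichlet
#' @return A `data.frame` with columns `C`, `p`, `k_opt`, `prob`, `mc_se`,
#'   `lanes`, `total`.
#' @export
design_table_dirichlet <- function(C_list, p_list, T = 3L, alpha, target = 0.8,
                                   n_w = 20000L, seed, k_min = 2L, k_max = 25L) {
  if (length(C_list) < 1L || length(p_list) < 1L)
    pd_stop("C_list and p_list must be nonempty")
  for (p in p_list) assert_maf(p, allow_zero = FALSE)
  grid <- expand.grid(p = p_list, C = C_list)[, c("C", "p")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    C <- grid$C[i]; p <- grid$p[i]
    opt <- optimal_pool_size_dirichlet(p, C, T, alpha, k_min, k_max,
                                       n_w = n_w, seed = seed)
    lanes <- lanes_for_power(opt$prob, target)
    data.frame(C = C, p = p, k_opt = opt$k_opt, prob = opt$prob,
               mc_se = opt$se, lanes = lanes, total = opt$k_opt * lanes)
  })
  do.call(rbind, rows)
}
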