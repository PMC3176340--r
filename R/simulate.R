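# Forward simulator of pooled sequencing. Serves as the brute-force oracle
# for the analytic detection and mis-detection probabilities and as the
# synthetic-data generator for contribution estimation. Every function
# requires an explicit seed and restores the caller's RNG state.

#' Simulate pooled-sequencing detection of a rare variant
#'
#' Per replicate: draw the contribution vector `w` (uniform, or symmetric
#' `Dirichlet(alpha)` when `alpha` is given), draw each individual's
#' genotype `g_i ~ Binomial(2, p)`, draw the variant read count
#' `Binomial(C, sum(w_i g_i / 2))`, and declare detection when it reaches
#' `T`.
#'
#' @inheritParams detection_prob_equal
#' @param alpha Optional symmetric Dirichlet concentration; `NULL` (default)
#'   uses equal contributions.
#' @param n_reps Number of simulated pools.
#' @param seed RNG seed (required).
#' @return List with `rate` (empirical detection rate), `se` (binomial
#'   standard error), `n_reps`, and `seed`.
#' @examples
#' simulate_detection(k = 3, p = 0.005, C = 20, T = 3,
#'                    n_reps = 1e5, seed = 1)$rate  # near 0.0200
#' @export
simulate_detection <- function(k, p, C, T, alpha = NULL, n_reps, seed) {
  spec <- assert_pool_spec(k, C, T)
  p <- assert_maf(p)
  n_reps <- assert_count(n_reps, "n_reps")
  seed <- assert_seed(seed)
  k <- spec$k
  withr::with_seed(seed, {
    g <- matrix(stats::rbinom(n_reps * k, 2L, p), n_reps, k)
    if (is.null(alpha)) {
      q <- rowSums(g) / (2 * k)
    } else {
      G <- matrix(stats::rgamma(n_reps * k, shape = alpha), n_reps, k)
      G[G < 1e-12] <- 1e-12
      q <- rowSums(g * G) / (2 * rowSums(G))
    }
    hits <- stats::rbinom(n_reps, spec$C, q) >= spec$T
  })
  rate <- mean(hits)
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_reps),
       n_reps = n_reps, seed = seed)
}

#' Generate synthetic per-site pooled genotype/read-count data
#'
#' Emulates the input of [estimate_w()]: per site, a minor allele frequency
#' is sampled, individual genotypes are drawn `Binomial(2, maf)`, the site
#' depth is `Poisson(mean_depth)` (at least 1), and the pooled alternate
#' read count is `Binomial(depth, sum(w_i g_i / 2))` under the true
#' contribution vector.
#'
#' @param k Number of individuals in the pool.
#' @param n_sites Number of sites to simulate.
#' @param maf_sampler Either a function `n -> numeric(n)` of per-site minor
#'   allele frequencies, or a single number used for every site. The default
#'   draws common frequencies `Uniform(0.05, 0.5)`, which keeps the sites
#'   genotypically diverse and the contribution vector well identified.
#' @param true_w True contribution vector on the simplex (length `k`).
#' @param mean_depth Mean per-site sequencing depth.
#' @param seed RNG seed (required).
#' @return A `data.frame` with columns `site`, `g1..gk`, `ref_count`,
#'   `alt_count`.
#' @export
simulate_site_data <- function(k, n_sites,
                               maf_sampler = function(n) stats::runif(n, 0.05, 0.5),
                               true_w, mean_depth, seed) {
  k <- assert_count(k, "k")
  n_sites <- assert_count(n_sites, "n_sites", min = 0L)
  # accept rounded vectors (e.g. printed to 4 decimals) and renormalize
  true_w <- assert_contribution(true_w, "true_w", tol = 1e-3)
  true_w <- true_w / sum(true_w)
  if (length(true_w) != k) pd_stop("true_w must have length k = ", k)
  seed <- assert_seed(seed)
  if (is.numeric(maf_sampler)) {
    maf_fixed <- assert_maf(maf_sampler, "maf_sampler")
    maf_sampler <- function(n) rep(maf_fixed, n)
  }
  withr::with_seed(seed, {
    maf <- maf_sampler(n_sites)
    g <- matrix(stats::rbinom(n_sites * k, 2L, rep(maf, k)), n_sites, k)
    depth <- pmax(stats::rpois(n_sites, mean_depth), 1L)
    q <- as.vector(g %*% true_w) / 2
    alt <- stats::rbinom(n_sites, depth, q)
  })
  out <- data.frame(site = seq_len(n_sites))
  for (i in seq_len(k)) out[[paste0("g", i)]] <- if (n_sites > 0) g[, i] else integer(0)
  out$ref_count <- if (n_sites > 0) depth - alt else integer(0)
  out$alt_count <- if (n_sites > 0) alt else integer(0)
  out
}

#' Simulate error-only sites and their maximum wrong-base count
#'
#' Draws `(correct, b1, b2, b3) ~ Multinomial(C; 1 - e, e/3, e/3, e/3)` per
#' replicate and returns `max(b1, b2, b3)` — the mis-detection statistic.
#'
#' @inheritParams misdetection_prob_multinomial
#' @param n_reps Number of simulated sites.
#' @param seed RNG seed (required).
#' @return Integer vector of length `n_reps`.
#' @examples
#' mean(simulate_error_sites(C = 50, e = 0.01, n_reps = 1e5, seed = 1) >= 3)
#' @export
simulate_error_sites <- function(C, e, n_reps, seed) {
  C <- assert_count(C, "C")
  e <- assert_error_rate(e)
  n_reps <- assert_count(n_reps, "n_reps")
  seed <- assert_seed(seed)
  withr::with_seed(seed, {
    counts <- stats::rmultinom(n_reps, C, c(1 - e, e / 3, e / 3, e / 3))
  })
  as.integer(pmax(counts[2, ], counts[3, ], counts[4, ]))
}
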