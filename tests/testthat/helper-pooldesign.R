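# Shared fixtures and independent oracles, all built in code.

# Contribution vector estimated from the 8-individual capture experiment
# (printed to 4 decimals, hence summing to 0.9999).
printed_w_hat <- c(0.1380, 0.0836, 0.1142, 0.0188, 0.1805, 0.1364, 0.1617, 0.1667)

# Published design table under equal contributions: per (coverage, MAF) the
# optimal pool size, its per-lane detection probability (4 dp), the minimum
# lanes for 80% power, and the total individuals.
table1_published <- data.frame(
  C     = rep(c(20, 30, 40, 50), each = 3),
  p     = rep(c(0.005, 0.010, 0.025), times = 4),
  k_opt = c(3, 3, 3,   4, 4, 5,   6, 6, 6,   7, 8, 8),
  prob  = c(0.0200, 0.0397, 0.0973,  0.0293, 0.0580, 0.1408,
            0.0390, 0.0768, 0.1836,  0.0482, 0.0947, 0.2247),
  lanes = c(80, 40, 16,  55, 27, 11,  41, 21, 8,  33, 17, 7),
  total = c(240, 120, 48,  220, 108, 55,  246, 126, 48,  231, 136, 56))

# Published Dirichlet-prior design table, concentration estimated by
# pseudo-ML (2.89) and pseudo-MM (4.76). Probabilities are the published
# Monte-Carlo averages at the published optimal pool size.
table2_published <- rbind(
  data.frame(alpha = 2.89,
             C     = rep(c(20, 30, 40, 50), each = 3),
             p     = rep(c(0.005, 0.010, 0.025), times = 4),
             k_opt = c(3, 3, 3,  5, 5, 6,  7, 7, 8,  10, 10, 12),
             prob  = c(0.0180, 0.0357, 0.0868,  0.0259, 0.0515, 0.1265,
                       0.0340, 0.0676, 0.1661,  0.0423, 0.0838, 0.2046)),
  data.frame(alpha = 4.76,
             C     = rep(c(20, 30, 40, 50), each = 3),
             p     = rep(c(0.005, 0.010, 0.025), times = 4),
             k_opt = c(3, 3, 3,  5, 5, 5,  6, 7, 7,  9, 8, 11),
             prob  = c(0.0183, 0.0368, 0.0904,  0.0268, 0.0539, 0.1307,
                       0.0356, 0.0703, 0.1710,  0.0442, 0.0872, 0.2100)))

# Brute-force survival of the maximum wrong-base count under
# (correct, b1, b2, b3) ~ Multinomial(C; 1-e, e/3, e/3, e/3):
# P(max >= T) = 1 - sum over all (x, y, z) below T of the multinomial pmf.
# Independent of the inclusion-exclusion implementation.
brute_max_survival <- function(C, e, T) {
  if (e == 0) return(0)
  q <- e / 3
  below <- 0
  for (x in 0:(T - 1)) for (y in 0:(T - 1)) for (z in 0:(T - 1)) {
    if (x + y + z > C) next
    below <- below + exp(
      lgamma(C + 1) - lgamma(x + 1) - lgamma(y + 1) - lgamma(z + 1) -
        lgamma(C - x - y - z + 1) +
        (x + y + z) * log(q) + (C - x - y - z) * log(1 - e))
  }
  1 - below
}

# Full simulation of one pooled lane: genotypes, read fraction, read draw.
# Brute-force oracle for the analytic detection probabilities.
brute_detection_rate <- function(k, p, C, T, n_reps, seed, w = NULL, alpha = NULL) {
  withr::with_seed(seed, {
    g <- matrix(rbinom(n_reps * k, 2L, p), n_reps, k)
    if (!is.null(w)) {
      q <- as.vector(g %*% (w / sum(w))) / 2
    } else if (!is.null(alpha)) {
      G <- matrix(rgamma(n_reps * k, shape = alpha), n_reps, k)
      q <- rowSums(g * G) / (2 * rowSums(G))
    } else {
      q <- rowSums(g) / (2 * k)
    }
    mean(rbinom(n_reps, C, q) >= T)
  })
}

# Symmetric-Dirichlet log density of one observation, up to no constant:
# the grid-search oracle for the pseudo-ML concentration estimate.
dirichlet_logdens <- function(alpha, w) {
  k <- length(w)
  lgamma(k * alpha) - k * lgamma(alpha) + (alpha - 1) * sum(log(w))
}

rdirichlet_one <- function(k, alpha) {
  g <- rgamma(k, shape = alpha)
  g / sum(g)
}
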