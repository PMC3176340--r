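test_that("per-read variant fraction mixes genotypes by contribution", {
  k <- 6
  g <- integer(k); g[2] <- 1L
  expect_equal(read_variant_fraction(rep(1 / k, k), g), 1 / (2 * k))
  expect_equal(read_variant_fraction(rep(1 / k, k), rep(2L, k)), 1)
  # printed contribution vector, only individual 4 heterozygous
  w <- printed_w_hat / sum(printed_w_hat)
  g <- integer(8); g[4] <- 1L
  expect_equal(round(read_variant_fraction(w, g), 4), 0.0094)
  expect_error(read_variant_fraction(rep(1 / 4, 4), c(0L, 1L)), "same length")
  expect_error(read_variant_fraction(rep(1 / 4, 4), c(0, 1, 3, 0)), "\\{0, 1, 2\\}")
})

test_that("fixed-w model reduces exactly to the equal-contribution closed form", {
  for (k in c(2, 4, 6, 8)) for (p in c(0.005, 0.025)) for (C in c(20, 50)) {
    expect_equal(detection_prob_given_w(rep(1 / k, k), p, C, 3),
                 detection_prob_equal(k, p, C, 3), tolerance = 1e-10)
  }
  expect_equal(detection_prob_given_w(rep(1 / 5, 5), 0, 20, 3), 0)
})

test_that("fixed-w exact probability agrees with a full pool simulation", {
  w <- printed_w_hat / sum(printed_w_hat)
  exact <- detection_prob_given_w(w, p = 0.01, C = 30, T = 3)
  n_reps <- 4e5
  rate <- brute_detection_rate(k = 8, p = 0.01, C = 30, T = 3,
                               n_reps = n_reps, seed = 11, w = w)
  se <- sqrt(exact * (1 - exact) / n_reps)
  expect_lt(abs(rate - exact), 4 * se)
  # Monte-Carlo genotype mode converges to the exact enumeration
  mc <- detection_prob_given_w(w, 0.01, 30, 3, mode = "mc", reps = 3e5, seed = 4)
  expect_lt(abs(mc - exact), 4 * sqrt(exact * (1 - exact) / 3e5))
})

test_that("exact enumeration truncation keeps negligible carrier mass", {
  w <- printed_w_hat / sum(printed_w_hat)
  # truncated at the 1e-8 carrier-mass cap vs the complete enumeration
  n_trunc <- qbinom(1e-8, 16, 0.025, lower.tail = FALSE)
  full <- detection_prob_given_w(w, 0.025, 50, 3, n_max = 16)
  trunc <- detection_prob_given_w(w, 0.025, 50, 3, n_max = n_trunc)
  expect_lt(abs(full - trunc), 1e-6)
  expect_lte(trunc, full)
  # enumeration budget guard points at MC mode
  expect_error(detection_prob_given_w(rep(1 / 40, 40), 0.2, 50, 3),
               "mc", class = "pooldesign_budget_error")
})

test_that("Dirichlet-averaged probability hits published cells with small MC error", {
  cells <- data.frame(k = c(3, 11, 5, 3), p = c(0.005, 0.025, 0.01, 0.025),
                      C = c(20, 50, 30, 20), alpha = c(2.89, 4.76, 2.89, 4.76),
                      prob = c(0.0180, 0.2100, 0.0515, 0.0904))
  for (i in seq_len(nrow(cells))) {
    r <- average_detection_prob(cells$k[i], cells$p[i], cells$C[i], 3,
                                alpha = cells$alpha[i], n_w = 20000, seed = 1)
    expect_lt(r$se, 0.001)
    expect_lt(abs(r$prob - cells$prob[i]), 0.003)
  }
})

test_that("Dirichlet average is monotone in alpha and dominated by the equal case", {
  alphas <- c(0.25, 0.5, 0.75, 1, 2, 5)
  # common random numbers: same seed across alphas
  res <- lapply(alphas, function(a)
    average_detection_prob(5, 0.01, 30, 3, alpha = a, n_w = 8000, seed = 3))
  probs <- vapply(res, `[[`, numeric(1), "prob")
  ses <- vapply(res, `[[`, numeric(1), "se")
  expect_true(all(diff(probs) > -2 * (ses[-1] + ses[-length(ses)])))
  # unequal contributions cannot beat equal contributions (alpha >= 1)
  eq <- detection_prob_equal(5, 0.01, 30, 3)
  for (i in which(alphas >= 1)) expect_lt(probs[i], eq + 2 * ses[i])
  # large alpha concentrates at the uniform vector
  big <- average_detection_prob(4, 0.01, 30, 3, alpha = 1e4, n_w = 5000, seed = 2)
  expect_lt(abs(big$prob - detection_prob_equal(4, 0.01, 30, 3)),
            2 * big$se + 1e-4)
})

test_that("pool-size search under the prior matches published robust cells", {
  expect_identical(
    optimal_pool_size_dirichlet(0.005, 20, 3, alpha = 2.89, k_min = 2, k_max = 8,
                                n_w = 20000, seed = 1)$k_opt, 3L)
  expect_identical(
    optimal_pool_size_dirichlet(0.01, 30, 3, alpha = 2.89, k_min = 2, k_max = 10,
                                n_w = 20000, seed = 1)$k_opt, 5L)
  expect_identical(
    optimal_pool_size_dirichlet(0.025, 20, 3, alpha = 4.76, k_min = 2, k_max = 8,
                                n_w = 20000, seed = 1)$k_opt, 3L)
  # near-equal contributions recover the equal-contribution optimum
  eq_opt <- optimal_pool_size(0.01, 30, 3, k_min = 2, k_max = 10)$k_opt
  expect_identical(
    optimal_pool_size_dirichlet(0.01, 30, 3, alpha = 1e4, k_min = 2, k_max = 10,
                                n_w = 5000, seed = 5)$k_opt, eq_opt)
})

test_that("high-coverage optima sit on a flat ridge within one of the published size", {
  # at C = 50 the detection-probability curve is flat near its maximum;
  # the search must land within one pool size of the published optimum and
  # lose essentially no probability relative to the published cell
  opt <- optimal_pool_size_dirichlet(0.025, 50, 3, alpha = 4.76,
                                     k_min = 2, k_max = 16, n_w = 20000, seed = 1)
  expect_lte(abs(opt$k_opt - 11L), 1L)
  expect_lt(abs(opt$prob - 0.2100), 0.003)
})

test_that("Dirichlet design table reports lanes and totals consistently", {
  tab <- design_table_dirichlet(C_list = c(20, 30), p_list = c(0.01, 0.025),
                                T = 3, alpha = 2.89, n_w = 5000, seed = 9,
                                k_max = 10)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$total, tab$k_opt * tab$lanes)
  expect_true(all(tab$mc_se < 0.005))
  # published cell C = 30, p = 0.01: 5 individuals, ~0.0515, 31 lanes
  row <- tab[tab$C == 30 & tab$p == 0.01, ]
  expect_identical(row$k_opt, 5L)
  expect_lt(abs(row$prob - 0.0515), 0.003)
  expect_error(design_table_dirichlet(20, 0, alpha = 2, seed = 1), "positive")
})
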