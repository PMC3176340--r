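# Estimating individual contributions and the Dirichlet concentration.
#
# The contribution vector w of a pool can be estimated by comparing pooled
# sequencing read counts with the individual genotypes at a panel of sites:
# at a site with genotypes g the expected pooled alternate-allele read
# fraction is sum(w_i g_i / 2). A single estimated w-hat then calibrates the
# spread of contributions through a symmetric Dirichlet concentration.

site_matrix <- function(sites) {
  gcols <- grep("^g[0-9]+$", names(sites), value = TRUE)
  if (length(gcols) < 1L)
    pd_stop("site data must contain genotype columns g1..gk")
  gcols <- gcols[order(as.integer(sub("^g", "", gcols)))]
  g <- as.matrix(sites[, gcols, drop = FALSE])
  if (anyNA(g) || any(g != round(g)) || any(g < 0 | g > 2))
    pd_stop("genotype columns must be integers in {0, 1, 2}")
  if (!all(c("ref_count", "alt_count") %in% names(sites)))
    pd_stop("site data must contain ref_count and alt_count columns")
  list(g = g, ref = sites$ref_count, alt = sites$alt_count)
}

#' Estimate a pool's contribution vector from genotypes and read counts
#'
#' Depth-weighted least squares of the pooled alternate-allele read
#' fraction on the genotype-implied fraction: minimizes
#' `sum_s d_s * (a_s / d_s - sum_i w_i g_si / 2)^2` over the simplex
#' (`sum w = 1`, `w >= 0`), with `d_s = r_s + a_s` the site depth. The
#' equality-constrained weighted normal equations are solved in closed
#' form; nonnegativity is enforced by an active-set loop that pins negative
#' coordinates to zero and re-solves.
#'
#' @param sites A `data.frame` with genotype columns `g1..gk` (integers in
#'   `{0, 1, 2}`), `ref_count`, and `alt_count` — the layout written by
#'   [simulate_site_data()] and read by [read_site_data()].
#' @return Estimated contribution vector on the simplex (length `k`).
#' @examples
#' sites <- simulate_site_data(k = 4, n_sites = 300,
#'                             true_w = c(0.4, 0.3, 0.2, 0.1),
#'                             mean_depth = 150, seed = 1)
#' round(estimate_w(sites), 3)
#' @export
estimate_w <- function(sites) {
  if (!is.data.frame(sites) || nrow(sites) < 1L)
    pd_stop("sites must be a nonempty data.frame")
  sm <- site_matrix(sites)
  d <- sm$ref + sm$alt
  if (any(d < 1)) {
    warning("dropping ", sum(d < 1), " site(s) with zero depth")
    keep <- d >= 1
    sm$g <- sm$g[keep, , drop = FALSE]
    sm$alt <- sm$alt[keep]
    d <- d[keep]
  }
  if (nrow(sm$g) < 1L) pd_stop("no sites with positive depth")
  k <- ncol(sm$g)
  if (k == 1L) return(1)
  X <- sm$g / 2
  f <- sm$alt / d
  if (qr(rbind(X, rep(1, k)))$rank < k)
    pd_stop("contribution vector is not identifiable: genotype columns are ",
            "linearly dependent (e.g. two individuals with identical ",
            "genotypes at every site)", class = "pooldesign_identifiability_error")
  A <- crossprod(X, X * d)        # X' D X
  b <- crossprod(X, f * d)        # X' D f
  free <- rep(TRUE, k)
  w <- rep(NA_real_, k)
  for (iter in seq_len(k)) {
    kf <- sum(free)
    # KKT system for min w'Aw - 2b'w subject to sum(w[free]) = 1
    K <- rbind(cbind(2 * A[free, free, drop = FALSE], rep(1, kf)),
               c(rep(1, kf), 0))
    sol <- solve(K, c(2 * b[free], 1))
    w[free] <- sol[seq_len(kf)]
    w[!free] <- 0
    if (all(w[free] >= -1e-12)) break
    free[free][which.min(w[free])] <- FALSE
    if (sum(free) == 0L)
      pd_stop("active-set solver eliminated all coordinates; data are degenerate")
  }
  w <- pmax(w, 0)
  w / sum(w)
}

#' Pseudo maximum-likelihood estimate of the Dirichlet concentration
#'
#' Treats the single estimated contribution vector as one observation from
#' a symmetric `Dirichlet(alpha, ..., alpha)` and maximizes its log-density.
#' The score equation is `digamma(k * alpha) - digamma(alpha) =
#' -(1/k) * sum(log w_i)`; the left side decreases strictly from infinity
#' to `log k` as `alpha` grows, so a unique root exists precisely when the
#' right side exceeds `log k` (i.e. the vector is not uniform). Solved by
#' bracketed root-finding over `[1e-6, 1e6]` to `|score| < 1e-10`.
#'
#' @param w_hat Estimated contribution vector, strictly positive, on the
#'   simplex.
#' @return List with `alpha` and `method = "pmle"`.
#' @examples
#' w_hat <- c(0.1380, 0.0836, 0.1142, 0.0188, 0.1805, 0.1364, 0.1617, 0.1667)
#' pmle_alpha(w_hat)$alpha  # 2.89
#' @export
pmle_alpha <- function(w_hat) {
  # estimated vectors are often printed/stored rounded; accept a 1e-3
  # departure from the simplex and use the values as given
  w_hat <- assert_contribution(w_hat, "w_hat", strict_positive = TRUE, tol = 1e-3)
  k <- length(w_hat)
  if (k < 2L) pd_stop("w_hat must have at least 2 coordinates")
  mlog <- mean(log(w_hat))
  if (-mlog <= log(k) + 1e-12)
    pd_stop("degenerate: w_hat too uniform, the likelihood increases without ",
            "bound as alpha grows", class = "pooldesign_degenerate_error")
  score <- function(a) digamma(k * a) - digamma(a) + mlog
  root <- stats::uniroot(score, c(1e-6, 1e6), tol = .Machine$double.eps^0.75)
  if (abs(score(root$root)) > 1e-10)
    pd_stop("root-finding did not converge: |score| = ", abs(score(root$root)))
  list(alpha = root$root, method = "pmle")
}

#' Pseudo method-of-moments estimate of the Dirichlet concentration
#'
#' Matches the coordinate variance of a symmetric `Dirichlet(alpha)` on `k`
#' coordinates, `(1/k)(1 - 1/k) / (k * alpha + 1)`, to the sample variance
#' `s^2` of the observed vector's coordinates (divisor `k - 1`), giving
#' `alpha = ((1/k)(1 - 1/k) / s^2 - 1) / k`.
#'
#' @inheritParams pmle_alpha
#' @return List with `alpha` and `method = "pmme"`.
#' @examples
#' w_hat <- c(0.1380, 0.0836, 0.1142, 0.0188, 0.1805, 0.1364, 0.1617, 0.1667)
#' pmme_alpha(w_hat)$alpha  # 4.76
#' @export
pmme_alpha <- function(w_hat) {
  w_hat <- assert_contribution(w_hat, "w_hat", tol = 1e-3)
  k <- length(w_hat)
  if (k < 2L) pd_stop("w_hat must have at least 2 coordinates")
  s2 <- stats::var(w_hat)
  if (s2 == 0)
    pd_stop("degenerate: w_hat is exactly uniform, alpha is unbounded",
            class = "pooldesign_degenerate_error")
  alpha <- ((1 / k) * (1 - 1 / k) / s2 - 1) / k
  if (alpha <= 0)
    pd_stop("w_hat is more dispersed than any Dirichlet allows ",
            "(implied alpha <= 0)", class = "pooldesign_degenerate_error")
  list(alpha = alpha, method = "pmme")
}

#' Read per-site pooled genotype/read-count data from a TSV
#'
#' Expects tab-separated columns `site`, `g1..gk`, `ref_count`, `alt_count`
#' as written by [write_site_data()].
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` in the layout accepted by [estimate_w()].
#' @export
read_site_data <- function(path) {
  sites <- utils::read.delim(path, sep = "\t", check.names = TRUE)
  site_matrix(sites)  # validates layout
  sites
}

#' Write per-site pooled data to a TSV
#'
#' @param sites Site data as produced by [simulate_site_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_data <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
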