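# Internal argument checks shared across the package.
# All user-facing errors are signalled with a "pooldesign_error" condition
# class so the CLI can map them to a clean exit status.

pd_stop <- function(..., class = "pooldesign_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    pd_stop(name, " must be a single integer >= ", min, " (got ", deparse(x), ")")
  as.integer(x)
}

assert_prob <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) ||
      x < lo || x > hi || (open_lo && x <= lo) || (open_hi && x >= hi))
    pd_stop(name, " must be a probability in ",
            if (open_lo) "(" else "[", lo, ", ", hi, if (open_hi) ")" else "]",
            " (got ", deparse(x), ")")
  as.numeric(x)
}

# MAF is restricted to the minor-allele range [0, 0.5]; a zero frequency is
# accepted only where the result is trivially zero.
assert_maf <- function(p, name = "p", allow_zero = TRUE) {
  p <- assert_prob(p, name, lo = 0, hi = 0.5)
  if (!allow_zero && p == 0)
    pd_stop(name, " must be positive")
  p
}

assert_pool_spec <- function(k, C, T, L = 1L) {
  k <- assert_count(k, "k")
  C <- assert_count(C, "C")
  T <- assert_count(T, "T")
  L <- assert_count(L, "L")
  if (T > C) pd_stop("threshold T must satisfy 1 <= T <= C (T = ", T, ", C = ", C, ")")
  list(k = k, C = C, T = T, L = L)
}

assert_contribution <- function(w, name = "w", strict_positive = FALSE, tol = 1e-9) {
  if (!is.numeric(w) || length(w) < 1L || anyNA(w))
    pd_stop(name, " must be a numeric vector without NAs")
  if (any(w < 0))
    pd_stop("all entries of ", name, " must be >= 0")
  if (strict_positive && any(w == 0))
    pd_stop("all entries of ", name, " must be strictly positive")
  if (abs(sum(w) - 1) > tol)
    pd_stop(name, " must sum to 1 (sum = ", format(sum(w), digits = 12), ")")
  as.numeric(w)
}

assert_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed))
    pd_stop("seed must be a single integer; stochastic results are only ",
            "reproducible under an explicit seed")
  as.integer(seed)
}
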