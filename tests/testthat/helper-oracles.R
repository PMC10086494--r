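# Independent oracles used across tests.

# --- Exact hypergeometric enumeration via prime factorization -------------
# Every table probability with fixed margins is a ratio of factorials of
# integers <= 60, hence an exact rational whose prime factorization we can
# compute with Legendre's formula. Converting prod(p^e) to double loses only
# one rounding step (~1e-16 relative), far below the 1e-9 comparison level.
.oracle_primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53, 59)

# exponent of prime p in n! (Legendre)
.fact_exp <- function(n, p) {
  e <- 0; q <- p
  while (q <= n) { e <- e + n %/% q; q <- q * p }
  e
}

# rows: n = 0..60; cols: primes
.oracle_fact_table <- local({
  tab <- sapply(.oracle_primes, function(p) vapply(0:60, .fact_exp, numeric(1), p))
  rownames(tab) <- 0:60
  tab
})

# exact probabilities of all tables with margins (r1, r2, c1); returns
# list(k, prob, expo) where expo rows are exact prime exponent vectors
oracle_hyper_probs <- function(r1, r2, c1) {
  n <- r1 + r2
  stopifnot(n <= 60)
  k <- max(0, c1 - r2):min(r1, c1)
  F <- .oracle_fact_table
  expo <- t(vapply(k, function(a) {
    F[r1 + 1L, ] + F[r2 + 1L, ] + F[c1 + 1L, ] + F[n - c1 + 1L, ] -
      F[n + 1L, ] - F[a + 1L, ] - F[r1 - a + 1L, ] - F[c1 - a + 1L, ] -
      F[r2 - c1 + a + 1L, ]
  }, numeric(length(.oracle_primes))))
  prob <- apply(expo, 1L, function(e) prod(.oracle_primes^e))
  list(k = k, prob = prob, expo = expo)
}

# Exact-enumeration Fisher oracle: two-sided by the "no more probable than
# observed" rule with the same 1e-7 relative tie tolerance as the
# implementation (ties themselves are detected exactly, by unique
# factorization: equal probabilities have equal exponent vectors).
oracle_fisher <- function(a, b, c, d) {
  hp <- oracle_hyper_probs(a + b, c + d, a + c)
  i_obs <- which(hp$k == a)
  p_obs <- hp$prob[i_obs]
  is_tie <- apply(hp$expo, 1L, function(e) all(e == hp$expo[i_obs, ]))
  sel <- is_tie | hp$prob <= p_obs * (1 + 1e-7)
  list(p_two_sided = min(1, sum(hp$prob[sel])),
       p_one_sided_enrichment = min(1, sum(hp$prob[hp$k >= a])))
}

# --- Brute-force survival oracles -----------------------------------------
# Empirical survival function evaluated at the distinct event times.
oracle_empirical_surv <- function(times) {
  t_sort <- sort(unique(times))
  vapply(t_sort, function(t) mean(times > t), numeric(1))
}
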