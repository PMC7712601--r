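# Independent oracles, written directly from first principles and kept
# separate from the implementation paths they check.

# Plain double-loop concordance counter: the smaller observed time must end
# in death for a pair to be comparable; equal times are comparable only when
# exactly one is a death (the death losing).
brute_force_wins <- function(t1, e1, t0, e0) {
  gamma <- 0L; n <- 0L
  for (i in seq_along(t1)) {
    for (j in seq_along(t0)) {
      if (t1[i] < t0[j]) {
        if (e1[i] == 1) n <- n + 1L            # treated death first: loss
      } else if (t1[i] > t0[j]) {
        if (e0[j] == 1) { n <- n + 1L; gamma <- gamma + 1L }
      } else {
        if (e1[i] == 1 && e0[j] == 0) n <- n + 1L
        if (e1[i] == 0 && e0[j] == 1) { n <- n + 1L; gamma <- gamma + 1L }
      }
    }
  }
  list(gamma = gamma, n = n)
}

# Random censored instance for the concordance property tests.
random_win_instance <- function(max_side = 30L) {
  n1 <- sample.int(max_side, 1L)
  n0 <- sample.int(max_side, 1L)
  # mix of continuous and tied integer times to exercise the tie rules
  draw <- function(n) {
    if (runif(1) < 0.5) round(rexp(n, 0.1)) else rexp(n, 0.1)
  }
  list(t1 = draw(n1), e1 = rbinom(n1, 1, 0.6),
       t0 = draw(n0), e0 = rbinom(n0, 1, 0.6))
}

# Deterministic quadrature for P(A > B), A ~ Beta(a1,b1), B ~ Beta(a2,b2):
# integral of f_A(x) * F_B(x) dx over (0,1).
beta_exceed_quadrature <- function(a1, b1, a2, b2) {
  stats::integrate(function(x) dbeta(x, a1, b1) * pbeta(x, a2, b2),
                   0, 1, rel.tol = 1e-10)$value
}

# Bisection inversion of the regularized incomplete beta (credible-bound
# oracle, independent of qbeta).
bisect_beta_quantile <- function(p, a, b, tol = 1e-12) {
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pbeta(mid, a, b) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Independent log-gamma evaluation of the Beta density at 0.5.
log_dbeta_half <- function(a, b) {
  (lgamma(a + b) - lgamma(a) - lgamma(b)) + (a - 1) * log(0.5) +
    (b - 1) * log(0.5)
}

# Brute-force logistic log-likelihood, maximized by a generic optimizer.
logistic_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}
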