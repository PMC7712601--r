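# Concordance win counting, conjugate updating, Bayes factors, selection.

test_that("count_wins applies the comparability rules", {
  # exhaustive enumeration of 4 pairs, all comparable, 3 treated wins
  tal <- count_wins(c(5, 10), c(1, 1), c(3, 7), c(1, 1))
  expect_equal(tal$gamma, 3L)
  expect_equal(tal$n, 4L)
  expect_equal(tal$n_incomparable, 0L)

  # treated censored before the untreated death: incomparable
  tal2 <- count_wins(5, 0, 7, 1)
  expect_equal(tal2$n, 0L)
  expect_equal(tal2$n_incomparable, 1L)

  # treated censored after the untreated death: a treated win
  tal3 <- count_wins(9, 0, 3, 1)
  expect_equal(c(tal3$gamma, tal3$n), c(1L, 1L))

  # equal times: comparable only when exactly one is a death, which loses
  expect_equal(count_wins(4, 1, 4, 0)$n, 1L)
  expect_equal(count_wins(4, 1, 4, 0)$gamma, 0L)
  expect_equal(count_wins(4, 0, 4, 1)$gamma, 1L)
  expect_equal(count_wins(4, 1, 4, 1)$n, 0L)
  expect_equal(count_wins(4, 0, 4, 0)$n, 0L)

  # empty arm: a zero tally, not an error
  tal4 <- count_wins(numeric(0), numeric(0), c(1, 2), c(1, 1))
  expect_equal(tal4$n, 0L)
})

test_that("count_wins equals the brute-force double loop (property)", {
  set.seed(123)
  for (i in 1:40) {
    inst <- random_win_instance(30L)
    got <- count_wins(inst$t1, inst$e1, inst$t0, inst$e0)
    want <- brute_force_wins(inst$t1, inst$e1, inst$t0, inst$e0)
    expect_equal(got$gamma, want$gamma)
    expect_equal(got$n, want$n)
    expect_equal(got$n + got$n_incomparable,
                 length(inst$t1) * length(inst$t0))
  }
})

test_that("swapping arms mirrors the tally (symmetry property)", {
  set.seed(321)
  for (i in 1:20) {
    inst <- random_win_instance(15L)
    fwd <- count_wins(inst$t1, inst$e1, inst$t0, inst$e0)
    rev <- count_wins(inst$t0, inst$e0, inst$t1, inst$e1)
    expect_equal(rev$n, fwd$n)
    expect_equal(rev$gamma, fwd$n - fwd$gamma)
    # posterior mirrors Beta(a,b) -> Beta(b,a); BF is invariant
    pf <- update_posterior(c(1, 1), fwd)
    pr <- update_posterior(c(1, 1), rev)
    expect_equal(c(pr$alpha, pr$beta), c(pf$beta, pf$alpha))
    expect_equal(bayes_factor(rev), bayes_factor(fwd), tolerance = 1e-12)
  }
})

test_that("conjugate update is exact and order-invariant", {
  post <- update_posterior(c(1, 1), 3, n = 10)
  expect_equal(c(post$alpha, post$beta), c(4, 8))
  expect_equal(posterior_mean(post), 4 / 12)

  empty <- update_posterior(c(2.5, 7), 0, n = 0)
  expect_equal(c(empty$alpha, empty$beta), c(2.5, 7))

  allwins <- update_posterior(c(1, 1), 5, n = 5)
  expect_equal(c(allwins$alpha, allwins$beta), c(6, 1))
  expect_equal(posterior_mean(allwins), 6 / 7)

  # splitting a tally and updating twice equals one pooled update
  set.seed(9)
  for (i in 1:25) {
    n1 <- sample(0:50, 1); g1 <- sample(0:n1, 1)
    n2 <- sample(0:50, 1); g2 <- sample(0:n2, 1)
    two <- update_posterior(update_posterior(c(1, 1), g1, n = n1), g2, n = n2)
    one <- update_posterior(c(1, 1), g1 + g2, n = n1 + n2)
    expect_identical(c(two$alpha, two$beta), c(one$alpha, one$beta))
  }
})

test_that("credible intervals invert the incomplete beta", {
  expect_equal(credible_interval(beta_posterior(1, 1)),
               c(lower = 0.025, upper = 0.975), tolerance = 1e-12)

  ci <- credible_interval(beta_posterior(4, 8))
  expect_equal(unname(ci["lower"]), bisect_beta_quantile(0.025, 4, 8),
               tolerance = 1e-6)
  expect_equal(unname(ci["upper"]), bisect_beta_quantile(0.975, 4, 8),
               tolerance = 1e-6)

  # narrowing level collapses toward the median
  med <- qbeta(0.5, 4, 8)
  tight <- credible_interval(beta_posterior(4, 8), level = 1e-6)
  expect_lt(tight["upper"] - tight["lower"], 1e-5)
  expect_lt(abs(mean(tight) - med), 1e-5)

  # bounds are monotone nondecreasing in gamma at fixed n
  lows <- highs <- numeric(21)
  for (g in 0:20) {
    ci <- credible_interval(update_posterior(c(1, 1), g, n = 20))
    lows[g + 1] <- ci["lower"]; highs[g + 1] <- ci["upper"]
  }
  expect_true(all(diff(lows) > 0))
  expect_true(all(diff(highs) > 0))

  # the mean lies inside the equal-tailed bounds for alpha, beta >= 1
  set.seed(2)
  for (i in 1:20) {
    p <- beta_posterior(1 + rexp(1, 0.1), 1 + rexp(1, 0.1))
    ci <- credible_interval(p)
    m <- posterior_mean(p)
    expect_true(ci["lower"] <= m && m <= ci["upper"])
  }
})

test_that("Bayes factor matches an independent density oracle", {
  expect_equal(bayes_factor(0, n = 0), 1)

  # prior (1,1), gamma 3, n 10: BF = 1 / dbeta(0.5; 4, 8), evaluated by an
  # independent log-gamma computation
  bf <- bayes_factor(3, n = 10)
  expect_equal(bf, exp(-log_dbeta_half(4, 8)), tolerance = 1e-12)

  # perfectly balanced tallies at large n accumulate evidence FOR the null
  expect_lt(bayes_factor(100, n = 200), 1)
  expect_lt(bayes_factor(100, n = 200), bayes_factor(10, n = 20))
})

test_that("Savage-Dickey and marginal-likelihood routes agree to 1e-10", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(0:200, 1); g <- sample(0:n, 1)
    prior <- beta_posterior(runif(1, 0.5, 3), runif(1, 0.5, 3))
    sd <- bayes_factor(g, prior, method = "savage-dickey", log = TRUE, n = n)
    ml <- bayes_factor(g, prior, method = "marginal", log = TRUE, n = n)
    expect_equal(sd, ml, tolerance = 1e-10)
  }
})

test_that("selection applies the gates and documented tie-breaks", {
  mk <- function(key, ci_low, ci_high, bf, n) {
    data.frame(key = key, ci_low = ci_low, ci_high = ci_high, bf = bf,
               n = n)
  }
  res <- rbind(
    mk(1, 0.62, 0.90, 10, 50),   # qualifies for optimal
    mk(2, 0.70, 0.95, 2, 50),    # fails BF gate
    mk(3, 0.70, 0.95, 10, 5),    # fails min_n
    mk(4, 0.10, 0.45, 10, 50),   # qualifies for worst
    mk(5, 0.40, 0.60, 10, 50)    # straddles 0.5: neither
  )
  expect_equal(select_optimal(res)$key, 1)
  expect_equal(select_worst(res)$key, 4)
  expect_null(select_optimal(mk(9, 0.7, 0.9, 2, 50)))
  expect_null(select_worst(res[res$key != 4, ]))
  expect_null(select_optimal(res[0, ]))

  # ties: larger n wins, then smaller key
  tie <- rbind(mk(7, 0.70, 0.9, 10, 30), mk(6, 0.70, 0.9, 10, 40),
               mk(5, 0.70, 0.9, 10, 40))
  expect_equal(select_optimal(tie)$key, 5)
})
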