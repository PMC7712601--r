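# Propensity fitting, caliper matching, and balance diagnostics.

test_that("logistic fit matches glm and a brute-force optimizer", {
  co <- small_cohort(n = 200, seed = 8,
                     propensity_coefs = c(0.2, 0.8, 0, -0.5, rep(0, 6)))
  fit <- fit_propensity(co, "chemo")
  expect_true(fit$converged)

  bits <- dichotomize(co, "chemo")
  ref <- glm(co$chemo ~ bits, family = binomial())
  expect_equal(unname(c(fit$intercept, fit$coefs)),
               unname(coef(ref)), tolerance = 1e-6)

  # independent generic-optimizer (gradient BFGS) maximum of the likelihood
  X <- cbind(1, bits)
  opt <- optim(rep(0, 10), function(b) -logistic_loglik(b, X, co$chemo),
               gr = function(b) {
                 -drop(crossprod(X, co$chemo - plogis(drop(X %*% b))))
               },
               method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
  expect_equal(logistic_loglik(c(fit$intercept, fit$coefs), X, co$chemo),
               -opt$value, tolerance = 1e-4)

  # small-instance cross-check: 20 records, 2 covariates
  idx <- 1:20
  y20 <- co$chemo[idx]
  X20 <- cbind(1, bits[idx, c("age_over_20", "male"), drop = FALSE])
  opt20 <- optim(rep(0, 3), function(b) -logistic_loglik(b, X20, y20),
                 gr = function(b) {
                   -drop(crossprod(X20, y20 - plogis(drop(X20 %*% b))))
                 },
                 method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
  fit20 <- suppressWarnings(glm(y20 ~ X20 - 1, family = binomial()))
  expect_equal(logistic_loglik(unname(coef(fit20)), X20, y20),
               -opt20$value, tolerance = 1e-4)
})

test_that("null assignment recovers near-zero coefficients", {
  co <- small_cohort(n = 5000, seed = 17)
  fit <- fit_propensity(co, "chemo")
  expect_true(fit$converged)
  expect_lt(max(abs(c(fit$intercept, fit$coefs))), 0.2)
})

test_that("a planted log-odds coefficient of 1.5 is recovered within 0.2", {
  est <- vapply(1:3, function(s) {
    co <- small_cohort(n = 5000, seed = 100 + s,
                       propensity_coefs = c(0, 1.5, rep(0, 8)))
    fit_propensity(co, "chemo")$coefs[["age_over_20"]]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.5), 0.2)
})

test_that("degenerate arms and separation are handled", {
  df <- toy_cohort_df()
  df$chemo <- 1L
  expect_error(fit_propensity(as_cohort(df), "chemo"), "arms")

  # quasi-separated instance: treatment determined by one bit
  co <- small_cohort(n = 80, seed = 3)
  co$chemo <- dichotomize(co, "chemo")[, "male"]
  if (all(co$chemo %in% 0:1) && var(co$chemo) > 0) {
    fit <- suppressWarnings(fit_propensity(co, "chemo"))
    expect_false(fit$converged)
    expect_true(all(is.finite(c(fit$intercept, fit$coefs))))
  }
})

test_that("matching pairs identical scores and respects the caliper", {
  scores <- c(0.4, 0.6, 0.4, 0.6)
  treated <- c(1, 1, 0, 0)
  m <- match_propensity(scores, treated, caliper_mult = 0.2, seed = 1)
  expect_equal(nrow(m$pairs), 2L)
  expect_equal(m$n_unmatched_treated, 0L)
  expect_true(all(abs(qlogis(m$pairs$score_t) - qlogis(m$pairs$score_c)) <=
                    m$caliper_used))

  # a treated score far outside the caliper stays unmatched
  scores2 <- c(0.99, 0.30, 0.31, 0.32)
  m2 <- suppressWarnings(
    match_propensity(scores2, c(1, 0, 0, 0), caliper_mult = 0.2, seed = 1))
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$n_unmatched_treated, 1L)
  expect_warning(match_propensity(scores2, c(1, 0, 0, 0),
                                  caliper_mult = 0.2, seed = 1),
                 "no admissible")
})

test_that("matching is without replacement and caliper-faithful at scale", {
  co <- small_cohort(n = 1000, seed = 23,
                     propensity_coefs = c(0, 1, -1, 0.5, rep(0, 6)))
  fit <- fit_propensity(co, "chemo")
  m <- match_propensity(fit$scores, co$chemo, ids = co$id, seed = 7)
  expect_gt(nrow(m$pairs), 0L)
  expect_false(anyDuplicated(m$pairs$control_id) > 0)
  expect_false(anyDuplicated(m$pairs$treated_id) > 0)
  expect_true(all(abs(qlogis(m$pairs$score_t) - qlogis(m$pairs$score_c)) <=
                    m$caliper_used + 1e-12))
})

test_that("standardized differences follow the binary SMD formula", {
  # direct formula oracle: p1 = 0.6, p0 = 0.4
  oracle <- (0.6 - 0.4) / sqrt((0.6 * 0.4 + 0.4 * 0.6) / 2)
  expect_equal(oracle, 0.40824829, tolerance = 1e-6)

  n <- 200
  df <- small_cohort(n = 2 * n, seed = 5)
  bits <- dichotomize(df, "chemo")
  # engineer arms with exact proportions on one covariate
  df$chemo <- rep(c(1L, 0L), each = n)
  df$sex <- c(rep(c("male", "female"), c(0.6 * n, 0.4 * n)),
              rep(c("male", "female"), c(0.4 * n, 0.6 * n)))
  tab <- standardized_differences(df, "chemo")
  expect_equal(tab$smd_unmatched[tab$covariate == "male"], oracle,
               tolerance = 1e-10)

  # identical arms give all-zero SMDs
  df2 <- rbind(df, df)
  df2$id <- sprintf("x%04d", seq_len(nrow(df2)))
  df2$chemo <- rep(c(1L, 0L), each = nrow(df))
  tab2 <- standardized_differences(df2, "chemo")
  expect_equal(tab2$smd_unmatched, rep(0, 9))

  # degenerate covariate identical in both arms scores 0
  df3 <- df
  df3$surgery <- 1L
  tab3 <- standardized_differences(df3, "chemo")
  expect_equal(tab3$smd_unmatched[tab3$covariate == "surgery"], 0)
})

test_that("matching improves worst-case balance on a confounded cohort", {
  better <- vapply(1:3, function(s) {
    co <- small_cohort(n = 1500, seed = 200 + s,
                       propensity_coefs = c(-1.1, 1, 0.8, -0.8, 0.5,
                                            rep(0, 5)))
    fit <- fit_propensity(co, "chemo")
    m <- match_propensity(fit$scores, co$chemo, seed = s)
    tab <- standardized_differences(co, "chemo", m)
    max(abs(tab$smd_matched)) < max(abs(tab$smd_unmatched))
  }, logical(1))
  expect_true(all(better))
})
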