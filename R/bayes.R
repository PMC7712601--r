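# Concordance win counting under right censoring, conjugate beta-binomial
# posterior updating, Savage-Dickey Bayes factors against the no-effect
# point (win probability 0.5), and credible-bound subgroup selection.

#' Beta distribution over a win probability
#'
#' @param alpha,beta Positive shape parameters.
#' @return A `beta_posterior` list with elements `alpha` and `beta`.
#' @export
beta_posterior <- function(alpha = 1, beta = 1) {
  stopifnot(is.finite(alpha), is.finite(beta), alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "beta_posterior")
}

.as_beta <- function(prior) {
  if (inherits(prior, "beta_posterior")) return(prior)
  stopifnot(is.numeric(prior), length(prior) == 2L)
  beta_posterior(prior[1], prior[2])
}

#' @export
print.beta_posterior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g), mean %.4f\n", x$alpha, x$beta,
              posterior_mean(x)))
  invisible(x)
}

#' Posterior mean of a beta distribution
#' @param posterior A [beta_posterior()].
#' @return `alpha / (alpha + beta)`.
#' @export
posterior_mean <- function(posterior) {
  posterior <- .as_beta(posterior)
  posterior$alpha / (posterior$alpha + posterior$beta)
}

#' Count concordance wins between treated and untreated survival records
#'
#' Every treated x untreated pair is examined.  A pair is *comparable* when
#' the ordering of the two survival times is determinable under right
#' censoring: the smaller observed time must end in death.  Concretely, with
#' treated observation `(t1, e1)` and untreated `(t0, e0)`:
#' * `t1 < t0`: comparable iff `e1 = 1` (the treated death is a loss);
#' * `t1 > t0`: comparable iff `e0 = 1` (the treated subject wins whether it
#'   later dies or is censored);
#' * `t1 = t0`: comparable iff exactly one is a death, the death losing.
#' Incomparable pairs are excluded from `n` (the information loss is
#' reported as `n_incomparable`), so `(gamma, n)` keeps a binomial reading.
#'
#' @param time_treated,event_treated Treated arm times and event flags.
#' @param time_untreated,event_untreated Untreated arm times and event flags.
#' @return A `win_tally` list: `gamma` (treated wins), `n` (comparable
#'   pairs), `n_incomparable`, `n_treated`, `n_untreated`.  Empty arms give
#'   `n = 0`, not an error.
#' @export
count_wins <- function(time_treated, event_treated,
                       time_untreated, event_untreated) {
  stopifnot(length(time_treated) == length(event_treated),
            length(time_untreated) == length(event_untreated))
  n1 <- length(time_treated); n0 <- length(time_untreated)
  if (n1 == 0L || n0 == 0L) {
    return(structure(list(gamma = 0L, n = 0L, n_incomparable = 0L,
                          n_treated = n1, n_untreated = n0),
                     class = "win_tally"))
  }
  stopifnot(all(event_treated %in% c(0, 1)),
            all(event_untreated %in% c(0, 1)))
  T1 <- matrix(time_treated, n1, n0)
  T0 <- matrix(time_untreated, n1, n0, byrow = TRUE)
  E1 <- matrix(event_treated == 1, n1, n0)
  E0 <- matrix(event_untreated == 1, n1, n0, byrow = TRUE)
  comparable <- (T1 < T0 & E1) | (T1 > T0 & E0) | (T1 == T0 & xor(E1, E0))
  win <- (T1 > T0 & E0) | (T1 == T0 & E0 & !E1)
  structure(list(gamma = sum(win), n = sum(comparable),
                 n_incomparable = n1 * n0 - sum(comparable),
                 n_treated = n1, n_untreated = n0),
            class = "win_tally")
}

#' Conjugate beta-binomial posterior update
#'
#' `Beta(alpha, beta)` prior with `gamma` wins out of `n` comparable pairs
#' yields `Beta(alpha + gamma, beta + n - gamma)`.  The default prior is the
#' uniform `Beta(1, 1)` (no prior knowledge of the treatment outcome).
#'
#' @param prior A [beta_posterior()] or length-2 numeric `c(alpha, beta)`.
#' @param tally A `win_tally` from [count_wins()], or a single win count
#'   (then `n` must be given).
#' @param n Number of observations when `tally` is a bare win count.
#' @return The posterior [beta_posterior()].
#' @export
update_posterior <- function(prior = beta_posterior(1, 1), tally, n = NULL) {
  prior <- .as_beta(prior)
  if (inherits(tally, "win_tally")) {
    gamma <- tally$gamma; n <- tally$n
  } else {
    gamma <- tally
    if (is.null(n)) stop("n must be supplied with a bare win count",
                         call. = FALSE)
  }
  stopifnot(gamma >= 0, n >= gamma)
  beta_posterior(prior$alpha + gamma, prior$beta + n - gamma)
}

#' Equal-tailed credible interval of a beta distribution
#'
#' Cuts probability `(1 - level)/2` from each tail by inverting the
#' regularized incomplete beta function.
#'
#' @param posterior A [beta_posterior()].
#' @param level Credibility level in (0, 1), default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
credible_interval <- function(posterior, level = 0.95) {
  posterior <- .as_beta(posterior)
  stopifnot(level > 0, level < 1)
  a <- (1 - level) / 2
  c(lower = stats::qbeta(a, posterior$alpha, posterior$beta),
    upper = stats::qbeta(1 - a, posterior$alpha, posterior$beta))
}

#' Bayes factor against the no-effect point (win probability 0.5)
#'
#' `BF10` compares H1 (the win probability Y is free, with the given beta
#' prior) against the point null H0: Y = 0.5.  Two algebraically equivalent
#' routes are implemented: the Savage-Dickey density ratio (prior density at
#' 0.5 over posterior density at 0.5) and the ratio of the beta-binomial
#' marginal likelihood to `Binomial(n, 0.5)`; their agreement is asserted in
#' the test suite to 1e-10.  With no data (`n = 0`) the factor is 1.
#'
#' @inheritParams update_posterior
#' @param method `"savage-dickey"` (default) or `"marginal"`.
#' @param log Return the natural log of the Bayes factor?
#' @return Positive scalar (or its log).
#' @export
bayes_factor <- function(tally, prior = beta_posterior(1, 1),
                         method = c("savage-dickey", "marginal"),
                         log = FALSE, n = NULL) {
  method <- match.arg(method)
  prior <- .as_beta(prior)
  if (inherits(tally, "win_tally")) {
    gamma <- tally$gamma; n <- tally$n
  } else {
    gamma <- tally
    if (is.null(n)) stop("n must be supplied with a bare win count",
                         call. = FALSE)
  }
  stopifnot(gamma >= 0, n >= gamma)
  if (n == 0) return(if (log) 0 else 1)
  lbf <- if (method == "savage-dickey") {
    stats::dbeta(0.5, prior$alpha, prior$beta, log = TRUE) -
      stats::dbeta(0.5, prior$alpha + gamma, prior$beta + n - gamma,
                   log = TRUE)
  } else {
    # log m1 - log m0; the binomial coefficient cancels
    (lbeta(prior$alpha + gamma, prior$beta + n - gamma) -
       lbeta(prior$alpha, prior$beta)) + n * log(2)
  }
  if (log) lbf else exp(lbf)
}

#' Per-subgroup win tallies, posteriors and Bayes factors
#'
#' Stratifies the cohort on the nine covariate bits, counts concordance wins
#' in every non-empty cell, and returns one row per cell with the conjugate
#' posterior, equal-tailed credible bounds, and the Bayes factor against
#' win probability 0.5.
#'
#' @inheritParams stratify
#' @param prior Beta prior, default uniform `c(1, 1)`.
#' @param level Credibility level (default 0.95).
#' @return A `subgroup_results` data frame with columns `key`, `profile`,
#'   `n_treated`, `n_untreated`, `gamma`, `n`, `n_incomparable`, `alpha`,
#'   `beta`, `mean`, `ci_low`, `ci_high`, `bf`.
#' @export
subgroup_results <- function(cohort, treatment = c("chemo", "rt"),
                             prior = c(1, 1), level = 0.95,
                             advanced_stages = 3L) {
  treatment <- match.arg(treatment)
  prior <- .as_beta(prior)
  cells <- stratify(cohort, treatment, advanced_stages)
  rows <- lapply(names(cells), function(k) {
    cell <- cells[[k]]
    tally <- count_wins(cell$treated$time_months, cell$treated$event,
                        cell$untreated$time_months, cell$untreated$event)
    post <- update_posterior(prior, tally)
    ci <- credible_interval(post, level)
    data.frame(key = as.integer(k),
               n_treated = tally$n_treated, n_untreated = tally$n_untreated,
               gamma = tally$gamma, n = tally$n,
               n_incomparable = tally$n_incomparable,
               alpha = post$alpha, beta = post$beta,
               mean = posterior_mean(post),
               ci_low = unname(ci["lower"]), ci_high = unname(ci["upper"]),
               bf = bayes_factor(tally, prior))
  })
  out <- do.call(rbind, rows)
  out <- cbind(key = out$key, profile = describe_subgroup(out$key),
               out[, -1, drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("subgroup_results", "data.frame")
  attr(out, "treatment") <- treatment
  attr(out, "prior") <- c(prior$alpha, prior$beta)
  attr(out, "level") <- level
  out
}

.select_candidates <- function(results, bf_threshold, min_n) {
  stopifnot(is.data.frame(results))
  results[results$bf > bf_threshold & results$n >= min_n, , drop = FALSE]
}

#' Select the optimal subgroup for a treatment
#'
#' Among subgroups passing the evidence gate (Bayes factor above
#' `bf_threshold`, the "substantial" mark being 3, and at least `min_n`
#' comparable pairs), keeps those whose lower 95% credible bound on the win
#' probability exceeds 0.5 and returns the one with the highest lower bound
#' (ties broken by larger `n`, then smaller key).
#'
#' @param results A `subgroup_results` data frame.
#' @param bf_threshold Bayes-factor gate (default 3).
#' @param min_n Minimum comparable-pair count (default 10); set 0 to allow
#'   selection on vacuously wide intervals.
#' @return A one-row data frame, or `NULL` when no subgroup qualifies.
#' @export
select_optimal <- function(results, bf_threshold = 3, min_n = 10L) {
  cand <- .select_candidates(results, bf_threshold, min_n)
  cand <- cand[cand$ci_low > 0.5, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand[order(-cand$ci_low, -cand$n, cand$key), , drop = FALSE][1, ,
                                                               drop = FALSE]
}

#' Select the worst subgroup for a treatment
#'
#' Mirror of [select_optimal()]: requires the upper 95% credible bound on
#' the win probability to fall below 0.5 and returns the subgroup with the
#' lowest upper bound.  `NULL` when none qualifies (an expected outcome, not
#' an error).
#'
#' @inheritParams select_optimal
#' @return A one-row data frame, or `NULL`.
#' @export
select_worst <- function(results, bf_threshold = 3, min_n = 10L) {
  cand <- .select_candidates(results, bf_threshold, min_n)
  cand <- cand[cand$ci_high < 0.5, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand[order(cand$ci_high, -cand$n, cand$key), , drop = FALSE][1, ,
                                                               drop = FALSE]
}
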