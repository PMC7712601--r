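# Kaplan-Meier estimation, (stratified) log-rank testing, and an O/E
# hazard-ratio summary.  Deliberately self-contained: the formulas are fully
# specified here and cross-checked against the 'survival' package in the
# test suite only.

#' Kaplan-Meier product-limit estimate
#'
#' Computes `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct times
#' with at least one death, together with the Greenwood variance
#' `S(t)^2 * sum d_i / (n_i (n_i - d_i))`.  Records censored at a death time
#' are counted as at risk for that time and removed afterwards.
#'
#' @param time Non-negative follow-up times.
#' @param event Binary event indicators (1 = death, 0 = censored).
#' @return A `km_curve` data frame with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `greenwood_var`; attribute `n` holds the sample
#'   size.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (!length(time)) stop("empty input", call. = FALSE)
  stopifnot(all(time >= 0), all(event %in% c(0, 1)))
  n <- length(time)
  ut <- sort(unique(time))
  d <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  c_ <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  at_risk <- n - c(0, cumsum(d + c_))[seq_along(ut)]
  keep <- d > 0
  surv <- cumprod(1 - d[keep] / at_risk[keep])
  gw <- surv^2 * cumsum(d[keep] / (at_risk[keep] *
                                     pmax(at_risk[keep] - d[keep], 1e-300)))
  out <- data.frame(time = ut[keep], n_risk = at_risk[keep],
                    n_event = d[keep], n_censor = c_[keep],
                    survival = surv, greenwood_var = gw)
  class(out) <- c("km_curve", "data.frame")
  attr(out, "n") <- n
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `km_curve` from [kaplan_meier()].
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first death).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (!length(i)) 1 else curve$survival[max(i)]
  }, numeric(1))
}

# O, E and V per arm for one stratum; hypergeometric variance with the
# standard multi-death tie correction.
.logrank_stratum <- function(time, event, g1) {
  dt <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- d_tot <- 0
  for (t in dt) {
    at <- time >= t
    n_all <- sum(at)
    n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n_all
    if (n_all > 1) {
      v <- v + d * (n1 / n_all) * (1 - n1 / n_all) * (n_all - d) / (n_all - 1)
    }
    d_tot <- d_tot + d
  }
  c(o1 = o1, e1 = e1, v = v, d = d_tot)
}

#' Log-rank test, optionally stratified
#'
#' At each distinct death time the observed number of deaths in group 1 is
#' compared with its hypergeometric expectation given the at-risk counts;
#' the statistic is `(sum(O - E))^2 / sum(V)` on one degree of freedom.  With
#' strata, O - E and V are summed over strata before squaring (the stratified
#' test used to compare matched arms, each matched pair being one stratum).
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level grouping vector; the first level in sort order is
#'   "group 1".
#' @param strata Optional stratum labels.
#' @return A `logrank_test` list: `statistic`, `p_value`, `observed`,
#'   `expected` (length-2 vectors, group 1 then group 2), `variance`, and
#'   `per_stratum` (data frame of contributions).
#' @export
logrank <- function(time, event, group, strata = NULL) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2L) stop("group must have exactly two levels",
                              call. = FALSE)
  g1 <- as.character(group) == lev[1]
  if (!any(g1) || all(g1)) stop("both groups must be non-empty",
                                call. = FALSE)
  if (is.null(strata)) strata <- rep(1L, length(time))
  parts <- lapply(split(seq_along(time), strata), function(idx) {
    .logrank_stratum(time[idx], event[idx], g1[idx])
  })
  tab <- do.call(rbind, parts)
  o1 <- sum(tab[, "o1"]); e1 <- sum(tab[, "e1"]); v <- sum(tab[, "v"])
  d <- sum(tab[, "d"])
  if (v <= 0) {
    if (d > 0) warning("zero log-rank variance", call. = FALSE)
    stat <- 0; p <- 1
  } else {
    stat <- (o1 - e1)^2 / v
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(
    statistic = stat, p_value = p,
    observed = stats::setNames(c(o1, d - o1), lev),
    expected = stats::setNames(c(e1, d - e1), lev),
    variance = v,
    per_stratum = data.frame(stratum = rownames(tab),
                             o_minus_e = tab[, "o1"] - tab[, "e1"],
                             v = tab[, "v"], row.names = NULL)
  ), class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  observed %s vs expected %s\n",
              paste(round(x$observed, 2), collapse = "/"),
              paste(round(x$expected, 2), collapse = "/")))
  invisible(x)
}

#' O/E (Mantel-Haenszel-type) hazard ratio with 95% confidence interval
#'
#' `HR = (O1/E1) / (O2/E2)` from the log-rank observed and expected death
#' counts, with a log-scale confidence interval using
#' `SE = sqrt(1/E1 + 1/E2)`.  When any of the four counts is zero the ratio
#' is undefined and the result is flagged rather than an error raised.
#'
#' @inheritParams logrank
#' @param conf_level Confidence level (default 0.95).
#' @return A `hazard_ratio` list: `hr`, `ci_low`, `ci_high`, `defined`,
#'   `observed`, `expected`.
#' @export
hazard_ratio <- function(time, event, group, conf_level = 0.95) {
  lr <- logrank(time, event, group)
  o <- lr$observed; e <- lr$expected
  if (sum(o) == 0) stop("no deaths in either group", call. = FALSE)
  defined <- all(o > 0) && all(e > 0)
  if (defined) {
    hr <- (o[1] / e[1]) / (o[2] / e[2])
    se <- sqrt(1 / e[1] + 1 / e[2])
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(hr) + c(-1, 1) * z * se)
  } else {
    hr <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  structure(list(hr = unname(hr), ci_low = ci[1], ci_high = ci[2],
                 defined = defined, observed = o, expected = e),
            class = "hazard_ratio")
}

#' @export
print.hazard_ratio <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("O/E hazard ratio: %.3f (95%% CI %.3f-%.3f)\n",
                x$hr, x$ci_low, x$ci_high))
  } else {
    cat("O/E hazard ratio: undefined (zero observed or expected deaths)\n")
  }
  invisible(x)
}
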