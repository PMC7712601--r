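# Propensity-score estimation, greedy caliper matching, and covariate
# balance diagnostics.

#' Fit a logistic propensity model on the nine covariate bits
#'
#' Maximum-likelihood logistic regression of the treatment indicator on the
#' nine dichotomized covariates, fitted by Newton-Raphson.  Convergence is
#' declared when the largest absolute score (gradient) component falls below
#' `1e-8`; iteration stops after 100 steps.  Quasi-separation is flagged by
#' a non-converged result carrying the last stable iterate.
#'
#' @param cohort An imputed `cohort` data frame.
#' @param treatment `"chemo"` or `"rt"`; both arms must be non-empty.
#' @param advanced_stages Passed to [dichotomize()].
#' @return A `propensity_model` list with elements `intercept`, `coefs`
#'   (named length-9), `converged`, `n_iter`, and `scores` (fitted
#'   per-record propensities, in record order).
#' @export
fit_propensity <- function(cohort, treatment = c("chemo", "rt"),
                           advanced_stages = 3L) {
  treatment <- match.arg(treatment)
  df <- as.data.frame(cohort)
  y <- df[[treatment]]
  if (all(y == 1L) || all(y == 0L)) {
    stop("both treatment arms must be non-empty", call. = FALSE)
  }
  bits <- dichotomize(df, treatment, advanced_stages)
  X <- cbind(`(intercept)` = 1, bits)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(100L)) {
    n_iter <- it
    p <- stats::plogis(drop(X %*% beta))
    score <- drop(crossprod(X, y - p))
    if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    beta_new <- beta + step
    if (max(abs(beta_new)) > 30) break  # diverging: separation
    beta <- beta_new
  }
  scores <- stats::plogis(drop(X %*% beta))
  structure(list(
    intercept = unname(beta[1]),
    coefs = stats::setNames(beta[-1], colnames(bits)),
    converged = converged,
    n_iter = n_iter,
    scores = scores,
    treatment = treatment
  ), class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("Logistic propensity model for '%s' (%s, %d iterations)\n",
              x$treatment,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(round(c(`(intercept)` = x$intercept, x$coefs), 4))
  invisible(x)
}

#' Greedy 1:1 caliper matching on the logit propensity score
#'
#' Treated records are processed in descending score order (hardest to match
#' first; ties shuffled by the seed) and each is paired with the nearest
#' still-unused control on the logit scale, provided the distance is within
#' the caliper `caliper_mult * SD(logit(score))`.  Matching is without
#' replacement; treated records with no admissible control are counted, and
#' an empty matching yields a warning rather than an error.
#'
#' @param scores Per-record propensity scores in (0, 1).
#' @param treated Binary (0/1 or logical) treatment labels, same length.
#' @param ids Optional record ids (default: indices).
#' @param caliper_mult Caliper width as a multiple of the SD of the logit
#'   score (default 0.2, the conventional rule).
#' @param seed Integer seed used only to break score ties in the processing
#'   order.
#' @return A `matched_set` list: `pairs` (data frame `treated_id,
#'   control_id, score_t, score_c`), `caliper_used` (on the logit scale),
#'   and `n_unmatched_treated`.
#' @export
match_propensity <- function(scores, treated, ids = NULL,
                             caliper_mult = 0.2, seed = 1L) {
  stopifnot(all(scores > 0), all(scores < 1),
            length(scores) == length(treated))
  treated <- as.integer(treated)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  lg <- stats::qlogis(scores)
  caliper <- caliper_mult * stats::sd(lg)
  if (!is.finite(caliper)) caliper <- 0
  t_idx <- which(treated == 1L)
  c_idx <- which(treated == 0L)
  set.seed(as.integer(seed))
  t_idx <- t_idx[order(-lg[t_idx], stats::runif(length(t_idx)))]
  avail <- rep(TRUE, length(c_idx))
  pairs_t <- integer(0); pairs_c <- integer(0)
  for (i in t_idx) {
    if (!any(avail)) break
    open <- c_idx[avail]
    d <- abs(lg[open] - lg[i])
    j <- which.min(d)
    if (d[j] <= caliper) {
      pairs_t <- c(pairs_t, i)
      pairs_c <- c(pairs_c, open[j])
      avail[match(open[j], c_idx)] <- FALSE
    }
  }
  if (!length(pairs_t)) {
    warning("no admissible matches within the caliper", call. = FALSE)
  }
  structure(list(
    pairs = data.frame(treated_id = ids[pairs_t], control_id = ids[pairs_c],
                       score_t = scores[pairs_t], score_c = scores[pairs_c],
                       stringsAsFactors = FALSE),
    treated_index = pairs_t,
    control_index = pairs_c,
    caliper_used = caliper,
    n_unmatched_treated = length(t_idx) - length(pairs_t)
  ), class = "matched_set")
}

.smd_binary <- function(p1, p0) {
  v <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
  ifelse(v <= 0, 0, (p1 - p0) / sqrt(v))
}

#' Standardized mean differences of the nine covariate bits
#'
#' Balance diagnostic between treatment arms: for a binary covariate with
#' arm proportions `p1`, `p0`, `SMD = (p1 - p0) / sqrt((p1(1-p1) +
#' p0(1-p0))/2)`; degenerate covariates (identical in both arms, including
#' all-0 or all-1) score 0.  When a matched set is supplied the SMDs are also
#' computed on the paired subset.
#'
#' @inheritParams fit_propensity
#' @param matched Optional `matched_set` from [match_propensity()] (built on
#'   the same record order).
#' @return Data frame with columns `covariate`, `smd_unmatched` and (when
#'   `matched` is given) `smd_matched`.
#' @export
standardized_differences <- function(cohort, treatment = c("chemo", "rt"),
                                     matched = NULL, advanced_stages = 3L) {
  treatment <- match.arg(treatment)
  df <- as.data.frame(cohort)
  bits <- dichotomize(df, treatment, advanced_stages)
  treat <- df[[treatment]]
  smd_of <- function(rows_t, rows_c) {
    p1 <- colMeans(bits[rows_t, , drop = FALSE])
    p0 <- colMeans(bits[rows_c, , drop = FALSE])
    .smd_binary(p1, p0)
  }
  out <- data.frame(covariate = colnames(bits),
                    smd_unmatched = unname(smd_of(which(treat == 1L),
                                                  which(treat == 0L))),
                    stringsAsFactors = FALSE)
  if (!is.null(matched)) {
    out$smd_matched <- if (length(matched$treated_index)) {
      unname(smd_of(matched$treated_index, matched$control_index))
    } else NA_real_
  }
  out
}
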