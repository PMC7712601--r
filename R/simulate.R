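# Synthetic SEER-like cohort generator with planted ground truth.
#
# Weibull proportional-hazards survival with exponential censoring; logistic
# (confounded) treatment assignment on the nine covariate bits; covariate-cell
# specific treatment effects planted through `effect_map`.

.default_prevalences <- c(
  age_over_20 = 0.85, male = 0.49, size_over_5cm = 0.61, extremity = 0.77,
  stage_advanced = 0.13, surgery = 0.90, co_treatment = 0.50,
  spindle = 0.37, biphasic = 0.23
)

.default_log_hazards <- c(
  age_over_20 = 0.30, male = 0.10, size_over_5cm = 0.40, extremity = -0.20,
  stage_advanced = 1.00, surgery = -0.70, co_treatment = 0.00,
  spindle = 0.10, biphasic = -0.10
)

#' Configuration of the synthetic cohort generator
#'
#' Encodes a fully stated simulated world: marginal covariate prevalences,
#' a logistic propensity model for treatment assignment, Weibull
#' proportional-hazards survival (shape shared across arms, so the win
#' probability in a cell with treatment hazard ratio `r` is exactly
#' `1 / (1 + r)`), exponential censoring, and covariate missingness.
#'
#' Defaults emulate a registry sarcoma cohort: mostly adult (85% over 20),
#' balanced sex, 61% large tumors, 77% extremity, 13% distant stage, 90%
#' resected, baseline survival Weibull(shape 1.2, scale 60 months), censoring
#' at rate 0.01/month (long registry follow-up), and 5% of covariate entries
#' missing.
#'
#' @param n Cohort size.
#' @param seed Integer master seed (< 2^31 - 10); labelled substreams for
#'   covariates, treatment, survival, censoring and masking are derived from
#'   it, so changing `missing_frac` does not perturb the survival draws.
#' @param treatment Which treatment column carries the simulated assignment
#'   (`"chemo"` or `"rt"`); the other is drawn as the `co_treatment` bit.
#' @param prevalences Nine marginal Bernoulli probabilities in the bit order
#'   of [covariate_names()]; `spindle + biphasic` must be < 1 (they come from
#'   one three-category histology draw).
#' @param propensity_coefs Length-10 vector: intercept then nine log-odds
#'   coefficients of treatment assignment on the covariate bits.
#' @param baseline_shape,baseline_scale Weibull parameters of untreated
#'   reference survival, in months.
#' @param covariate_log_hazards Nine log-hazard coefficients of the bits.
#' @param effect_map Named numeric vector mapping subgroup keys (as names)
#'   to treatment log-hazard-ratios; cells not named have no effect.
#' @param censor_rate Exponential censoring rate per month.
#' @param missing_frac Fraction of covariate entries masked at random.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n, seed = 1L, treatment = c("chemo", "rt"),
                              prevalences = .default_prevalences,
                              propensity_coefs = rep(0, 10),
                              baseline_shape = 1.2, baseline_scale = 60,
                              covariate_log_hazards = .default_log_hazards,
                              effect_map = numeric(0),
                              censor_rate = 0.01, missing_frac = 0.05) {
  treatment <- match.arg(treatment)
  stopifnot(n > 0, length(prevalences) == 9L,
            all(prevalences > 0), all(prevalences < 1),
            length(propensity_coefs) == 10L,
            baseline_shape > 0, baseline_scale > 0, censor_rate > 0,
            missing_frac >= 0, missing_frac < 1,
            length(covariate_log_hazards) == 9L)
  if (prevalences[8] + prevalences[9] >= 1) {
    stop("spindle + biphasic prevalence must be < 1", call. = FALSE)
  }
  seed <- as.integer(seed)
  stopifnot(abs(seed) < 2^31 - 10)
  if (length(effect_map)) {
    stopifnot(!is.null(names(effect_map)),
              all(as.integer(names(effect_map)) %in% 0:511))
  }
  structure(list(
    n = as.integer(n), seed = seed, treatment = treatment,
    prevalences = stats::setNames(prevalences, covariate_names()),
    propensity_coefs = propensity_coefs,
    baseline_shape = baseline_shape, baseline_scale = baseline_scale,
    covariate_log_hazards = stats::setNames(covariate_log_hazards,
                                            covariate_names()),
    effect_map = effect_map, censor_rate = censor_rate,
    missing_frac = missing_frac
  ), class = "simulation_config")
}

.cell_effect <- function(effect_map, key) {
  eff <- rep(0, length(key))
  if (length(effect_map)) {
    hit <- match(as.character(key), names(effect_map))
    eff[!is.na(hit)] <- effect_map[hit[!is.na(hit)]]
  }
  eff
}

# Inverse-CDF Weibull PH draw: S(t) = exp(-(t/scale)^shape * exp(lp))
.rweibull_ph <- function(u, shape, scale, lp) {
  scale * (-log(u) / exp(lp))^(1 / shape)
}

#' Generate a synthetic cohort
#'
#' Draws covariate bits independently from their marginal prevalences (the
#' two histology bits from one three-category draw), fills in continuous age
#' and tumor size consistently with the drawn bits (age uniform on (21, 80]
#' or (0.5, 20], size uniform on (5, 20] or (0.5, 5]), assigns treatment from
#' the logistic propensity model, draws Weibull survival with the record's
#' covariate log-hazards plus the treatment effect of its subgroup cell,
#' censors with an independent exponential time, and finally masks
#' `missing_frac` of the imputable covariate entries.  Fully reproducible
#' from the config seed.
#'
#' @param config A [simulation_config()].
#' @return A `cohort` data frame with attribute `truth`: a list holding the
#'   per-record true bits, subgroup key, treatment log-hazard-ratio, and the
#'   config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  sub_seed <- function(k) config$seed + k

  # -- covariates -----------------------------------------------------------
  set.seed(sub_seed(1L))
  bits <- matrix(0L, n, 9L, dimnames = list(NULL, covariate_names()))
  for (j in 1:7) bits[, j] <- stats::rbinom(n, 1L, config$prevalences[j])
  hist_draw <- stats::runif(n)
  p_sp <- config$prevalences[8]; p_bi <- config$prevalences[9]
  histology <- ifelse(hist_draw < p_sp, "spindle",
                      ifelse(hist_draw < p_sp + p_bi, "biphasic", "NOS"))
  bits[, "spindle"]  <- as.integer(histology == "spindle")
  bits[, "biphasic"] <- as.integer(histology == "biphasic")
  age <- ifelse(bits[, "age_over_20"] == 1L,
                stats::runif(n, 21, 80), stats::runif(n, 0.5, 20))
  size <- ifelse(bits[, "size_over_5cm"] == 1L,
                 stats::runif(n, 5.001, 20), stats::runif(n, 0.5, 5))
  stage <- ifelse(bits[, "stage_advanced"] == 1L, 3L,
                  1L + stats::rbinom(n, 1L, 0.3))

  # -- treatment assignment -------------------------------------------------
  set.seed(sub_seed(2L))
  lp_treat <- config$propensity_coefs[1] +
    drop(bits %*% config$propensity_coefs[-1])
  treat <- stats::rbinom(n, 1L, stats::plogis(lp_treat))

  # -- survival and censoring ----------------------------------------------
  key <- subgroup_key(bits)
  loghr <- .cell_effect(config$effect_map, key)
  set.seed(sub_seed(3L))
  lp_surv <- drop(bits %*% config$covariate_log_hazards) + treat * loghr
  t_event <- .rweibull_ph(stats::runif(n), config$baseline_shape,
                          config$baseline_scale, lp_surv)
  set.seed(sub_seed(4L))
  t_censor <- stats::rexp(n, config$censor_rate)
  time <- pmin(t_event, t_censor)
  event <- as.integer(t_event <= t_censor)

  df <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age = age,
    sex = ifelse(bits[, "male"] == 1L, "male", "female"),
    size_cm = size,
    site = ifelse(bits[, "extremity"] == 1L, "extremity", "axial"),
    seer_stage = stage,
    surgery = bits[, "surgery"],
    rt = NA_integer_, chemo = NA_integer_,
    histology = histology,
    time_months = time,
    event = event,
    stringsAsFactors = FALSE
  )
  if (config$treatment == "chemo") {
    df$chemo <- treat; df$rt <- bits[, "co_treatment"]
  } else {
    df$rt <- treat; df$chemo <- bits[, "co_treatment"]
  }

  # -- masking --------------------------------------------------------------
  if (config$missing_frac > 0) {
    set.seed(sub_seed(5L))
    for (f in .imputable_fields) {
      mask <- stats::rbinom(n, 1L, config$missing_frac) == 1L
      df[[f]][mask] <- NA
    }
  }

  out <- .as_cohort(df, provenance = sprintf("synthetic(seed=%d)", config$seed))
  attr(out, "truth") <- list(bits = bits, key = key, loghr = loghr,
                             config = config)
  out
}

#' Closed-form win probability under proportional hazards
#'
#' For two event times with proportional hazards at ratio `hr` (treated vs
#' untreated) and a shared baseline shape, the probability that the treated
#' time is the longer one is `1 / (1 + hr)`.
#'
#' @param hr Positive hazard ratio(s).
#' @return Win probabilities in (0, 1).
#' @export
win_probability_ph <- function(hr) {
  stopifnot(all(hr > 0))
  1 / (1 + hr)
}

#' Monte-Carlo certification of planted win probabilities
#'
#' For each subgroup cell named in the config's `effect_map` (and any extra
#' keys requested), simulates `mc_reps` independent treated/untreated event
#' time pairs under the cell's hazards, without censoring, and returns the
#' fraction of pairs where the treated subject survives longer.  Under the
#' generator's shared-shape Weibull model this must match the closed form
#' [win_probability_ph()] within Monte-Carlo error.
#'
#' @param config A [simulation_config()].
#' @param mc_reps Number of simulated pairs per cell (at least 10^4).
#' @param seed Seed for the certification draws (default: config seed).
#' @param keys Integer keys to certify (default: the planted cells, or cell 0
#'   if no effect is planted).
#' @return Named numeric vector of win probabilities with attribute
#'   `closed_form` holding `1 / (1 + hr)` per cell.
#' @export
planted_truth <- function(config, mc_reps = 10000L, seed = config$seed,
                          keys = NULL) {
  stopifnot(inherits(config, "simulation_config"), mc_reps >= 1e4)
  if (is.null(keys)) {
    keys <- if (length(config$effect_map)) {
      as.integer(names(config$effect_map))
    } else 0L
  }
  set.seed(as.integer(seed) %% (2^31 - 1))
  out <- numeric(length(keys))
  closed <- numeric(length(keys))
  for (i in seq_along(keys)) {
    bits <- key_to_bits(keys[i])
    lp0 <- drop(bits %*% config$covariate_log_hazards)
    loghr <- .cell_effect(config$effect_map, keys[i])
    t0 <- .rweibull_ph(stats::runif(mc_reps), config$baseline_shape,
                       config$baseline_scale, lp0)
    t1 <- .rweibull_ph(stats::runif(mc_reps), config$baseline_shape,
                       config$baseline_scale, lp0 + loghr)
    out[i] <- mean(t1 > t0)
    closed[i] <- win_probability_ph(exp(loghr))
  }
  names(out) <- as.character(keys)
  attr(out, "closed_form") <- stats::setNames(closed, as.character(keys))
  out
}
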