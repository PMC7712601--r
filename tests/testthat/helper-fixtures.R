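# In-code fixtures: every table used by the tests is built programmatically.

toy_cohort_df <- function() {
  data.frame(
    id = c("a", "b", "c", "d"),
    age = c(25, 18, 40, 55),
    sex = c("male", "female", "male", "female"),
    size_cm = c(7, 3, 6, 4),
    site = c("extremity", "axial", "extremity", "extremity"),
    seer_stage = c(3, 1, 2, 1),
    surgery = c(1, 1, 0, 1),
    rt = c(0, 1, 1, 0),
    chemo = c(1, 0, 1, 0),
    histology = c("spindle", "biphasic", "NOS", "spindle"),
    time_months = c(12.5, 60, 34, 80),
    event = c(1, 0, 1, 0),
    stringsAsFactors = FALSE
  )
}

write_cohort_file <- function(df, sep = ",", path = tempfile(fileext = ".csv")) {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

# Small complete synthetic cohort for mid-level tests.
small_cohort <- function(n = 400, seed = 42, effect_map = numeric(0),
                         propensity_coefs = rep(0, 10),
                         missing_frac = 0) {
  generate_cohort(simulation_config(
    n, seed = seed, effect_map = effect_map,
    propensity_coefs = propensity_coefs, missing_frac = missing_frac))
}
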