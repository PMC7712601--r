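# Cohort data model: tabular I/O, KNN imputation, dichotomization and
# exhaustive stratification on nine binary covariates (512 cells).

#' Names of the nine stratification covariates, in their fixed bit order
#'
#' The subgroup key packs these bits as `key = sum(bit_i * 2^(i-1))`, so the
#' order is part of the public contract: bit 1 (`age_over_20`) is the least
#' significant bit and bit 9 (`biphasic`) the most significant.
#'
#' @return Character vector of length 9.
#' @export
covariate_names <- function() {
  c("age_over_20", "male", "size_over_5cm", "extremity", "stage_advanced",
    "surgery", "co_treatment", "spindle", "biphasic")
}

.cohort_columns <- c("id", "age", "sex", "size_cm", "site", "seer_stage",
                     "surgery", "rt", "chemo", "histology", "time_months",
                     "event")

.imputable_fields <- c("age", "sex", "size_cm", "site", "seer_stage",
                       "histology")

.as_cohort <- function(df, provenance = "unknown") {
  stopifnot(is.data.frame(df))
  class(df) <- c("cohort", "data.frame")
  attr(df, "provenance") <- provenance
  df
}

.parse_num <- function(x, field, what = "numeric") {
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable %s value '%s' at row %d",
                 field, what, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

.parse_cat <- function(x, field, levels) {
  x[x == "" | is.na(x)] <- NA
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) {
    stop(sprintf("column '%s': invalid value '%s' at row %d (allowed: %s)",
                 field, x[bad[1]], bad[1], paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  x
}

.parse_binary <- function(x, field) {
  out <- .parse_num(x, field)
  bad <- which(!is.na(out) & !(out %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("column '%s': value not in {0,1} at row %d", field, bad[1]),
         call. = FALSE)
  }
  as.integer(out)
}

#' Read a patient-level cohort table
#'
#' Reads a delimited text file (comma or tab, auto-detected from the header
#' line) with one row per patient and the columns `id, age, sex, size_cm,
#' site, seer_stage, surgery, rt, chemo, histology, time_months, event`.
#' Missing values may be written as empty strings or `NA`.  Rows with a
#' missing treatment indicator (`rt` or `chemo`) and rows with missing
#' outcome (`time_months` or `event`) are dropped; the counts are recorded in
#' the exclusion report retrievable with [exclusion_report()].
#'
#' @param path Path to the delimited file.
#' @return A `cohort` data frame with attributes `provenance` (the path) and
#'   `exclusion_report` (named list of dropped-row counts per reason).
#' @seealso [write_cohort()], [exclusion_report()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = "NA",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    id          = as.character(raw$id),
    age         = .parse_num(raw$age, "age"),
    sex         = .parse_cat(raw$sex, "sex", c("male", "female")),
    size_cm     = .parse_num(raw$size_cm, "size_cm"),
    site        = .parse_cat(raw$site, "site", c("extremity", "axial")),
    seer_stage  = .parse_num(raw$seer_stage, "seer_stage"),
    surgery     = .parse_binary(raw$surgery, "surgery"),
    rt          = .parse_binary(raw$rt, "rt"),
    chemo       = .parse_binary(raw$chemo, "chemo"),
    histology   = .parse_cat(raw$histology, "histology",
                             c("spindle", "biphasic", "NOS")),
    time_months = .parse_num(raw$time_months, "time_months"),
    event       = .parse_binary(raw$event, "event"),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(df$seer_stage) & !(df$seer_stage %in% 1:3))) {
    stop("column 'seer_stage': values must be 1, 2 or 3", call. = FALSE)
  }
  missing_treatment <- is.na(df$rt) | is.na(df$chemo)
  missing_outcome <- (is.na(df$time_months) | is.na(df$event)) &
    !missing_treatment
  report <- list(missing_treatment = sum(missing_treatment),
                 missing_outcome = sum(missing_outcome))
  df <- df[!missing_treatment & !(is.na(df$time_months) | is.na(df$event)), ,
           drop = FALSE]
  if (!nrow(df)) stop("cohort is empty after exclusions", call. = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate patient ids", call. = FALSE)
  if (any(df$time_months < 0)) stop("negative time_months", call. = FALSE)
  rownames(df) <- NULL
  out <- .as_cohort(df, provenance = path)
  attr(out, "exclusion_report") <- report
  out
}

#' Exclusion report of a cohort read from disk
#'
#' @param cohort A `cohort` object returned by [read_cohort()].
#' @return Named list of dropped-row counts per exclusion reason.
#' @export
exclusion_report <- function(cohort) {
  rep <- attr(cohort, "exclusion_report")
  if (is.null(rep)) list(missing_treatment = 0L, missing_outcome = 0L) else rep
}

#' Write a cohort table to delimited text
#'
#' @param cohort A `cohort` data frame.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(as.data.frame(cohort)[, .cohort_columns], path,
                     sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a cohort from an in-memory data frame
#'
#' Validates the schema and wraps the data frame in the `cohort` class used
#' throughout the package.  No rows are dropped: treatments and outcomes must
#' already be complete.
#'
#' @param df Data frame with the cohort columns (see [read_cohort()]).
#' @param provenance Free-text label recording where the data came from.
#' @return A `cohort` data frame.
#' @export
as_cohort <- function(df, provenance = "in-memory") {
  missing_cols <- setdiff(.cohort_columns, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(df$rt) | is.na(df$chemo))) {
    stop("treatment indicators must be complete", call. = FALSE)
  }
  if (any(is.na(df$time_months) | is.na(df$event))) {
    stop("outcomes must be complete", call. = FALSE)
  }
  if (anyDuplicated(df$id)) stop("duplicate patient ids", call. = FALSE)
  if (!nrow(df)) stop("cohort must be non-empty", call. = FALSE)
  .as_cohort(as.data.frame(df)[, .cohort_columns], provenance)
}

# Feature matrix for KNN distances: standardized numerics plus 0/1 indicator
# expansions of the categorical fields.  NA where the source field is missing.
.knn_features <- function(df) {
  std <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    (x - mean(x, na.rm = TRUE)) / s
  }
  cbind(
    age      = std(df$age),
    size     = std(df$size_cm),
    male     = as.numeric(df$sex == "male"),
    extrem   = as.numeric(df$site == "extremity"),
    stage2   = as.numeric(df$seer_stage == 2),
    stage3   = as.numeric(df$seer_stage == 3),
    surgery  = as.numeric(df$surgery),
    rt       = as.numeric(df$rt),
    chemo    = as.numeric(df$chemo),
    spindle  = as.numeric(df$histology == "spindle"),
    biphasic = as.numeric(df$histology == "biphasic")
  )
}

.vote <- function(values, ordered_ranks) {
  # majority vote; ties resolved by the nearest neighbour among tied values
  tab <- table(values)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  for (v in values[order(ordered_ranks)]) if (v %in% winners) return(v)
  winners[1L]
}

#' Impute missing covariates by K-nearest neighbours
#'
#' Distances are averaged squared differences over the mutually observed
#' entries of a feature matrix built from standardized numeric covariates and
#' one-hot encodings of the categoricals (treatments included as features;
#' treatments and outcomes are never imputed).  Numeric fields take the mean
#' of the `k` nearest donors, categorical fields the majority vote (ties
#' resolved by the nearest tied donor, then record order).  All donors come
#' from the original, pre-imputation table, so the result does not depend on
#' the order in which fields are filled.
#'
#' @param cohort A `cohort` data frame.
#' @param k Number of neighbours (default 5).
#' @param seed Integer seed, kept for interface stability; the procedure is
#'   deterministic (ties broken by record order).
#' @return The cohort with all covariate fields populated.
#' @export
impute_missing <- function(cohort, k = 5L, seed = 1L) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  n_obs <- vapply(.imputable_fields, function(f) sum(!is.na(df[[f]])),
                  integer(1))
  if (any(n_obs == 0L)) {
    stop("field '", .imputable_fields[which(n_obs == 0L)[1]],
         "' is missing in all records", call. = FALSE)
  }
  if (any(n_obs < k)) {
    stop("fewer than k = ", k, " records observe field '",
         .imputable_fields[which(n_obs < k)[1]], "'", call. = FALSE)
  }
  any_missing <- Reduce(`|`, lapply(.imputable_fields, function(f) is.na(df[[f]])))
  if (!any(any_missing)) return(cohort)

  feat <- .knn_features(df)
  out <- df
  for (i in which(any_missing)) {
    d <- rowMeans((feat - matrix(feat[i, ], n, ncol(feat), byrow = TRUE))^2,
                  na.rm = TRUE)
    d[i] <- Inf
    d[!is.finite(d)] <- Inf
    for (f in .imputable_fields) {
      if (!is.na(df[[f]][i])) next
      cand <- which(!is.na(df[[f]]))
      ord <- cand[order(d[cand], cand)][seq_len(k)]
      vals <- df[[f]][ord]
      out[[f]][i] <- if (is.numeric(vals)) mean(vals) else
        .vote(vals, seq_along(ord))
    }
  }
  res <- .as_cohort(out, attr(cohort, "provenance"))
  attr(res, "exclusion_report") <- attr(cohort, "exclusion_report")
  res
}

#' Dichotomize the nine stratification covariates
#'
#' Maps each (fully imputed) record to the ordered 9-bit covariate vector
#' `(age_over_20, male, size_over_5cm, extremity, stage_advanced, surgery,
#' co_treatment, spindle, biphasic)`.  Cutoffs are strict: age must exceed 20
#' years and the longest tumor diameter must exceed 5 cm for those bits to be
#' set.  The treatment being analyzed is excluded from the vector; the other
#' adjuvant treatment enters as the `co_treatment` bit.  `NOS` histology is
#' the reference category (both histology bits 0).
#'
#' @param cohort A `cohort` data frame (or any data frame with the cohort
#'   columns); all covariate fields must be non-missing.
#' @param treatment Which treatment is analyzed: `"rt"` or `"chemo"`.
#' @param advanced_stages SEER stages coded as "advanced" for the
#'   `stage_advanced` bit (default stage 3, distant disease).
#' @return Integer matrix with one row per record and the nine named bit
#'   columns of [covariate_names()].
#' @export
dichotomize <- function(cohort, treatment = c("chemo", "rt"),
                        advanced_stages = 3L) {
  treatment <- match.arg(treatment)
  df <- as.data.frame(cohort)
  needed <- c("age", "sex", "size_cm", "site", "seer_stage", "surgery",
              "rt", "chemo", "histology")
  for (f in needed) {
    if (anyNA(df[[f]])) {
      stop("field '", f, "' has missing values; run impute_missing() first",
           call. = FALSE)
    }
  }
  co <- if (treatment == "chemo") df$rt else df$chemo
  bits <- cbind(
    age_over_20    = as.integer(df$age > 20),
    male           = as.integer(df$sex == "male"),
    size_over_5cm  = as.integer(df$size_cm > 5),
    extremity      = as.integer(df$site == "extremity"),
    stage_advanced = as.integer(df$seer_stage %in% advanced_stages),
    surgery        = as.integer(df$surgery),
    co_treatment   = as.integer(co),
    spindle        = as.integer(df$histology == "spindle"),
    biphasic       = as.integer(df$histology == "biphasic")
  )
  rownames(bits) <- df$id
  bits
}

#' Pack a 9-bit covariate vector into its subgroup key
#'
#' `key = sum(bit_i * 2^(i-1))` over the fixed bit order of
#' [covariate_names()], giving a bijection between valid covariate vectors
#' and integers in `[0, 511]`.
#'
#' @param bits Integer vector of length 9, or a matrix with 9 columns (one
#'   row per record).
#' @return Integer key(s) in `[0, 511]`.
#' @seealso [key_to_bits()]
#' @export
subgroup_key <- function(bits) {
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  stopifnot(ncol(bits) == 9L, all(bits %in% c(0L, 1L)))
  as.integer(bits %*% 2^(0:8))
}

#' Unpack a subgroup key into its 9-bit covariate vector
#'
#' @param key Integer vector of keys in `[0, 511]`.
#' @return Integer matrix with one row per key and the nine named bit columns.
#' @export
key_to_bits <- function(key) {
  stopifnot(all(key >= 0L), all(key <= 511L))
  bits <- t(vapply(as.integer(key),
                   function(k) as.integer(bitwAnd(bitwShiftR(k, 0:8), 1L)),
                   integer(9)))
  colnames(bits) <- covariate_names()
  bits
}

#' Decode a subgroup key into a readable covariate profile
#'
#' @param key Integer key in `[0, 511]`.
#' @return Character string listing the bits that are set (or "reference
#'   profile" when none are).
#' @export
describe_subgroup <- function(key) {
  bits <- key_to_bits(key)
  vapply(seq_len(nrow(bits)), function(i) {
    on <- covariate_names()[bits[i, ] == 1L]
    if (!length(on)) "reference profile" else paste(on, collapse = "+")
  }, character(1))
}

#' Stratify a cohort into exhaustive covariate subgroups
#'
#' Partitions the cohort into cells of identical covariate vectors (at most
#' 512) and splits each cell by the analyzed treatment.  Every record lands
#' in exactly one cell; empty cells are absent.
#'
#' @inheritParams dichotomize
#' @return A named list (names are subgroup keys) of `list(treated =,
#'   untreated =)` sub-data frames, with the per-record key vector attached
#'   as attribute `keys`.
#' @export
stratify <- function(cohort, treatment = c("chemo", "rt"),
                     advanced_stages = 3L) {
  treatment <- match.arg(treatment)
  df <- as.data.frame(cohort)
  keys <- subgroup_key(dichotomize(df, treatment, advanced_stages))
  treat <- df[[treatment]]
  cells <- lapply(split(seq_len(nrow(df)), keys), function(idx) {
    list(treated   = df[idx[treat[idx] == 1L], , drop = FALSE],
         untreated = df[idx[treat[idx] == 0L], , drop = FALSE])
  })
  attr(cells, "keys") <- keys
  attr(cells, "treatment") <- treatment
  cells
}
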