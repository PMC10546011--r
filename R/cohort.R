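# Cohort tables are plain data.frames with one row per participant and the
# canonical column set below; empty CSV cells are missing values.

.sg_cohort_cols <- c("participant_id", "age", "education", "onset_age",
                     "mmse", "mdrs", "bds", "hdrs",
                     "semantic_fluency", "phonemic_fluency",
                     "mean_lcc", "mean_lsc")

#' Read / write a cohort table
#'
#' The cohort CSV has the header `participant_id, age, education, onset_age,
#' mmse, mdrs, bds, hdrs, semantic_fluency, phonemic_fluency, mean_lcc,
#' mean_lsc`; empty cells are missing. `read_cohort()` validates the header,
#' participant-id uniqueness and `onset_age <= age` (errors), and checks the
#' instrument ranges (MMSE 0-30, MDRS 0-144, BDS 0-28, HDRS >= 0) with a
#' warning — simulated severity scores are unclipped by default, see
#' [generate_cohort()].
#'
#' @param path CSV file path.
#' @param cohort data.frame with the canonical columns.
#' @return `read_cohort()`: a validated data.frame; `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    sg_stop(sprintf("file not found: %s", path), "sgdem_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, .sg_cohort_cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

validate_cohort <- function(df) {
  missing_cols <- setdiff(.sg_cohort_cols, names(df))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$participant_id))
    stop("duplicate participant_id values in cohort")
  # instrument-range violations warn rather than error: simulated severity
  # scores are intentionally unclipped by default (see generate_cohort)
  chk <- function(v, lo, hi, nm) {
    x <- df[[v]]
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad))
      warning(sprintf("%s outside [%g, %g] for participant(s): %s", nm, lo, hi,
                      paste(df$participant_id[bad], collapse = ", ")))
  }
  chk("mmse", 0, 30, "MMSE"); chk("mdrs", 0, 144, "MDRS")
  chk("bds", 0, 28, "BDS"); chk("hdrs", 0, Inf, "HDRS")
  bad <- !is.na(df$onset_age) & !is.na(df$age) & df$onset_age > df$age
  if (any(bad))
    stop("onset_age exceeds age for participant(s): ",
         paste(df$participant_id[bad], collapse = ", "))
  df
}

#' Aggregate verbal-fluency z-score
#'
#' Standardizes semantic and phonemic fluency counts against the analysis
#' sample's own mean and standard deviation (denominator n-1) and sums the
#' two z-scores. Both measures must be complete (impute first, see
#' [impute_fluency()]).
#'
#' @param semantic,phonemic numeric vectors of fluency counts, or pass a
#'   cohort data.frame as `semantic` to use its `semantic_fluency` and
#'   `phonemic_fluency` columns.
#' @return numeric vector of aggregate z-scores (mean 0 by construction).
#' @examples
#' fluency_z(c(8, 10, 12), c(5, 7, 9))  # third participant: 1 + 1 = 2
#' @export
fluency_z <- function(semantic, phonemic = NULL) {
  if (is.data.frame(semantic)) {
    phonemic <- semantic$phonemic_fluency
    semantic <- semantic$semantic_fluency
  }
  if (anyNA(semantic) || anyNA(phonemic))
    stop("fluency scores contain missing values; impute before aggregating")
  zs <- function(x, nm) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      sg_stop(sprintf("degenerate fluency distribution: %s has zero variance", nm),
              "sgdem_degenerate")
    (x - mean(x)) / s
  }
  zs(semantic, "semantic") + zs(phonemic, "phonemic")
}

#' Descriptive summary of a cohort
#'
#' Mean, standard deviation (denominator n-1), observed range and missing
#' count for each analysis variable, in the conventional reporting order
#' (demographics, severity instruments, depression, fluency, connectedness).
#' With a single observation the SD is reported as `NA`.
#'
#' @param cohort a cohort data.frame.
#' @return data.frame with columns `variable`, `mean`, `sd`, `min`, `max`,
#'   `n_missing`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(nrow(cohort) >= 1L)
  vars <- setdiff(.sg_cohort_cols, "participant_id")
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    obs <- x[!is.na(x)]
    data.frame(variable = v,
               mean = if (length(obs)) mean(obs) else NA_real_,
               sd = if (length(obs) > 1L) stats::sd(obs) else NA_real_,
               min = if (length(obs)) min(obs) else NA_real_,
               max = if (length(obs)) max(obs) else NA_real_,
               n_missing = sum(is.na(x)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
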