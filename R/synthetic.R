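# Synthetic data with known structure, so every pipeline stage can be
# validated without access-restricted clinical corpora.

#' Default covariate distribution of the synthetic cohort
#'
#' Means, SDs and ranges used by [generate_cohort()] for the demographic,
#' clinical and connectedness variables. Values are chosen to match the
#' profile of published Alzheimer's picture-description cohorts (age ~72,
#' modest education, mild-to-moderate depression scores, fluency counts
#' under 25). Connectedness scores are drawn at the whole-narrative scale on
#' which cohort norms are reported; see the package vignette for the
#' relation to windowed means.
#'
#' @return data.frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
sg_covariate_defaults <- function() {
  data.frame(
    variable = c("age", "education", "onset_age", "hdrs",
                 "semantic_fluency", "phonemic_fluency",
                 "mean_lcc", "mean_lsc"),
    mean = c(71.93, 12.37, 68.26, 5.93, 9.11, 6.74, 57.07, 35.78),
    sd   = c(8.70, 2.95, 8.34, 3.55, 4.66, 4.23, 22.85, 21.91),
    min  = c(50, 6, 47, 0, 2, 0, 14, 1),
    max  = c(88, 20, 85, 16, 22, 19, 151, 117),
    stringsAsFactors = FALSE)
}

#' Default generating coefficients of the synthetic severity models
#'
#' One row per severity outcome; columns are the intercept and the slopes on
#' HDRS, onset age, education, the aggregate fluency z-score and the
#' connectedness score. Magnitudes reflect the effect sizes reported for
#' cohorts of this kind: education, fluency and connectedness carry positive
#' weight for the cognitive instruments (MMSE, MDRS), while the
#' informant-rated functional scale (BDS) loads mainly on depression.
#'
#' @return matrix with rownames `mmse`, `mdrs`, `bds`.
#' @export
sg_default_coefs <- function() {
  m <- rbind(
    mmse = c(17.08, 0.02, -0.04, 0.27, 1.59, 0.04),
    mdrs = c(100.25, 0.13, -0.06, 1.11, 4.90, 0.09),
    bds  = c(8.58, 0.40, -0.02, -0.18, -0.34, -0.01))
  colnames(m) <- c("intercept", "hdrs", "onset_age", "education",
                   "fluency_z", "connectedness")
  m
}

#' Generate a synthetic picture-description transcript
#'
#' Token sequences come from a repetition process: the first token is drawn
#' from the vocabulary; each subsequent token either *revisits* a uniformly
#' chosen earlier token (probability `p_return`) or is a fresh uniform
#' vocabulary draw. After each token a new utterance starts with probability
#' `p_break`, modelling interruptions. Returns create cycles in the
#' word-trajectory graph, so `p_return` is the handle on connectedness;
#' `n_tokens` controls verbosity. The defaults produce whole-transcript
#' LCC/LSC near the center of the ranges observed in dementia
#' picture-description corpora.
#'
#' Note that connectedness is not monotone in `p_return` over its whole
#' range: as `p_return` approaches 1 the number of distinct word types
#' collapses, so the strongly connected component first grows and then
#' shrinks (see the vignette).
#'
#' @param n_tokens transcript length in tokens (default 100).
#' @param vocab_size vocabulary size for fresh draws (default 250).
#' @param p_return probability that a token revisits an earlier one.
#' @param p_break probability of an utterance break after each token.
#' @param seed integer seed; output is bit-reproducible.
#' @param distinct if `TRUE`, fresh draws sample the vocabulary *without*
#'   replacement (requires `vocab_size >= n_tokens`); with `p_return = 0`
#'   this yields an all-distinct token sequence.
#' @param participant_id identifier for the generated transcript.
#' @return an `sg_transcript`.
#' @export
generate_transcript <- function(n_tokens = 100L, vocab_size = 250L,
                                p_return = 0.35, p_break = 0.15,
                                seed = NULL, distinct = FALSE,
                                participant_id = "sim") {
  n_tokens <- as.integer(n_tokens); vocab_size <- as.integer(vocab_size)
  stopifnot(vocab_size >= 1L, n_tokens >= 1L,
            p_return >= 0, p_return <= 1, p_break >= 0, p_break <= 1)
  if (distinct && vocab_size < n_tokens)
    stop("distinct = TRUE requires vocab_size >= n_tokens")
  with_seed(seed, {
    ids <- integer(n_tokens)
    brk <- logical(n_tokens)
    unused <- if (distinct) sample.int(vocab_size) else integer(0)
    fresh <- function(k) {
      if (distinct) unused[k] else sample.int(vocab_size, 1L)
    }
    nfresh <- 1L
    ids[1L] <- fresh(1L)
    if (n_tokens > 1L) {
      for (k in 2L:n_tokens) {
        if (stats::runif(1L) < p_return) {
          ids[k] <- ids[sample.int(k - 1L, 1L)]
        } else {
          nfresh <- nfresh + 1L
          ids[k] <- fresh(nfresh)
        }
      }
    }
    brk <- stats::runif(n_tokens) < p_break
    width <- nchar(as.character(vocab_size))
    toks <- paste0("w", formatC(ids, width = width, flag = "0"))
    utt_id <- cumsum(c(1L, brk[-n_tokens]))
    transcript(split(toks, utt_id), participant_id)
  })
}

#' Generate a synthetic cohort with known regression structure
#'
#' Covariates are drawn from truncated normals at the defaults of
#' [sg_covariate_defaults()]; age of onset is age minus a positive gap.
#' Each severity score is generated from the linear model
#' `intercept + b1*hdrs + b2*onset_age + b3*education + b4*fluency_z +
#' b5*connectedness + N(0, noise_sd)`, with the aggregate fluency z-score
#' computed within the generated sample, so refitting with
#' [fit_severity()] recovers the generating coefficients (exactly when
#' `noise_sd = 0`).
#'
#' When `noise_sd` is `NULL` it is derived per outcome from `target_r2`:
#' `noise_sd = sd(linear predictor) * sqrt(1/R2 - 1)`, which fixes the
#' model's construction R-squared. Severity scores are left unclipped by
#' default so the linear model is exact; `clip = TRUE` clamps them to the
#' instrument ranges (MMSE 0-30, MDRS 0-144, BDS 0-28), which biases
#' coefficient-recovery checks and is therefore opt-in.
#'
#' @param n cohort size (default 128).
#' @param seed integer seed.
#' @param coefs generating coefficient matrix, see [sg_default_coefs()].
#' @param target_r2 named vector of construction R-squared per outcome, used
#'   when `noise_sd` is `NULL`.
#' @param noise_sd optional named vector of residual SDs per outcome,
#'   overriding `target_r2`.
#' @param missing_rate MCAR cell-deletion rate applied to the two fluency
#'   columns via [apply_missingness()] (default 0: complete data).
#' @param clip clamp severity scores to instrument ranges? Default `FALSE`.
#' @param conn_measure which generated connectedness column drives severity:
#'   `"lcc"` (default) or `"lsc"`.
#' @param transcripts if `TRUE`, also generate one transcript per
#'   participant and *compute* `mean_lcc`/`mean_lsc` through the windowed
#'   pipeline instead of drawing them; returns
#'   `list(cohort, transcripts)`.
#' @param covariates covariate parameter table, defaulting to
#'   [sg_covariate_defaults()].
#' @return a cohort data.frame (or a list when `transcripts = TRUE`).
#' @export
generate_cohort <- function(n = 128L, seed = NULL, coefs = sg_default_coefs(),
                            target_r2 = c(mmse = 0.44, mdrs = 0.61, bds = 0.15),
                            noise_sd = NULL, missing_rate = 0, clip = FALSE,
                            conn_measure = c("lcc", "lsc"),
                            transcripts = FALSE,
                            covariates = sg_covariate_defaults()) {
  n <- as.integer(n)
  stopifnot(n >= 10L, missing_rate >= 0, missing_rate < 1)
  conn_measure <- match.arg(conn_measure)
  cv <- covariates
  rownames(cv) <- cv$variable
  draw <- function(v, integer = FALSE) {
    x <- rtruncnorm(n, cv[v, "mean"], cv[v, "sd"], cv[v, "min"], cv[v, "max"])
    if (integer) round(x) else x
  }
  out <- with_seed(seed, {
    age <- draw("age")
    gap <- rtruncnorm(n, 3.7, 2.5, 0, 25)
    onset_age <- pmax(age - gap, cv["onset_age", "min"])
    education <- draw("education", integer = TRUE)
    hdrs <- draw("hdrs", integer = TRUE)
    semantic_fluency <- draw("semantic_fluency", integer = TRUE)
    phonemic_fluency <- draw("phonemic_fluency", integer = TRUE)
    trs <- NULL
    if (transcripts) {
      trs <- lapply(seq_len(n), function(i)
        generate_transcript(
          n_tokens = round(rtruncnorm(1, 100, 40, 35, 400)),
          p_return = stats::runif(1, 0.15, 0.55),
          participant_id = sprintf("sim%03d", i)))
      wc <- lapply(trs, windowed_connectedness)
      mean_lcc <- vapply(wc, `[[`, 0, "mean_lcc")
      mean_lsc <- vapply(wc, `[[`, 0, "mean_lsc")
    } else {
      mean_lcc <- draw("mean_lcc")
      mean_lsc <- draw("mean_lsc")
    }
    flz <- fluency_z(semantic_fluency, phonemic_fluency)
    conn <- if (conn_measure == "lcc") mean_lcc else mean_lsc
    sev <- list()
    for (oc in c("mmse", "mdrs", "bds")) {
      b <- coefs[oc, ]
      lp <- b["intercept"] + b["hdrs"] * hdrs + b["onset_age"] * onset_age +
        b["education"] * education + b["fluency_z"] * flz +
        b["connectedness"] * conn
      s <- if (!is.null(noise_sd)) noise_sd[[oc]]
           else {
             v <- stats::sd(lp)
             if (!is.finite(v) || v == 0) 1
             else v * sqrt(1 / target_r2[[oc]] - 1)
           }
      y <- lp + stats::rnorm(n, 0, s)
      if (clip) {
        rng <- switch(oc, mmse = c(0, 30), mdrs = c(0, 144), bds = c(0, 28))
        y <- pmin(pmax(y, rng[1L]), rng[2L])
      }
      sev[[oc]] <- y
    }
    coh <- data.frame(
      participant_id = sprintf("sim%03d", seq_len(n)),
      age = age, education = education, onset_age = onset_age,
      mmse = sev$mmse, mdrs = sev$mdrs, bds = sev$bds, hdrs = hdrs,
      semantic_fluency = semantic_fluency,
      phonemic_fluency = phonemic_fluency,
      mean_lcc = mean_lcc, mean_lsc = mean_lsc,
      stringsAsFactors = FALSE)
    if (missing_rate > 0)
      coh <- apply_missingness(coh, rate = missing_rate)
    list(cohort = coh, transcripts = trs)
  })
  if (transcripts) out else out$cohort
}

#' Delete fluency cells completely at random
#'
#' Each cell of the target columns is set missing independently with the
#' given probability (missing completely at random). Errors if a column
#' would be left with fewer than 3 observed values, the minimum the
#' imputation model needs.
#'
#' @param cohort a cohort data.frame.
#' @param rate per-cell deletion probability in `[0, 1)`.
#' @param seed integer seed; `NULL` uses the current RNG state (as when
#'   called from inside [generate_cohort()]).
#' @param vars columns to delete from.
#' @return the cohort with deletions applied.
#' @export
apply_missingness <- function(cohort, rate = 0.25, seed = NULL,
                              vars = c("semantic_fluency", "phonemic_fluency")) {
  stopifnot(rate >= 0, rate < 1)
  res <- with_seed(seed, {
    for (v in vars) {
      del <- stats::runif(nrow(cohort)) < rate
      cohort[[v]][del] <- NA
      if (sum(!is.na(cohort[[v]])) < 3L)
        sg_stop(sprintf(
          "missingness rate %.3g leaves fewer than 3 observed values in %s",
          rate, v), "sgdem_cannot_impute")
    }
    cohort
  })
  res
}
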