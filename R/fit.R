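#' Regress dementia severity on education, fluency and speech connectedness
#'
#' The central model of the package: an ordinary least-squares regression of
#' one severity score (MMSE, MDRS or BDS) on five predictors — depression
#' (HDRS) and age of symptom onset as controls, plus years of education, the
#' aggregate verbal-fluency z-score ([fluency_z()]) and one windowed
#' connectedness measure (mean LCC or mean LSC). When fluency scores are
#' missing they are multiply imputed ([impute_fluency()]) and the `m`
#' per-table fits are pooled by Rubin's rules with Barnard–Rubin adjusted
#' degrees of freedom; with `m = 1` the result is exactly the single-table
#' fit.
#'
#' Rows with a missing outcome are dropped (complete-case analysis per
#' outcome), so different outcomes may use different numbers of records.
#' The fluency z-scores are computed within each completed analysis sample,
#' after imputation.
#'
#' @param cohort a cohort data.frame, or an `sg_imputed` object (in which
#'   case `m`, `seed` and the engine arguments are ignored).
#' @param outcome `"mmse"`, `"mdrs"` or `"bds"`.
#' @param measure `"lcc"` or `"lsc"`: which windowed connectedness mean
#'   enters the model.
#' @param m,seed,maxit,donors,engine passed to [impute_fluency()] when
#'   `cohort` has missing fluency values.
#' @return object of class `severity_fit` with components `coefficients`
#'   (data.frame: term, estimate, se, ci_low, ci_high, statistic, df, p),
#'   `r_squared`, `f_stat`, `df_model`, `df_resid`, `n_used`, `m`,
#'   `outcome`, `measure`. Methods: `print`, `summary`, `coef`, `confint`,
#'   `vcov`, `predict`.
#' @examples
#' coh <- generate_cohort(n = 60, seed = 42)
#' fit <- fit_severity(coh, outcome = "mmse", measure = "lcc", m = 1)
#' summary(fit)
#' @export
fit_severity <- function(cohort, outcome = c("mmse", "mdrs", "bds"),
                         measure = c("lcc", "lsc"), m = 5L, seed = NULL,
                         maxit = 10L, donors = 5L, engine = "pmm") {
  outcome <- match.arg(outcome)
  measure <- match.arg(measure)
  cl <- match.call()
  if (inherits(cohort, "sg_imputed")) {
    imp <- cohort
  } else {
    imp <- impute_fluency(cohort, m = m, seed = seed, maxit = maxit,
                          donors = donors, engine = engine)
  }
  conn_col <- paste0("mean_", measure)
  fits <- lapply(imp$completed, function(dat)
    fit_one(dat, outcome, conn_col))
  res <- pool_fits(fits, m = imp$m)
  res$outcome <- outcome
  res$measure <- toupper(measure)
  res$seed <- imp$seed
  res$call <- cl
  # average fluency scale across completed analysis sets, for predict()
  res$fluency_scale <- Reduce(`+`, lapply(fits, `[[`, "fluency_scale")) /
    length(fits)
  class(res) <- "severity_fit"
  res
}

# Fit one completed table: complete cases for the outcome, z-scores within
# the analysis sample, OLS via lm.
fit_one <- function(dat, outcome, conn_col) {
  keep <- !is.na(dat[[outcome]]) & !is.na(dat[[conn_col]]) &
    !is.na(dat$hdrs) & !is.na(dat$onset_age) & !is.na(dat$education)
  dat <- dat[keep, , drop = FALSE]
  if (sum(!is.na(dat[[outcome]])) < 8L)
    stop(sprintf("outcome '%s' observed for fewer than 8 records", outcome))
  if (nrow(dat) < 7L)
    stop("too few complete records to fit 5 predictors")
  d <- data.frame(y = dat[[outcome]],
                  hdrs = dat$hdrs,
                  onset_age = dat$onset_age,
                  education = dat$education,
                  fluency = fluency_z(dat),
                  connectedness = dat[[conn_col]])
  X <- stats::model.matrix(y ~ ., data = d)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    sg_stop(paste0("collinear predictors: ", paste(bad, collapse = ", ")),
            "sgdem_collinear")
  }
  fit <- stats::lm(y ~ ., data = d)
  s <- suppressWarnings(summary(fit))  # silence lm's perfect-fit notice
  r2 <- s$r.squared
  # constant outcome: no variance to explain, not a perfect fit
  if (!is.finite(r2) || stats::sd(d$y) < 1e-12 * (abs(mean(d$y)) + 1))
    r2 <- 0
  list(coef = stats::coef(fit), vcov = suppressWarnings(stats::vcov(fit)),
       r_squared = r2, n = nrow(d),
       fluency_scale = c(sem_mean = mean(dat$semantic_fluency),
                         sem_sd = stats::sd(dat$semantic_fluency),
                         pho_mean = mean(dat$phonemic_fluency),
                         pho_sd = stats::sd(dat$phonemic_fluency)))
}

# Rubin's rules across m fits; Barnard-Rubin small-sample df for m > 1.
# R^2 pooled on the Fisher-z scale of its square root (Harel's method);
# the overall F statistic is recomputed from the pooled R^2, which for
# m = 1 coincides exactly with the usual F.
pool_fits <- function(fits, m) {
  terms <- names(fits[[1L]]$coef)
  p <- length(terms)
  n_used <- fits[[1L]]$n
  dfcom <- n_used - p
  est_mat <- do.call(rbind, lapply(fits, `[[`, "coef"))
  qbar <- colMeans(est_mat)
  ubar <- Reduce(`+`, lapply(fits, `[[`, "vcov")) / m
  if (m > 1L) {
    B <- stats::cov(est_mat)
    total <- ubar + (1 + 1 / m) * B
    bdiag <- diag(B)
  } else {
    total <- ubar
    bdiag <- rep(0, p)
  }
  se <- sqrt(diag(total))
  if (m > 1L) {
    lambda <- pmin(pmax((1 + 1 / m) * bdiag / diag(total), 0), 1 - 1e-12)
    df_old <- (m - 1) / pmax(lambda^2, 1e-12)
    df_obs <- ((dfcom + 1) / (dfcom + 3)) * dfcom * (1 - lambda)
    df <- df_old * df_obs / (df_old + df_obs)
  } else {
    df <- rep(dfcom, p)
  }
  tval <- qbar / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tcrit <- stats::qt(0.975, df)
  r2 <- vapply(fits, `[[`, 0, "r_squared")
  r2_pooled <- tanh(mean(atanh(sqrt(pmin(pmax(r2, 0), 1 - 1e-15)))))^2
  df_model <- p - 1L
  f_stat <- (r2_pooled / df_model) / ((1 - r2_pooled) / dfcom)
  list(coefficients = data.frame(
         term = terms, estimate = unname(qbar), se = unname(se),
         ci_low = unname(qbar - tcrit * se),
         ci_high = unname(qbar + tcrit * se),
         statistic = unname(tval), df = unname(df), p = unname(pval),
         stringsAsFactors = FALSE),
       vcov_pooled = total,
       r_squared = r2_pooled, f_stat = f_stat,
       df_model = df_model, df_resid = dfcom,
       n_used = n_used, m = m)
}

#' @export
print.severity_fit <- function(x, ...) {
  cat(sprintf("<severity_fit> %s ~ HDRS + onset age + education + fluency-z + %s\n",
              toupper(x$outcome), x$measure))
  cat(sprintf("  n = %d, m = %d imputation(s); R^2 = %.3f, F(%d, %d) = %.2f\n",
              x$n_used, x$m, x$r_squared, x$df_model, x$df_resid, x$f_stat))
  invisible(x)
}

#' @export
summary.severity_fit <- function(object, ...) {
  structure(object, class = "summary.severity_fit")
}

#' @export
print.summary.severity_fit <- function(x, ...) {
  print.severity_fit(x)
  cf <- x$coefficients
  mat <- cbind(Estimate = cf$estimate, `Std. Error` = cf$se,
               `2.5 %` = cf$ci_low, `97.5 %` = cf$ci_high,
               `t value` = cf$statistic, df = cf$df, `Pr(>|t|)` = cf$p)
  rownames(mat) <- cf$term
  stats::printCoefmat(mat, P.values = TRUE, has.Pvalue = TRUE,
                      cs.ind = 1:4, tst.ind = 5:6)
  overall_p <- stats::pf(x$f_stat, x$df_model, x$df_resid, lower.tail = FALSE)
  cat(sprintf("Overall: F(%d, %d) = %.2f, p = %.3g\n",
              x$df_model, x$df_resid, x$f_stat, overall_p))
  invisible(x)
}

#' @export
coef.severity_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.severity_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  tcrit <- stats::qt(1 - (1 - level) / 2, cf$df)
  out <- cbind(cf$estimate - tcrit * cf$se, cf$estimate + tcrit * cf$se)
  rownames(out) <- cf$term
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
vcov.severity_fit <- function(object, ...) object$vcov_pooled

#' Predict severity for new participants
#'
#' Applies the pooled coefficients to new data. Fluency z-scores for the new
#' records are computed against the *training* sample's fluency means and
#' SDs (averaged over completed tables), so predictions are comparable to
#' fitted values.
#'
#' @param object a `severity_fit`.
#' @param newdata data.frame with columns `hdrs`, `onset_age`, `education`,
#'   `semantic_fluency`, `phonemic_fluency` and the fitted connectedness
#'   column (`mean_lcc` or `mean_lsc`).
#' @param ... unused.
#' @return numeric vector of predicted severity scores.
#' @export
predict.severity_fit <- function(object, newdata, ...) {
  fs <- object$fluency_scale
  fl <- (newdata$semantic_fluency - fs["sem_mean"]) / fs["sem_sd"] +
    (newdata$phonemic_fluency - fs["pho_mean"]) / fs["pho_sd"]
  conn <- newdata[[paste0("mean_", tolower(object$measure))]]
  b <- coef(object)
  drop(cbind(1, newdata$hdrs, newdata$onset_age, newdata$education,
             fl, conn) %*% b)
}

#' Fit both connectedness measures for every outcome
#'
#' Convenience wrapper producing the full grid of six models (three outcomes
#' x two connectedness measures) from one cohort, sharing one imputation per
#' call.
#'
#' @inheritParams fit_severity
#' @return data.frame in long layout: one row per outcome x measure x term
#'   with the pooled estimate, SE, CI, statistic, df, p, plus model-level
#'   `r_squared`, `f_stat`, `df_resid`, `n_used`.
#' @export
fit_severity_grid <- function(cohort, m = 5L, seed = NULL, maxit = 10L,
                              donors = 5L, engine = "pmm") {
  imp <- if (inherits(cohort, "sg_imputed")) cohort
         else impute_fluency(cohort, m = m, seed = seed, maxit = maxit,
                             donors = donors, engine = engine)
  out <- list()
  for (outc in c("mmse", "mdrs", "bds")) {
    for (meas in c("lcc", "lsc")) {
      f <- fit_severity(imp, outcome = outc, measure = meas)
      cf <- f$coefficients
      cf$outcome <- outc; cf$measure <- toupper(meas)
      cf$r_squared <- f$r_squared; cf$f_stat <- f$f_stat
      cf$df_resid <- f$df_resid; cf$n_used <- f$n_used
      out[[length(out) + 1L]] <- cf
    }
  }
  do.call(rbind, out)
}
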