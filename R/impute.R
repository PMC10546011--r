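#' Multiple imputation of missing fluency scores by chained equations
#'
#' Iteratively regresses each incomplete fluency measure on the other
#' analysis variables and draws imputations, producing `m` completed cohort
#' tables. The default engine is predictive-mean matching (PMM): regression
#' parameters are drawn from their posterior, predicted values of missing
#' cases are matched to predictions of observed cases, and one of the
#' `donors` closest observed values is sampled as the imputation — so
#' imputed fluency counts are always actually-observed values, appropriate
#' for non-negative integer scores. `engine = "norm"` instead draws from the
#' Bayesian normal linear model.
#'
#' Predictors are the fully observed analysis variables (demographics,
#' severity scores, depression, connectedness) plus the other fluency
#' measure at its current imputed values. Missingness is expected to be
#' confined to `semantic_fluency` and `phonemic_fluency`.
#'
#' @param cohort a cohort data.frame (see [read_cohort()]).
#' @param m number of completed tables (default 5).
#' @param seed integer seed; the result is bit-reproducible given
#'   `(seed, m, maxit)`. The caller's RNG state is left untouched.
#' @param maxit chained-equation iterations per table (default 10).
#' @param donors PMM donor-pool size (default 5).
#' @param engine `"pmm"` (default) or `"norm"`.
#' @return object of class `sg_imputed`: list with `completed` (list of `m`
#'   cohort data.frames with no missing fluency), `m`, `seed`, `maxit`,
#'   `donors`, `engine`, `targets`.
#' @seealso [fit_severity()], which pools regressions over the completed
#'   tables by Rubin's rules.
#' @export
impute_fluency <- function(cohort, m = 5L, seed = NULL, maxit = 10L,
                           donors = 5L, engine = c("pmm", "norm")) {
  engine <- match.arg(engine)
  m <- as.integer(m)
  stopifnot(m >= 1L, maxit >= 1L, donors >= 1L)
  targets <- c("semantic_fluency", "phonemic_fluency")
  other <- setdiff(.sg_cohort_cols, c("participant_id", targets))
  extra_na <- other[vapply(other, function(v) anyNA(cohort[[v]]), TRUE)]

  for (v in targets) {
    n_obs <- sum(!is.na(cohort[[v]]))
    if (n_obs == 0L)
      sg_stop(sprintf("cannot impute: %s is entirely missing", v),
              "sgdem_cannot_impute")
    if (n_obs < 3L && anyNA(cohort[[v]]))
      sg_stop(sprintf("cannot impute: %s has fewer than 3 observed values", v),
              "sgdem_cannot_impute")
  }
  if (!anyNA(cohort[, targets])) {
    return(structure(list(completed = rep(list(cohort), m), m = m,
                          seed = seed, maxit = maxit, donors = donors,
                          engine = engine, targets = character(0)),
                     class = "sg_imputed"))
  }
  # predictors must be complete; variables with their own missingness
  # (typically an unobserved outcome) are left out of the imputation model
  preds <- setdiff(other, extra_na)
  to_impute <- targets[vapply(targets, function(v) anyNA(cohort[[v]]), TRUE)]

  completed <- with_seed(seed, {
    lapply(seq_len(m), function(d) {
      dat <- cohort
      for (v in to_impute) {                    # initialize from observed
        mis <- is.na(dat[[v]])
        dat[[v]][mis] <- sample(dat[[v]][!mis], sum(mis), replace = TRUE)
      }
      for (it in seq_len(maxit)) {
        for (v in to_impute) {
          mis <- is.na(cohort[[v]])
          xcols <- c(preds, setdiff(targets, v))
          X <- cbind(`(Intercept)` = 1, as.matrix(dat[, xcols]))
          dat[[v]][mis] <- draw_imputations(
            y_obs = cohort[[v]][!mis], X_obs = X[!mis, , drop = FALSE],
            X_mis = X[mis, , drop = FALSE], donors = donors, engine = engine)
        }
      }
      dat
    })
  })
  structure(list(completed = completed, m = m, seed = seed, maxit = maxit,
                 donors = donors, engine = engine, targets = to_impute),
            class = "sg_imputed")
}

# One conditional draw for one variable: Bayesian linear regression of
# y_obs on X_obs, then PMM donor matching or a normal-model draw.
draw_imputations <- function(y_obs, X_obs, X_mis, donors, engine) {
  qr_fit <- qr(X_obs)
  k <- qr_fit$rank
  beta_hat <- qr.coef(qr_fit, y_obs)
  beta_hat[is.na(beta_hat)] <- 0
  resid <- y_obs - drop(X_obs %*% beta_hat)
  df <- max(length(y_obs) - k, 1L)
  sigma2_dot <- sum(resid^2) / stats::rchisq(1L, df)
  XtX <- crossprod(X_obs)
  # posterior covariance via a pseudo-inverse so rank-deficient designs
  # (tiny cohorts, collinear predictors) still yield a proper draw
  ev <- eigen(XtX, symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-10
  V <- ev$vectors[, pos, drop = FALSE] %*%
    (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  evv <- eigen((V + t(V)) / 2, symmetric = TRUE)
  L <- evv$vectors %*% diag(sqrt(pmax(evv$values, 0)), ncol(X_obs))
  beta_dot <- beta_hat +
    sqrt(sigma2_dot) * drop(L %*% stats::rnorm(ncol(X_obs)))
  if (engine == "norm") {
    return(drop(X_mis %*% beta_dot) +
             stats::rnorm(nrow(X_mis), 0, sqrt(sigma2_dot)))
  }
  yhat_obs <- drop(X_obs %*% beta_hat)
  yhat_mis <- drop(X_mis %*% beta_dot)
  vapply(yhat_mis, function(yh) {
    pool <- order(abs(yhat_obs - yh))[seq_len(min(donors, length(yhat_obs)))]
    y_obs[pool[sample.int(length(pool), 1L)]]
  }, 0)
}

#' @export
print.sg_imputed <- function(x, ...) {
  cat(sprintf("<sg_imputed> %d completed table(s), engine %s, %d iteration(s)\n",
              x$m, x$engine, x$maxit))
  if (length(x$targets))
    cat("  imputed:", paste(x$targets, collapse = ", "), "\n")
  else cat("  no missing values; tables are copies of the input\n")
  invisible(x)
}

#' Completed tables from an imputation
#'
#' @param x an `sg_imputed` object.
#' @return list of `m` completed cohort data.frames.
#' @export
completed_tables <- function(x) {
  stopifnot(inherits(x, "sg_imputed"))
  x$completed
}
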