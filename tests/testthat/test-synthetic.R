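test_that("generators are fully deterministic given a seed", {
  a <- generate_transcript(n_tokens = 120, seed = 14)
  b <- generate_transcript(n_tokens = 120, seed = 14)
  expect_identical(a, b)
  expect_false(identical(a, generate_transcript(n_tokens = 120, seed = 15)))

  ca <- generate_cohort(n = 40, seed = 14, missing_rate = 0.25)
  cb <- generate_cohort(n = 40, seed = 14, missing_rate = 0.25)
  expect_identical(ca, cb)
})

test_that("degenerate transcript settings behave as specified", {
  # no returns, sampling without replacement: all tokens distinct
  tr <- generate_transcript(n_tokens = 40, vocab_size = 40, p_return = 0,
                            distinct = TRUE, seed = 1)
  st <- token_stream(tr)
  expect_equal(length(unique(st$token)), 40L)
  expect_equal(lsc(speech_graph(tr)), 1L)

  # single-word vocabulary: one node regardless of length
  tr <- generate_transcript(n_tokens = 50, vocab_size = 1, seed = 2)
  cc <- connectedness(speech_graph(tr))
  expect_equal(cc, list(lcc = 1L, lsc = 1L))

  expect_error(generate_transcript(n_tokens = 10, vocab_size = 5,
                                   distinct = TRUE),
               "without replacement|vocab_size")
})

test_that("generated connectedness spans the observed corpus ranges", {
  # short sparse narratives reach the low end, long looping ones the high end
  short <- t(sapply(1:30, function(s) {
    g <- speech_graph(generate_transcript(n_tokens = 35, p_return = 0.1,
                                          p_break = 0.3, seed = s))
    unlist(connectedness(g))
  }))
  long <- t(sapply(1:30, function(s) {
    g <- speech_graph(generate_transcript(n_tokens = 300, vocab_size = 600,
                                          p_return = 0.3, p_break = 0.1,
                                          seed = 100 + s))
    unlist(connectedness(g))
  }))
  expect_lte(min(short[, "lcc"]), 14)
  expect_equal(min(short[, "lsc"]), 1)
  expect_gte(max(long[, "lcc"]), 151)
  expect_gte(max(long[, "lsc"]), 117)
})

test_that("mean LSC rises with moderate return probability then collapses", {
  mean_lsc_at <- function(p, seeds) {
    mean(vapply(seeds, function(s)
      lsc(speech_graph(generate_transcript(p_return = p, seed = s))), 0))
  }
  seeds <- 1:60
  low <- mean_lsc_at(0.05, seeds)
  mid <- mean_lsc_at(0.35, seeds)
  high <- mean_lsc_at(0.95, seeds)
  expect_gt(mid, low)    # returns create reciprocal paths
  expect_gt(mid, high)   # near-total returns collapse the vocabulary
})

test_that("MCAR deletion hits the expected number of fluency cells", {
  coh <- generate_cohort(n = 128, seed = 16)
  expect_identical(apply_missingness(coh, rate = 0, seed = 1), coh)

  del <- apply_missingness(coh, rate = 0.25, seed = 17)
  n_missing <- sum(is.na(del$semantic_fluency)) +
    sum(is.na(del$phonemic_fluency))
  bounds <- qbinom(c(0.005, 0.995), size = 2L * 128L, prob = 0.25)
  expect_gte(n_missing, bounds[1L])
  expect_lte(n_missing, bounds[2L])

  expect_error(apply_missingness(generate_cohort(n = 10, seed = 1),
                                 rate = 0.999, seed = 2),
               class = "sgdem_cannot_impute")
})

test_that("severity scores follow the generating linear model", {
  coh <- generate_cohort(n = 200, seed = 18)
  b <- sg_default_coefs()["mmse", ]
  lp <- b["intercept"] + b["hdrs"] * coh$hdrs +
    b["onset_age"] * coh$onset_age + b["education"] * coh$education +
    b["fluency_z"] * fluency_z(coh) + b["connectedness"] * coh$mean_lcc
  resid <- coh$mmse - lp
  # construction R^2 targeted at 0.44: residual and signal variances match
  r2 <- var(lp) / (var(lp) + var(resid))
  expect_gt(r2, 0.35); expect_lt(r2, 0.53)
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(200))
})

test_that("clipping keeps severity scores inside instrument ranges", {
  coh <- generate_cohort(n = 100, seed = 19, clip = TRUE)
  expect_true(all(coh$mmse >= 0 & coh$mmse <= 30))
  expect_true(all(coh$mdrs >= 0 & coh$mdrs <= 144))
  expect_true(all(coh$bds >= 0 & coh$bds <= 28))
})

test_that("transcript-backed cohorts carry windowed means through the pipeline", {
  out <- generate_cohort(n = 12, seed = 20, transcripts = TRUE)
  expect_length(out$transcripts, 12L)
  expect_true(all(out$cohort$mean_lcc <= 30))
  expect_true(all(out$cohort$mean_lsc <= out$cohort$mean_lcc))
  w <- windowed_connectedness(out$transcripts[[3L]])
  expect_equal(w$mean_lcc, out$cohort$mean_lcc[3L])
  expect_equal(w$mean_lsc, out$cohort$mean_lsc[3L])
})

test_that("end-to-end recovery: CIs cover the generating coefficient", {
  # transcripts -> windowing -> cohort -> regression, 20 replicates
  hits <- 0L
  b_true <- sg_default_coefs()["mmse", "connectedness"]
  for (r in 1:20) {
    out <- generate_cohort(n = 40, seed = 500 + r, transcripts = TRUE)
    fit <- fit_severity(out$cohort, "mmse", "lcc", m = 1)
    ci <- confint(fit)["connectedness", ]
    hits <- hits + (ci[1L] <= b_true && b_true <= ci[2L])
  }
  expect_gte(hits, 17L)   # P(X <= 16 | p = 0.95) ~ 0.003
})
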