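test_that("window enumeration emits exactly the complete 0-based spans", {
  expect_equal(enumerate_windows(30, window_spec(30, 3)),
               data.frame(start = 0L, end = 30L))
  expect_equal(enumerate_windows(36, window_spec(30, 3)),
               data.frame(start = c(0L, 3L, 6L), end = c(30L, 33L, 36L)))
  # 37..38 tokens still give the same three windows: no partial emitted
  expect_equal(nrow(enumerate_windows(38, window_spec(30, 3))), 3L)
  expect_error(enumerate_windows(29, window_spec(30, 3)),
               class = "sgdem_too_short")
  expect_error(window_spec(10, 11), "step")
})

test_that("consecutive windows overlap by (W - s)/W tokens", {
  for (spec in list(window_spec(30, 3), window_spec(20, 5), window_spec(8, 8))) {
    win <- enumerate_windows(100, spec)
    if (nrow(win) > 1L) {
      shared <- win$end[1L] - win$start[2L]
      expect_equal(shared / spec$window_length,
                   (spec$window_length - spec$step) / spec$window_length)
    }
  }
})

test_that("windowed connectedness matches whole-graph values on one window", {
  # same word 30 times: single node per window
  tr <- transcript(list(rep("word", 30)), "rep")
  w <- windowed_connectedness(tr)
  expect_equal(w$n_windows, 1L)
  expect_equal(w$mean_lcc, 1)
  expect_equal(w$mean_lsc, 1)

  # 30 all-distinct tokens
  w <- windowed_connectedness(distinct_transcript(30))
  expect_equal(w$mean_lcc, 30)
  expect_equal(w$mean_lsc, 1)

  # n_tokens == window_length: means equal whole-transcript connectedness
  tr <- generate_transcript(n_tokens = 30, seed = 5)
  w <- windowed_connectedness(tr)
  cc <- connectedness(speech_graph(tr))
  expect_equal(w$mean_lcc, cc$lcc)
  expect_equal(w$mean_lsc, cc$lsc)
})

test_that("windows cross utterance boundaries but edges respect them", {
  # two 15-token utterances: one 30-token window, no bridging edge
  tr <- transcript(list(sprintf("a%02d", 1:15), sprintf("b%02d", 1:15)), "x")
  w <- windowed_connectedness(tr)
  expect_equal(w$n_windows, 1L)
  # all 30 types distinct but split into two undirected chains of 15
  expect_equal(w$per_window$lcc, 15L)
  expect_equal(w$per_window$lsc, 1L)
})

test_that("periodic sequences with period dividing step give constant windows", {
  tr <- transcript(list(rep(c("a", "b", "c"), 20)), "periodic")
  w <- windowed_connectedness(tr, window_spec(30, 3))
  expect_true(all(w$per_window$lcc == w$per_window$lcc[1L]))
  expect_true(all(w$per_window$lsc == w$per_window$lsc[1L]))
  expect_equal(w$mean_lcc, w$per_window$lcc[1L])
  expect_equal(w$mean_lsc, w$per_window$lsc[1L])
})

test_that("tokens beyond the last complete window do not change the means", {
  tr_full <- generate_transcript(n_tokens = 32, seed = 12)
  st <- token_stream(tr_full)
  keep <- st[1:30, ]
  tr_trunc <- transcript(split(keep$token, keep$utterance), "trunc")
  w1 <- windowed_connectedness(tr_full)
  w2 <- windowed_connectedness(tr_trunc)
  expect_equal(w1$mean_lcc, w2$mean_lcc)
  expect_equal(w1$mean_lsc, w2$mean_lsc)
})

test_that("window counts and invariants hold on generated transcripts", {
  for (seed in 1:8) {
    tr <- generate_transcript(n_tokens = sample(30:200, 1), seed = seed,
                              p_return = runif(1, 0, 0.8))
    w <- windowed_connectedness(tr)
    spec <- w$spec
    expect_equal(w$n_windows,
                 floor((w$n_tokens - spec$window_length) / spec$step) + 1)
    expect_true(all(w$per_window$lsc >= 1L))
    expect_true(all(w$per_window$lsc <= w$per_window$lcc))
    expect_true(all(w$per_window$lcc <= spec$window_length))
    expect_lte(w$mean_lsc, w$mean_lcc)
  }
})

test_that("too-short transcripts error with participant id and token count", {
  tr <- generate_transcript(n_tokens = 20, seed = 3, participant_id = "shorty")
  err <- tryCatch(windowed_connectedness(tr), condition = identity)
  expect_s3_class(err, "sgdem_too_short")
  expect_equal(err$participant_id, "shorty")
  expect_equal(err$n_tokens, 20L)
})

test_that("batch analysis separates results from logged exclusions", {
  trs <- c(lapply(1:4, function(s)
             generate_transcript(n_tokens = 80, seed = s,
                                 participant_id = paste0("ok", s))),
           lapply(1:3, function(s)
             generate_transcript(n_tokens = 10 + s, seed = 100 + s,
                                 participant_id = paste0("short", s))))
  out <- analyze_transcripts(trs)
  expect_equal(nrow(out$results), 4L)
  expect_equal(nrow(out$exclusions), 3L)
  expect_setequal(out$exclusions$participant_id, paste0("short", 1:3))
  expect_match(out$exclusions$reason, "fewer than 30 words")
  expect_true(all(out$results$mean_lsc <= out$results$mean_lcc))
})

test_that("batch analysis reads a directory of plain-text transcripts", {
  d <- withr::local_tempdir()
  for (s in 1:3)
    write_plaintext(generate_transcript(n_tokens = 50, seed = s,
                                        participant_id = paste0("p", s)),
                    file.path(d, paste0("p", s, ".txt")))
  write_plaintext(generate_transcript(n_tokens = 12, seed = 9,
                                      participant_id = "tiny"),
                  file.path(d, "tiny.txt"))
  out <- analyze_transcripts(d)
  expect_equal(nrow(out$results), 3L)
  expect_equal(out$exclusions$participant_id, "tiny")
})
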