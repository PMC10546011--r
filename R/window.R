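#' Moving-window specification
#'
#' The verbosity control: graph attributes are computed on fixed-length
#' overlapping token windows and averaged, so that participants who simply
#' talk more do not get larger graphs. Defaults are a 30-word window sliding
#' in steps of 3 words, i.e. 90% overlap between consecutive windows.
#'
#' @param window_length window size in tokens (default 30).
#' @param step slide in tokens (default 3); must not exceed `window_length`.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(window_length = 30L, step = 3L) {
  window_length <- as.integer(window_length); step <- as.integer(step)
  stopifnot(window_length >= 1L, step >= 1L)
  if (step > window_length)
    stop("step must be <= window_length")
  structure(list(window_length = window_length, step = step),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> length %d, step %d (overlap %.0f%%)\n",
              x$window_length, x$step,
              100 * (x$window_length - x$step) / x$window_length))
  invisible(x)
}

#' Enumerate complete windows over a token sequence
#'
#' Spans are 0-based half-open `[k*step, k*step + window_length)` for
#' `k = 0, 1, ...`; trailing tokens that cannot fill a complete window are
#' not emitted as a partial window. A sequence shorter than one window is an
#' error — such transcripts are excluded from analysis, mirroring the
#' exclusion of speech samples with fewer than 30 words.
#'
#' @param n_tokens length of the token sequence.
#' @param spec a [window_spec()].
#' @return data.frame with 0-based half-open columns `start`, `end`.
#' @examples
#' enumerate_windows(36, window_spec(30, 3))  # starts 0, 3, 6
#' @export
enumerate_windows <- function(n_tokens, spec = window_spec()) {
  n_tokens <- as.integer(n_tokens)
  if (n_tokens < spec$window_length)
    sg_stop(sprintf("transcript too short: %d tokens < window length %d",
                    n_tokens, spec$window_length),
            "sgdem_too_short", n_tokens = n_tokens)
  starts <- seq.int(0L, n_tokens - spec$window_length, by = spec$step)
  data.frame(start = starts, end = starts + spec$window_length)
}

#' Windowed connectedness of a transcript
#'
#' Slides the window over the transcript's concatenated token stream;
#' within each window a word-trajectory graph is built that still respects
#' the original utterance boundaries (a window may span several utterances,
#' but no edge crosses a boundary), and LCC/LSC are computed per window.
#' The grand means are the plain arithmetic means over all complete windows
#' — these are the connectedness measures carried into the severity
#' regressions.
#'
#' @param x an `sg_transcript`.
#' @param spec a [window_spec()].
#' @return object of class `sg_windowed`: list with `participant_id`,
#'   `n_tokens`, `n_windows`, `per_window` (data.frame `start`, `end`, `lcc`,
#'   `lsc`), `mean_lcc`, `mean_lsc`, `spec`.
#' @seealso [analyze_transcripts()] for batch processing with an exclusion
#'   log.
#' @export
windowed_connectedness <- function(x, spec = window_spec()) {
  stopifnot(inherits(x, "sg_transcript"))
  stream <- token_stream(x)
  n <- nrow(stream)
  if (n < spec$window_length)
    sg_stop(sprintf("transcript too short: participant '%s' has %d tokens < window length %d",
                    x$participant_id, n, spec$window_length),
            "sgdem_too_short",
            participant_id = x$participant_id, n_tokens = n)
  win <- enumerate_windows(n, spec)
  ids <- match(stream$token, unique(stream$token))
  same_utt <- stream$utterance[-n] == stream$utterance[-1L]
  res <- matrix(0L, nrow(win), 2L)
  for (i in seq_len(nrow(win))) {
    idx <- (win$start[i] + 1L):win$end[i]
    cc <- conn_from_stream(ids[idx], same_utt[idx[-length(idx)]])
    res[i, ] <- c(cc$lcc, cc$lsc)
  }
  structure(
    list(participant_id = x$participant_id,
         n_tokens = n,
         n_windows = nrow(win),
         per_window = data.frame(start = win$start, end = win$end,
                                 lcc = res[, 1L], lsc = res[, 2L]),
         mean_lcc = mean(res[, 1L]),
         mean_lsc = mean(res[, 2L]),
         spec = spec),
    class = "sg_windowed")
}

#' @export
print.sg_windowed <- function(x, ...) {
  cat(sprintf(
    "<sg_windowed> participant '%s': %d tokens, %d windows (length %d, step %d)\n  mean LCC %.2f, mean LSC %.2f\n",
    x$participant_id, x$n_tokens, x$n_windows,
    x$spec$window_length, x$spec$step, x$mean_lcc, x$mean_lsc))
  invisible(x)
}

#' Batch windowed-connectedness analysis with an exclusion log
#'
#' Applies [windowed_connectedness()] to a list of transcripts (or every
#' `.txt`/`.cha` file in a directory). Transcripts shorter than the window
#' are not an error here: they are collected into a machine-readable
#' exclusion table with their token counts, and analysis proceeds on the
#' rest.
#'
#' @param x list of `sg_transcript` objects, or a directory path.
#' @param spec a [window_spec()].
#' @param speaker speaker code passed to [read_chat()] for `.cha` files.
#' @return list with `results` (data.frame: `participant_id`, `n_tokens`,
#'   `n_windows`, `mean_lcc`, `mean_lsc`) and `exclusions` (data.frame:
#'   `participant_id`, `n_tokens`, `reason`).
#' @export
analyze_transcripts <- function(x, spec = window_spec(), speaker = "PAR") {
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- list.files(x, pattern = "\\.(txt|cha)$", full.names = TRUE)
    x <- lapply(files, function(f) {
      if (grepl("\\.cha$", f)) read_chat(f, speaker = speaker)
      else read_plaintext(f)
    })
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "sg_transcript")))
  rows <- list(); excl <- list()
  for (tr in x) {
    w <- tryCatch(windowed_connectedness(tr, spec), sgdem_too_short = identity)
    if (inherits(w, "condition")) {
      excl[[length(excl) + 1L]] <- data.frame(
        participant_id = tr$participant_id, n_tokens = tr$n_tokens,
        reason = sprintf("fewer than %d words", spec$window_length),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = w$participant_id, n_tokens = w$n_tokens,
        n_windows = w$n_windows, mean_lcc = w$mean_lcc,
        mean_lsc = w$mean_lsc, stringsAsFactors = FALSE)
    }
  }
  empty_res <- data.frame(participant_id = character(0), n_tokens = integer(0),
                          n_windows = integer(0), mean_lcc = numeric(0),
                          mean_lsc = numeric(0), stringsAsFactors = FALSE)
  empty_exc <- data.frame(participant_id = character(0), n_tokens = integer(0),
                          reason = character(0), stringsAsFactors = FALSE)
  list(results = if (length(rows)) do.call(rbind, rows) else empty_res,
       exclusions = if (length(excl)) do.call(rbind, excl) else empty_exc)
}
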