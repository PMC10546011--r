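#' Construct a transcript
#'
#' A transcript is an ordered list of utterances, each an ordered character
#' vector of normalized word tokens, for a single participant. Utterance
#' boundaries matter: they encode interruptions in spontaneous speech, and no
#' word-trajectory edge is ever drawn across a boundary (see
#' [speech_graph()]). Empty utterances are dropped.
#'
#' @param utterances list of character vectors of tokens, one per utterance,
#'   in spoken order. Tokens are used as given; apply [normalize_tokens()]
#'   first if they are raw.
#' @param participant_id single string identifying the speaker.
#' @return An object of class `sg_transcript` with elements `participant_id`,
#'   `utterances` and `n_tokens`.
#' @seealso [read_plaintext()], [read_chat()], [generate_transcript()]
#' @export
transcript <- function(utterances, participant_id = "unknown") {
  stopifnot(is.list(utterances), is.character(participant_id),
            length(participant_id) == 1L)
  utterances <- lapply(unname(utterances), function(u) unname(as.character(u)))
  utterances <- utterances[vapply(utterances, length, 0L) > 0L]
  structure(
    list(participant_id = participant_id,
         utterances = utterances,
         n_tokens = sum(vapply(utterances, length, 0L))),
    class = "sg_transcript")
}

#' @export
print.sg_transcript <- function(x, ...) {
  cat(sprintf("<sg_transcript> participant '%s': %d utterances, %d tokens\n",
              x$participant_id, length(x$utterances), x$n_tokens))
  invisible(x)
}

#' Extract the concatenated token stream of a transcript
#'
#' Returns every token in spoken order together with the index of the
#' utterance it belongs to; consecutive tokens with differing utterance
#' indices are separated by an interruption boundary.
#'
#' @param x an `sg_transcript`.
#' @return data.frame with columns `token` and `utterance`.
#' @export
token_stream <- function(x) {
  stopifnot(inherits(x, "sg_transcript"))
  lens <- vapply(x$utterances, length, 0L)
  data.frame(token = unlist(x$utterances, use.names = FALSE),
             utterance = rep.int(seq_along(lens), lens),
             stringsAsFactors = FALSE)
}

# Filled pauses treated as removable when drop_fillers = TRUE. They are kept
# by default: they are words the speaker produced, and removing them changes
# window contents.
.sg_fillers <- c("uh", "um", "uhm", "er", "ah", "eh", "hm", "hmm", "mhm", "mm")

#' Normalize raw word tokens
#'
#' Lowercases, strips leading/trailing punctuation (internal apostrophes and
#' hyphens are retained, so contractions and possessives survive) and drops
#' tokens that become empty. Filled pauses (uh, um, ...) are kept by default;
#' `drop_fillers = TRUE` removes them. An optional `lemmatizer` function
#' (character vector in, character vector out) can be supplied; none is
#' applied by default, so nodes are surface forms.
#'
#' Normalization is idempotent: applying it twice gives the same result.
#'
#' @param raw character vector of raw tokens.
#' @param drop_fillers drop filled pauses? Default `FALSE`.
#' @param lemmatizer optional function mapping tokens to lemmas.
#' @return character vector of normalized tokens (possibly shorter than
#'   `raw`).
#' @examples
#' normalize_tokens(c("The", "boy's", "..."))   # "the" "boy's"
#' @export
normalize_tokens <- function(raw, drop_fillers = FALSE, lemmatizer = NULL) {
  x <- tolower(as.character(raw))
  # strip punctuation at token edges only; ’ is the curly apostrophe,
  # kept internally like the ASCII one
  punct <- "[\\p{P}\\p{S}]"
  keep_internal <- "[^\\p{L}\\p{N}'’-]"
  x <- gsub(paste0("^", punct, "+|", punct, "+$"), "", x, perl = TRUE)
  x <- gsub(keep_internal, "", x, perl = TRUE)
  x <- gsub("\\s+", "", x, perl = TRUE)
  x <- x[nzchar(x)]
  # edge-stripping again in case symbol removal exposed new edges
  x <- gsub("^['’-]+|['’-]+$", "", x, perl = TRUE)
  x <- x[nzchar(x)]
  if (drop_fillers) x <- x[!x %in% .sg_fillers]
  if (!is.null(lemmatizer)) {
    x <- as.character(lemmatizer(x))
    x <- x[nzchar(x)]
  }
  x
}

#' Read a plain-text transcript
#'
#' One utterance per line; blank lines are ignored. Line breaks are the
#' interruption boundaries: the writer of the file is responsible for placing
#' speech following an interruption on a new line.
#'
#' @param path path to a UTF-8 text file.
#' @param participant_id identifier; defaults to the file name without
#'   extension.
#' @inheritParams normalize_tokens
#' @return an `sg_transcript`.
#' @export
read_plaintext <- function(path, participant_id = NULL,
                           drop_fillers = FALSE, lemmatizer = NULL) {
  if (!file.exists(path))
    sg_stop(sprintf("file not found: %s", path), "sgdem_io_error")
  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  utts <- lapply(lines, function(l)
    normalize_tokens(strsplit(trimws(l), "\\s+")[[1]],
                     drop_fillers = drop_fillers, lemmatizer = lemmatizer))
  tr <- transcript(utts, participant_id)
  if (tr$n_tokens == 0L)
    sg_stop(sprintf("empty transcript: %s", path), "sgdem_empty_transcript")
  tr
}

#' Write a transcript as plain text
#'
#' One utterance per line, tokens space-separated. Reading the file back with
#' [read_plaintext()] reproduces the transcript exactly (tokens are already
#' normalized, and normalization is idempotent).
#'
#' @param x an `sg_transcript`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plaintext <- function(x, path) {
  stopifnot(inherits(x, "sg_transcript"))
  writeLines(vapply(x$utterances, paste, "", collapse = " "), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a CHAT (.cha) transcript
#'
#' Minimal reader for the TalkBank CHAT format: selects the main-tier lines
#' of one speaker (`*PAR:` by default, including tab-indented continuation
#' lines), ignores header (`@`) and dependent (`%mor:`, `%gra:`, ...) tiers,
#' strips CHAT markup, and normalizes the remaining tokens. Each main-tier
#' line becomes one utterance, so transcribed interruption boundaries are
#' preserved.
#'
#' Markup handling: bracketed codes (`[/]`, `[//]`, `[: text]`, `[* ...]`,
#' ...) are removed while the words they annotate are kept, so retraced or
#' repeated words remain in the token stream — repetition is exactly what the
#' strongly connected component measures. Angle-bracket groups keep their
#' content; `&=events` and unintelligible markers (`xxx`, `yyy`, `www`) are
#' dropped; `&-uh` filled pauses keep the word; parentheses marking elided
#' material are removed so `(be)cause` reads `because`; `word@x` form markers
#' and in-word lengthening colons are stripped; timestamps are discarded.
#'
#' @param path path to a `.cha` file.
#' @param speaker three-letter speaker code of the main tier to read
#'   (without `*` or `:`), default `"PAR"`.
#' @inheritParams normalize_tokens
#' @return an `sg_transcript` with `participant_id` taken from the file name.
#' @export
read_chat <- function(path, speaker = "PAR",
                      drop_fillers = FALSE, lemmatizer = NULL) {
  if (!file.exists(path))
    sg_stop(sprintf("file not found: %s", path), "sgdem_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tag <- paste0("*", toupper(speaker), ":")
  utt_lines <- character(0)
  in_tier <- FALSE
  for (l in lines) {
    if (startsWith(l, tag)) {
      utt_lines <- c(utt_lines, sub("^\\*[A-Z0-9]+:\\s*", "", l))
      in_tier <- TRUE
    } else if (in_tier && grepl("^[\t ]", l)) {
      utt_lines[length(utt_lines)] <-
        paste(utt_lines[length(utt_lines)], trimws(l))
    } else {
      in_tier <- FALSE
    }
  }
  if (!length(utt_lines))
    sg_stop(sprintf("empty transcript: no *%s tier in %s", toupper(speaker),
                    basename(path)),
            "sgdem_empty_transcript")
  utts <- lapply(utt_lines, function(l)
    normalize_tokens(strsplit(strip_chat_markup(l), "\\s+")[[1]],
                     drop_fillers = drop_fillers, lemmatizer = lemmatizer))
  tr <- transcript(utts, sub("\\.[^.]*$", "", basename(path)))
  if (tr$n_tokens == 0L)
    sg_stop(sprintf("empty transcript: %s", path), "sgdem_empty_transcript")
  tr
}

# Strip CHAT markup from one main-tier line, leaving plain words.
strip_chat_markup <- function(l) {
  l <- gsub("\x15[^\x15]*\x15", " ", l)           # bullet timestamps
  l <- gsub("\\[[^][]*\\]", " ", l)               # [/], [//], [: x], [* x], ...
  l <- gsub("[<>]", " ", l)                        # keep angle-group content
  l <- gsub("&=\\S+", " ", l)                      # events: &=laughs
  l <- gsub("&[-+]?", "", l)                       # &-uh, &+fr fragments: keep word
  l <- gsub("\\+\\S*", " ", l)                     # +..., +//. terminators
  l <- gsub("\\b(xxx|yyy|www)\\b", " ", l)         # unintelligible
  l <- gsub("\\(\\.{1,3}\\)", " ", l)              # pauses (.) (..) (...)
  l <- gsub("[()]", "", l)                         # elisions: (be)cause
  l <- gsub("@\\S*", "", l)                        # form markers: word@o
  l <- gsub("(\\w):", "\\1", l)                    # lengthening: no: -> no
  l
}
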