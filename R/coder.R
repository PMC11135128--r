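#' Tokenize an utterance
#'
#' Lowercases, strips punctuation (apostrophes inside words are kept, and
#' typographic apostrophes are normalised to `'`), splits on whitespace, and
#' drops a leading wake word ("alexa" by default).
#'
#' @param text utterance string (vectorised over length-1 input only).
#' @param wake_words lowercase wake words removed when leading.
#' @return character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize("Alexa, play Akinator")
tokenize <- function(text, wake_words = "alexa") {
  x <- tolower(text)
  x <- gsub("’", "'", x)
  x <- gsub("[^a-z0-9' ]", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- gsub("^'+|'+$", "", toks)
  toks <- toks[nzchar(toks)]
  while (length(toks) > 0 && toks[1] %in% wake_words) {
    toks <- toks[-1]
  }
  toks
}

#' Word-overlap operators
#'
#' `find_same_words()` returns the tokens two utterances share;
#' `find_different_words()` returns the tokens unique to each side. Together
#' with the shared set, the two difference sets partition the union of both
#' token sets. These operators drive the detection of repeated and corrected
#' commands.
#'
#' @param a,b utterance strings.
#' @param wake_words passed to [tokenize()].
#' @return `find_same_words`: a character vector (set) of shared tokens.
#'   `find_different_words`: a list with elements `only_a` and `only_b`.
#' @export
#' @examples
#' find_same_words("alexa play music", "play music now")
#' find_different_words("play music", "play jazz")
find_same_words <- function(a, b, wake_words = "alexa") {
  intersect(unique(tokenize(a, wake_words)), unique(tokenize(b, wake_words)))
}

#' @rdname find_same_words
#' @export
find_different_words <- function(a, b, wake_words = "alexa") {
  ta <- unique(tokenize(a, wake_words))
  tb <- unique(tokenize(b, wake_words))
  list(only_a = setdiff(ta, tb), only_b = setdiff(tb, ta))
}

phrase_in_tokens <- function(phrase_tokens, tokens) {
  k <- length(phrase_tokens)
  n <- length(tokens)
  if (k == 0 || n < k) return(FALSE)
  for (i in seq_len(n - k + 1)) {
    if (all(tokens[i:(i + k - 1)] == phrase_tokens)) return(TRUE)
  }
  FALSE
}

#' Match an utterance to a category
#'
#' Returns the highest-precedence category whose keyword phrase occurs as a
#' contiguous token run in `tokens`, or `NA` when no keyword matches. Phrase
#' matching is exact contiguous-token matching after normalisation; the
#' lexicon's precedence order resolves utterances matching several
#' categories.
#'
#' @param tokens token vector from [tokenize()].
#' @param lexicon an `sva_lexicon`.
#' @return a category name, or `NA_character_`.
#' @export
#' @examples
#' match_category(tokenize("alexa tell me a joke"), default_lexicon())
match_category <- function(tokens, lexicon) {
  for (cat in lexicon$precedence) {
    for (kw in lexicon$keywords[[cat]]) {
      if (phrase_in_tokens(strsplit(kw, " ")[[1]], tokens)) return(cat)
    }
  }
  NA_character_
}

# TRUE iff the token sequence is a concatenation of continuation phrases
# ("yes", "no", "i don't know", ...). Dynamic programming over positions so
# multi-word phrases are handled.
is_continuation <- function(tokens, lexicon) {
  n <- length(tokens)
  if (n == 0) return(FALSE)
  phrases <- lapply(lexicon$continuation_tokens,
                    function(p) strsplit(p, " ")[[1]])
  reach <- logical(n + 1)
  reach[1] <- TRUE
  for (i in seq_len(n)) {
    if (!reach[i]) next
    for (p in phrases) {
      k <- length(p)
      if (i + k - 1 <= n && all(tokens[i:(i + k - 1)] == p)) {
        reach[i + k] <- TRUE
      }
    }
  }
  reach[n + 1]
}

#' Segment a log into coded episodes
#'
#' The core coding rule: repeated keywords or phrases within a single,
#' temporally continuous interaction count as one interaction. User
#' utterances are scanned in time order. A matched utterance opens an
#' episode in its category. A subsequent user utterance extends the open
#' episode when it arrives within `gap_seconds` of the previous user
#' utterance and (a) matches the same category, (b) consists solely of
#' continuation tokens (the yes/no answers of a game session), or (c)
#' matches no category but shares at least one token with the previous user
#' utterance (a repeated or corrected command that garbles the keyword). An
#' utterance matching a different category always closes the open episode
#' and opens a new one. Unmatched, non-continuation utterances with no open
#' episode are dropped. Assistant utterances never open or extend episodes;
#' they only determine episode completion (see [flag_completion()]).
#'
#' @param log a week-assigned, sorted `participant_log`.
#' @param lexicon an `sva_lexicon`.
#' @param gap_seconds maximum silence between user utterances of one
#'   episode; default 60.
#' @return a data.frame of episodes with columns `participant_id`,
#'   `category`, `code`, `week`, `start_ts`, `end_ts`, `n_user_commands`,
#'   `completed`, plus a list-column `record_refs` of row indices into
#'   `log$records`.
#' @export
segment_episodes <- function(log, lexicon = default_lexicon(),
                             gap_seconds = 60) {
  stopifnot(inherits(log, "participant_log"), gap_seconds > 0)
  r <- log$records
  if (nrow(r) > 0 && is.unsorted(as.numeric(r$timestamp))) {
    stop("log records are not sorted by timestamp")
  }
  if (nrow(r) > 0 && anyNA(r$week)) {
    stop("log has unassigned weeks; call assign_weeks() first")
  }
  user_idx <- which(r$role == "user")

  episodes <- list()
  open <- NULL   # list(category, refs, last_user_ts, prev_text)

  close_open <- function() {
    if (!is.null(open)) episodes[[length(episodes) + 1]] <<- open
    open <<- NULL
  }

  for (i in user_idx) {
    ts <- r$timestamp[i]
    toks <- tokenize(r$text[i], lexicon$wake_words)
    cat_i <- match_category(toks, lexicon)

    if (!is.null(open)) {
      within_gap <-
        as.numeric(ts) - as.numeric(open$last_user_ts) <= gap_seconds
      if (!is.na(cat_i) && cat_i != open$category) {
        close_open()
      } else if (within_gap &&
                 ((!is.na(cat_i) && cat_i == open$category) ||
                  is_continuation(toks, lexicon) ||
                  (is.na(cat_i) &&
                   length(find_same_words(r$text[i], open$prev_text,
                                          lexicon$wake_words)) >= 1))) {
        open$refs <- c(open$refs, i)
        open$last_user_ts <- ts
        open$prev_text <- r$text[i]
        next
      } else {
        close_open()
      }
    }
    if (!is.na(cat_i)) {
      open <- list(category = cat_i, refs = i, last_user_ts = ts,
                   prev_text = r$text[i])
    }
  }
  close_open()

  cats <- categories()
  out <- data.frame(
    participant_id = rep(log$participant_id, length(episodes)),
    category = vapply(episodes, `[[`, character(1), "category"),
    stringsAsFactors = FALSE
  )
  out$code <- cats$code[match(out$category, cats$name)]
  out$week <- vapply(episodes, function(e) r$week[e$refs[1]], integer(1))
  out$start_ts <- as.POSIXct(
    vapply(episodes, function(e) as.numeric(r$timestamp[e$refs[1]]),
           numeric(1)),
    origin = "1970-01-01", tz = "UTC"
  )
  out$end_ts <- as.POSIXct(
    vapply(episodes,
           function(e) as.numeric(r$timestamp[e$refs[length(e$refs)]]),
           numeric(1)),
    origin = "1970-01-01", tz = "UTC"
  )
  out$n_user_commands <- vapply(episodes, function(e) length(e$refs),
                                integer(1))
  # completion: assistant responses from episode start up to gap_seconds
  # after its last command (but never past the next episode's start)
  n_ep <- nrow(out)
  completed <- logical(n_ep)
  if (n_ep > 0) {
    for (j in seq_len(n_ep)) {
      lo <- as.numeric(out$start_ts[j])
      hi <- as.numeric(out$end_ts[j]) + gap_seconds
      if (j < n_ep) hi <- min(hi, as.numeric(out$start_ts[j + 1]))
      in_span <- r$role == "assistant" &
        as.numeric(r$timestamp) >= lo & as.numeric(r$timestamp) < hi
      completed[j] <- flag_completion(out[j, , drop = FALSE],
                                      r[in_span, , drop = FALSE], lexicon)
    }
  }
  out$completed <- completed
  out$record_refs <- lapply(episodes, `[[`, "refs")
  out
}

empty_episodes <- function() {
  data.frame(
    participant_id = character(0), category = character(0),
    code = integer(0), week = integer(0),
    start_ts = as.POSIXct(character(0), tz = "UTC"),
    end_ts = as.POSIXct(character(0), tz = "UTC"),
    n_user_commands = integer(0), completed = logical(0)
  )
}

#' Flag episode completion
#'
#' An episode counts as completed when at least one assistant response fell
#' within its span and none of those responses contains a configured error
#' phrase (substring match after lowercasing).
#'
#' @param episode one episode row (as produced by [segment_episodes()]).
#' @param responses data.frame of assistant records within the episode span
#'   (columns `role`, `text`).
#' @param lexicon an `sva_lexicon` supplying `error_phrases`.
#' @return logical scalar.
#' @export
flag_completion <- function(episode, responses, lexicon = default_lexicon()) {
  resp <- responses[responses$role == "assistant", , drop = FALSE]
  if (nrow(resp) == 0) return(FALSE)
  txt <- tolower(resp$text)
  for (ph in lexicon$error_phrases) {
    if (any(grepl(ph, txt, fixed = TRUE))) return(FALSE)
  }
  TRUE
}

#' Write / read episode tables
#'
#' Episodes serialise to CSV with columns `participant_id`, `category`,
#' `code`, `week`, `start_ts`, `end_ts`, `n_user_commands`, `completed`
#' (record references are an in-memory convenience and are not written).
#'
#' @param episodes an episode data.frame.
#' @param path file path.
#' @return `write_episodes`: `path` invisibly; `read_episodes`: a
#'   data.frame.
#' @export
write_episodes <- function(episodes, path) {
  df <- episodes[, c("participant_id", "category", "code", "week",
                     "start_ts", "end_ts", "n_user_commands", "completed")]
  df$start_ts <- format(df$start_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  df$end_ts <- format(df$end_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    participant_id = "character", category = "character", code = "integer",
    week = "integer", start_ts = "character", end_ts = "character",
    n_user_commands = "integer", completed = "logical"
  ))
  df$start_ts <- as.POSIXct(df$start_ts, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%S")
  df$end_ts <- as.POSIXct(df$end_ts, tz = "UTC",
                          format = "%Y-%m-%dT%H:%M:%S")
  df
}
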