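# Independent brute-force oracles used to cross-check the coder.
# These deliberately re-derive the rules with different machinery
# (recursion, string regexes) rather than calling the implementation paths
# they validate.

# Can this token sequence be split into continuation phrases? (recursive)
oracle_is_continuation <- function(tokens, phrases) {
  if (length(tokens) == 0) return(FALSE)
  for (p in phrases) {
    pt <- strsplit(p, " ")[[1]]
    k <- length(pt)
    if (k <= length(tokens) && all(tokens[seq_len(k)] == pt)) {
      if (k == length(tokens)) return(TRUE)
      if (oracle_is_continuation(tokens[-seq_len(k)], phrases)) return(TRUE)
    }
  }
  FALSE
}

# All categories whose keyword occurs contiguously, via regex on the joined
# token string; first in precedence order wins.
oracle_match <- function(text, lexicon) {
  toks <- tokenize(text, lexicon$wake_words)
  joined <- paste(toks, collapse = " ")
  hits <- character(0)
  for (cat in names(lexicon$keywords)) {
    for (kw in lexicon$keywords[[cat]]) {
      pat <- paste0("(^| )", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw),
                    "( |$)")
      if (grepl(pat, joined)) {
        hits <- c(hits, cat)
        break
      }
    }
  }
  if (length(hits) == 0) return(NA_character_)
  lexicon$precedence[min(match(hits, lexicon$precedence))]
}

# Brute-force episode enumeration: maximal contiguous runs of user
# utterances satisfying the extension predicate.
oracle_segment <- function(log, lexicon, gap_seconds) {
  r <- log$records
  u_idx <- which(r$role == "user")
  n <- length(u_idx)
  cats <- vapply(u_idx, function(i) {
    m <- match_category(tokenize(r$text[i], lexicon$wake_words), lexicon)
    if (is.na(m)) "" else m
  }, character(1))
  eps <- list()
  i <- 1
  while (i <= n) {
    if (cats[i] == "") {
      i <- i + 1
      next
    }
    cat0 <- cats[i]
    j <- i
    while (j < n) {
      nxt <- j + 1
      if (cats[nxt] != "" && cats[nxt] != cat0) break
      dt <- as.numeric(r$timestamp[u_idx[nxt]]) -
        as.numeric(r$timestamp[u_idx[j]])
      toks <- tokenize(r$text[u_idx[nxt]], lexicon$wake_words)
      prev_toks <- tokenize(r$text[u_idx[j]], lexicon$wake_words)
      extend <- dt <= gap_seconds &&
        (cats[nxt] == cat0 ||
         oracle_is_continuation(toks, lexicon$continuation_tokens) ||
         (cats[nxt] == "" && length(intersect(toks, prev_toks)) >= 1))
      if (!extend) break
      j <- nxt
    }
    eps[[length(eps) + 1]] <- data.frame(
      category = cat0,
      week = r$week[u_idx[i]],
      start_ts = r$timestamp[u_idx[i]],
      end_ts = r$timestamp[u_idx[j]],
      n_user_commands = as.integer(j - i + 1),
      stringsAsFactors = FALSE
    )
    i <- j + 1
  }
  if (length(eps) == 0) {
    data.frame(category = character(0), week = integer(0),
               start_ts = as.POSIXct(character(0), tz = "UTC"),
               end_ts = as.POSIXct(character(0), tz = "UTC"),
               n_user_commands = integer(0))
  } else {
    do.call(rbind, eps)
  }
}
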