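# In-code fixtures shared across test files.

make_log <- function(texts, roles = NULL, gaps = NULL,
                     start = "2023-01-02 09:00:00", id = "T01") {
  n <- length(texts)
  if (is.null(roles)) roles <- rep("user", n)
  if (is.null(gaps)) gaps <- rep(10, n)   # gaps[1] is offset from start
  ts <- as.POSIXct(start, tz = "UTC") + cumsum(gaps)
  records <- data.frame(
    timestamp = ts, role = roles, text = texts, week = NA_integer_,
    stringsAsFactors = FALSE
  )
  assign_weeks(svacoder:::new_participant_log(id, records))
}

# Random small log drawn from a pool mixing keyword commands, repeats,
# continuations, overlap-only corrections and chatter, with gaps straddling
# the 60 s threshold.
random_small_log <- function(seed, max_records = 20) {
  set.seed(seed)
  pool <- c(
    "alexa play some music", "music please", "play it again",
    "alexa what's the weather today", "weather please",
    "alexa play akinator", "yes", "no", "i don't know", "stop",
    "alexa tell me a joke", "another joke",
    "alexa good morning", "alexa call my daughter",
    "hello there", "what time is dinner", "alexa open big sky",
    "alexa turn the volume up", "repeat"
  )
  n <- sample(1:max_records, 1)
  gaps <- sample(c(2, 10, 30, 59, 60, 61, 90, 300), n, replace = TRUE)
  roles <- sample(c("user", "assistant"), n, replace = TRUE,
                  prob = c(0.85, 0.15))
  make_log(sample(pool, n, replace = TRUE), roles, gaps,
           id = sprintf("R%03d", seed))
}

# The multi-turn game worked example: one command plus yes/no answers.
akinator_log <- function(gaps = c(0, 10, 10, 10, 10)) {
  make_log(
    c("Alexa, play Akinator", "Yes", "No", "I don't know, Akinator", "Yes"),
    gaps = gaps
  )
}

# pairs table with a given 2x2 confusion matrix [[aa, ab], [ba, bb]]
confusion_pairs <- function(aa, ab, ba, bb,
                            codes = c("Music", "Joke")) {
  data.frame(
    case_id = as.character(seq_len(aa + ab + ba + bb)),
    code_a = c(rep(codes[1], aa + ab), rep(codes[2], ba + bb)),
    code_b = c(rep(codes[1], aa), rep(codes[2], ab),
               rep(codes[1], ba), rep(codes[2], bb)),
    stringsAsFactors = FALSE
  )
}

# study-scale pairs: n cases, n_agree agreements, disagreements labelled
# program/human/definition with the given counts
study_pairs <- function(n = 1020, n_agree = 872,
                        n_program = 3, n_human = 67, n_definition = 78) {
  stopifnot(n_agree + n_program + n_human + n_definition == n)
  lab <- c(rep("", n_agree),
           rep("program_error", n_program),
           rep("human_error", n_human),
           rep("definition_difference", n_definition))
  data.frame(
    case_id = sprintf("case%04d", seq_len(n)),
    code_a = rep("Music", n),
    code_b = c(rep("Music", n_agree), rep("Joke", n - n_agree)),
    discrepancy_label = lab,
    stringsAsFactors = FALSE
  )
}

sorted_episode_key <- function(df) {
  key <- df[, c("participant_id", "category", "week", "n_user_commands",
                "completed")]
  key <- key[order(df$participant_id, df$start_ts), ]
  rownames(key) <- NULL
  key
}
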