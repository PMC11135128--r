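lex <- default_lexicon()

test_that("tokenize lowercases, strips punctuation, drops leading wake word", {
  expect_equal(tokenize("Alexa, play Akinator"), c("play", "akinator"))
  expect_equal(tokenize("I don't know, Akinator"),
               c("i", "don't", "know", "akinator"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("Alexa!"), character(0))
  # typographic apostrophe is normalised, mid-word apostrophe kept
  expect_equal(tokenize("what’s up"), c("what's", "up"))
})

test_that("find_same_words / find_different_words partition the token union", {
  expect_setequal(find_same_words("alexa play music", "play music now"),
                  c("play", "music"))
  expect_setequal(find_same_words("joke", "weather"), character(0))
  d <- find_different_words("play music", "play jazz")
  expect_setequal(d$only_a, "music")
  expect_setequal(d$only_b, "jazz")
  expect_equal(find_different_words("", "hello"),
               list(only_a = character(0), only_b = "hello"))

  # property: same + only_a + only_b partitions union(tokens a, tokens b)
  pool <- c("alexa play some music", "play it again", "yes", "tell me a joke",
            "what's the weather like today", "call my daughter please")
  set.seed(5)
  for (k in 1:25) {
    a <- paste(sample(unlist(strsplit(pool, " ")), sample(0:6, 1),
                      replace = TRUE), collapse = " ")
    b <- paste(sample(unlist(strsplit(pool, " ")), sample(0:6, 1),
                      replace = TRUE), collapse = " ")
    s <- find_same_words(a, b)
    d <- find_different_words(a, b)
    u <- union(unique(tokenize(a)), unique(tokenize(b)))
    expect_setequal(c(s, d$only_a, d$only_b), u)
    expect_length(intersect(s, c(d$only_a, d$only_b)), 0)
    expect_length(intersect(d$only_a, d$only_b), 0)
  }
})

test_that("match_category picks highest-precedence contiguous keyword", {
  expect_equal(match_category(tokenize("alexa tell me a joke"), lex), "Joke")
  expect_true(is.na(match_category(tokenize("how are you today"), lex)))
  expect_equal(match_category(tokenize("alexa open big sky"), lex), "Big Sky")
  # phrase must be contiguous: "big ... sky" apart is no match
  expect_true(is.na(match_category(c("big", "blue", "sky"), lex)))

  # multi-match utterances resolve by precedence; cross-check against an
  # independent enumerate-all-then-rank oracle
  probes <- c("alexa play akinator music", "good morning play some music",
              "alexa open big sky", "call me about the weather",
              "tell me a riddle and a joke", "turn the volume up please",
              "hello there", "play akinator", "alexa weather forecast")
  for (txt in probes) {
    expect_equal(match_category(tokenize(txt), lex), oracle_match(txt, lex),
                 info = txt)
  }
  # keyword list order inside a category must not matter
  lex2 <- lex
  lex2$keywords <- lapply(lex$keywords, rev)
  for (txt in probes) {
    expect_equal(match_category(tokenize(txt), lex2),
                 match_category(tokenize(txt), lex), info = txt)
  }
})

test_that("a continuous game session codes as one episode", {
  eps <- segment_episodes(akinator_log(), lex, gap_seconds = 60)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$category, "Akinator")
  expect_equal(eps$n_user_commands, 5L)
  expect_equal(eps$code, 9L)
  expect_equal(eps$week, 1L)
})

test_that("gap and category-change rules split episodes", {
  # repeated command beyond the gap threshold -> two episodes
  eps <- segment_episodes(
    make_log(c("play akinator", "play akinator"), gaps = c(0, 120)),
    lex, gap_seconds = 60
  )
  expect_equal(eps$n_user_commands, c(1L, 1L))
  expect_equal(eps$category, c("Akinator", "Akinator"))

  # a different-category match always splits, even within the gap
  eps <- segment_episodes(
    make_log(c("play music", "what's the weather"), gaps = c(0, 5)),
    lex, gap_seconds = 60
  )
  expect_equal(eps$category, c("Music", "Weather"))

  # keywordless corrections sharing a token extend; orphans are dropped
  eps <- segment_episodes(
    make_log(c("yes", "alexa play some music", "play it again now",
               "hello there"),
             gaps = c(0, 10, 10, 10)),
    lex, gap_seconds = 60
  )
  expect_equal(nrow(eps), 1)
  expect_equal(eps$n_user_commands, 2L)
})

test_that("segmentation requires sorted, week-assigned input", {
  lg <- make_log(c("a", "b"), gaps = c(0, 10))
  lg$records <- lg$records[2:1, ]
  expect_error(segment_episodes(lg, lex), "sorted")
  lg2 <- make_log("alexa play music")
  lg2$records$week <- NA_integer_
  expect_error(segment_episodes(lg2, lex), "week")
})

test_that("segment_episodes matches the brute-force run enumerator", {
  for (seed in 1:60) {
    lg <- random_small_log(seed)
    got <- segment_episodes(lg, lex, gap_seconds = 60)
    want <- oracle_segment(lg, lex, gap_seconds = 60)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    expect_equal(got$category, want$category, info = paste("seed", seed))
    expect_equal(got$week, want$week, info = paste("seed", seed))
    expect_equal(got$start_ts, want$start_ts, info = paste("seed", seed))
    expect_equal(got$end_ts, want$end_ts, info = paste("seed", seed))
    expect_equal(got$n_user_commands, want$n_user_commands,
                 info = paste("seed", seed))
  }
})

test_that("episode counts are bounded and monotone in the gap threshold", {
  for (seed in 61:80) {
    lg <- random_small_log(seed)
    n_user <- sum(lg$records$role == "user")
    prev <- Inf
    for (gap in c(5, 30, 60, 120, 1000)) {
      eps <- segment_episodes(lg, lex, gap_seconds = gap)
      expect_lte(nrow(eps), n_user)
      expect_lte(sum(eps$n_user_commands), n_user)
      expect_lte(nrow(eps), prev)
      prev <- nrow(eps)
    }
    # determinism: identical call, identical output
    expect_identical(segment_episodes(lg, lex, 60),
                     segment_episodes(lg, lex, 60))
  }
})

test_that("flag_completion needs a response and no error phrase", {
  resp_ok <- data.frame(role = "assistant", text = "Here's a joke ...")
  resp_err <- data.frame(role = "assistant",
                         text = "Sorry, I don't know that one")
  ep <- data.frame(category = "Joke")
  expect_true(flag_completion(ep, resp_ok, lex))
  expect_false(flag_completion(ep, resp_err, lex))
  expect_false(flag_completion(ep, resp_ok[0, ], lex))
  expect_false(flag_completion(ep, rbind(resp_ok, resp_err), lex))
})

test_that("episode tables round-trip through CSV", {
  lg <- akinator_log()
  eps <- segment_episodes(lg, lex, 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_episodes(eps, path)
  back <- read_episodes(path)
  expect_equal(back, eps[, names(back)], ignore_attr = TRUE)
})
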