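#' The twelve routine categories
#'
#' The coding scheme enumerates twelve daily routines and other interactions
#' observed in older adults' smart voice assistant logs. Each category carries
#' a fixed integer code (1--12); the label order is the canonical row order
#' used throughout crosstabs and factor analyses.
#'
#' @return A data.frame with columns `name` (character) and `code` (integer),
#'   one row per category, in code order.
#' @export
#' @examples
#' categories()
categories <- function() {
  data.frame(
    name = c(
      "Good Morning", "Big Sky", "Riddle", "Five Minute Morning Meditation",
      "Music", "Good Afternoon & Evening", "Weather", "Joke", "Akinator",
      "Calls", "Goodnight", "Setting Volume & Speed"
    ),
    code = 1:12,
    stringsAsFactors = FALSE
  )
}

#' @rdname categories
#' @export
category_names <- function() categories()$name

#' Default keyword lexicon
#'
#' Returns the lexicon shipped with the package: a keyword set per category,
#' continuation tokens for multi-turn sessions (such as the yes/no answer
#' sequences of the Akinator guessing game), wake words stripped before
#' matching, a precedence order that resolves multi-category matches, and
#' assistant error phrases used to judge whether a routine completed.
#'
#' The shipped keyword lists are an editorial reconstruction built from the
#' category labels and the routine examples the coding scheme describes; they
#' are not a study codebook and every entry can be replaced via
#' [load_lexicon()]. Precedence places named skills (Big Sky, Akinator,
#' Five Minute Morning Meditation, Riddle) ahead of generic categories
#' (Weather, Music), so a command such as "open big sky" is coded as the
#' Big Sky skill rather than generic weather.
#'
#' @return An object of class `sva_lexicon`: a list with elements `keywords`
#'   (named list, category -> character vector of lowercase phrases),
#'   `continuation_tokens`, `wake_words`, `precedence` (a permutation of the
#'   12 category names) and `error_phrases`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' lex$keywords[["Joke"]]
default_lexicon <- function() {
  keywords <- list(
    "Good Morning" = c("good morning"),
    "Big Sky" = c("big sky"),
    "Riddle" = c("riddle"),
    "Five Minute Morning Meditation" = c(
      "five minute morning", "morning meditation", "meditation"
    ),
    "Music" = c("music", "song", "play some jazz", "country music"),
    "Good Afternoon & Evening" = c("good afternoon", "good evening"),
    "Weather" = c("weather", "forecast", "temperature"),
    "Joke" = c("joke"),
    "Akinator" = c("akinator"),
    "Calls" = c("call", "phone"),
    "Goodnight" = c("goodnight", "good night"),
    "Setting Volume & Speed" = c(
      "volume", "speed", "louder", "quieter", "slower", "faster",
      "speak slower", "speak faster"
    )
  )
  precedence <- c(
    # named skills and specific multi-word routines first
    "Big Sky", "Akinator", "Five Minute Morning Meditation", "Riddle",
    "Good Morning", "Good Afternoon & Evening", "Goodnight",
    "Setting Volume & Speed", "Calls", "Joke",
    # generic catch-all categories last
    "Weather", "Music"
  )
  new_lexicon(
    keywords = keywords,
    continuation_tokens = c(
      "yes", "no", "stop", "i don't know", "i do not know", "repeat"
    ),
    wake_words = "alexa",
    precedence = precedence,
    error_phrases = c(
      "sorry, i don't know that",
      "sorry, i'm not sure",
      "i didn't understand"
    )
  )
}

new_lexicon <- function(keywords, continuation_tokens, wake_words,
                        precedence, error_phrases) {
  lex <- structure(
    list(
      keywords = keywords,
      continuation_tokens = tolower(continuation_tokens),
      wake_words = tolower(wake_words),
      precedence = precedence,
      error_phrases = tolower(error_phrases)
    ),
    class = "sva_lexicon"
  )
  validate_lexicon(lex)
}

#' Validate a lexicon
#'
#' Checks the structural invariants: every one of the 12 categories has a
#' non-empty keyword set, all keywords are lowercase, and the precedence is a
#' permutation of the 12 category names. Validation is idempotent.
#'
#' @param lex an `sva_lexicon`.
#' @return `lex`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_lexicon <- function(lex) {
  stopifnot(inherits(lex, "sva_lexicon"))
  want <- category_names()
  missing <- setdiff(want, names(lex$keywords))
  if (length(missing) > 0) {
    stop("lexicon is missing categories: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(lex$keywords), want)
  if (length(extra) > 0) {
    stop("lexicon has unknown categories: ", paste(extra, collapse = ", "))
  }
  for (cat in want) {
    kw <- lex$keywords[[cat]]
    if (length(kw) == 0 || any(!nzchar(kw))) {
      stop("category '", cat, "' has an empty keyword list")
    }
    if (any(kw != tolower(kw))) {
      stop("category '", cat, "' has non-lowercase keywords")
    }
  }
  if (length(lex$precedence) != length(want) ||
      !setequal(lex$precedence, want) ||
      anyDuplicated(lex$precedence) > 0) {
    stop("precedence must be a permutation of the 12 category names")
  }
  lex
}

#' Load a lexicon from a YAML configuration file
#'
#' User-supplied entries replace the defaults per category; categories absent
#' from the file keep their default keywords. Top-level keys recognised:
#' `keywords` (mapping of category name to keyword list),
#' `continuation_tokens`, `wake_words`, `precedence`, `error_phrases`.
#'
#' @param path path to a YAML file.
#' @return a validated `sva_lexicon`.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon config not found: ", path)
  cfg <- yaml::read_yaml(path)
  lex <- default_lexicon()
  if (!is.null(cfg$keywords)) {
    bad <- setdiff(names(cfg$keywords), category_names())
    if (length(bad) > 0) {
      stop("unknown category in lexicon config: ",
           paste(bad, collapse = ", "))
    }
    for (cat in names(cfg$keywords)) {
      kw <- tolower(as.character(unlist(cfg$keywords[[cat]])))
      if (length(kw) == 0) {
        stop("empty keyword list for category '", cat, "' in config")
      }
      lex$keywords[[cat]] <- kw
    }
  }
  if (!is.null(cfg$continuation_tokens)) {
    lex$continuation_tokens <- tolower(as.character(cfg$continuation_tokens))
  }
  if (!is.null(cfg$wake_words)) {
    lex$wake_words <- tolower(as.character(cfg$wake_words))
  }
  if (!is.null(cfg$precedence)) {
    lex$precedence <- as.character(cfg$precedence)
  }
  if (!is.null(cfg$error_phrases)) {
    lex$error_phrases <- tolower(as.character(cfg$error_phrases))
  }
  validate_lexicon(lex)
}

#' @export
print.sva_lexicon <- function(x, ...) {
  cat("<sva_lexicon>\n")
  nkw <- vapply(x$keywords, length, integer(1))
  cat("  keywords:", sum(nkw), "phrases across", length(nkw), "categories\n")
  cat("  wake words:", paste(x$wake_words, collapse = ", "), "\n")
  cat("  continuation tokens:",
      paste(x$continuation_tokens, collapse = ", "), "\n")
  cat("  precedence:", paste(x$precedence, collapse = " > "), "\n")
  invisible(x)
}
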