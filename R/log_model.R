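#' @title Interaction logs
#' @description
#' An interaction log holds one participant's time-stamped utterances: user
#' commands and assistant responses, one row per utterance. In memory a log is
#' an S3 object of class `participant_log`: a list with
#' `participant_id` (string), `anchor_date` (the `Date` starting week 1) and
#' `records`, a data.frame with columns `timestamp` (POSIXct), `role`
#' (`"user"` or `"assistant"`), `text` (character) and `week` (integer,
#' `NA` until [assign_weeks()] runs). Records are kept sorted by timestamp,
#' ties broken by input order so that command/response pairs sharing a
#' timestamp keep their dialogue order.
#' @name participant_log
NULL

LOG_COLUMNS <- c("participant_id", "timestamp", "role", "text")

new_participant_log <- function(participant_id, records, anchor_date = NULL) {
  ord <- order(records$timestamp)   # stable sort: ties keep input order
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  if (is.null(records$week)) records$week <- NA_integer_
  if (is.null(anchor_date)) {
    anchor_date <- if (nrow(records) > 0) {
      as.Date(records$timestamp[1], tz = "UTC")
    } else {
      as.Date(NA)
    }
  }
  structure(
    list(
      participant_id = participant_id,
      anchor_date = anchor_date,
      records = records
    ),
    class = "participant_log"
  )
}

#' @export
print.participant_log <- function(x, ...) {
  cat("<participant_log> ", x$participant_id, ": ", nrow(x$records),
      " records, anchor ", format(x$anchor_date), "\n", sep = "")
  invisible(x)
}

parse_timestamps <- function(x) {
  # ISO 8601 with either 'T' or space separator; seconds optional.
  # Formats are tried per element so one bad row cannot mask the others.
  x <- trimws(x)
  ts <- rep(as.POSIXct(NA), length(x))
  attr(ts, "tzone") <- "UTC"
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  ts
}

#' Read an interaction log file
#'
#' Reads a CSV (RFC 4180) or XLSX file with required columns
#' `participant_id`, `timestamp` (ISO 8601), `role` (`user`/`assistant`) and
#' `text`, and returns one `participant_log` per distinct participant.
#' Records are sorted chronologically within each log; the total record count
#' equals the number of data rows in the file.
#'
#' @param path path to the file.
#' @param format `"csv"` or `"xlsx"`; defaults to the file extension.
#' @param anchor_date optional `Date` starting week 1 for every participant;
#'   by default each participant is anchored at the date of their first
#'   interaction.
#' @return a named list of `participant_log` objects (names = participant
#'   ids, in order of first appearance).
#' @export
read_log <- function(path, format = c("auto", "csv", "xlsx"),
                     anchor_date = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xlsx", "xls")) "xlsx" else "csv"
  }
  if (!file.exists(path)) stop("log file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx logs requires the 'readxl' package")
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = 1,
                                           col_types = "text"))
  }
  missing <- setdiff(LOG_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("log file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(structure(list(), names = character(0)))

  ts <- parse_timestamps(df$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("unparseable timestamp '", df$timestamp[bad],
         "' in data row ", bad)
  }
  role <- tolower(trimws(df$role))
  if (any(!role %in% c("user", "assistant"))) {
    bad <- which(!role %in% c("user", "assistant"))[1]
    stop("unknown role '", df$role[bad], "' in data row ", bad)
  }
  records <- data.frame(
    timestamp = ts,
    role = role,
    text = as.character(df$text),
    week = if ("week" %in% names(df)) {
      suppressWarnings(as.integer(df$week))
    } else {
      NA_integer_
    },
    stringsAsFactors = FALSE
  )
  ids <- unique(df$participant_id)
  logs <- lapply(ids, function(id) {
    new_participant_log(id, records[df$participant_id == id, , drop = FALSE],
                        anchor_date = anchor_date)
  })
  names(logs) <- ids
  logs
}

#' Write interaction logs to CSV
#'
#' Serializes a collection of `participant_log` objects back to the standard
#' log CSV. `read_log(write_log(x))` reproduces `x` field-for-field.
#'
#' @param logs a list of `participant_log` objects (may be empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_log <- function(logs, path) {
  rows <- lapply(logs, function(log) {
    r <- log$records
    data.frame(
      participant_id = rep(log$participant_id, nrow(r)),
      timestamp = format(r$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      role = r$role,
      text = r$text,
      week = r$week,
      stringsAsFactors = FALSE
    )
  })
  df <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(participant_id = character(0), timestamp = character(0),
               role = character(0), text = character(0),
               week = integer(0))
  }
  if (all(is.na(df$week))) df$week <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Assign week indices to a log
#'
#' Divides a participant's records into consecutive 7-day blocks anchored at
#' midnight of the log's `anchor_date`: a record dated d falls in week
#' `1 + floor((d - anchor_date) / 7)`. The assignment depends only on the
#' calendar date of each record, so it is deterministic and independent of
#' input order.
#'
#' @param log a `participant_log`.
#' @return the log with every record's `week` filled in.
#' @export
#' @examples
#' lg <- synthetic_example_log()
#' assign_weeks(lg)$records$week
assign_weeks <- function(log) {
  stopifnot(inherits(log, "participant_log"))
  if (nrow(log$records) == 0) return(log)
  if (is.na(log$anchor_date)) stop("log has no anchor_date")
  d <- as.Date(log$records$timestamp, tz = "UTC")
  offset <- as.integer(d - log$anchor_date)
  if (any(offset < 0)) {
    bad <- which(offset < 0)[1]
    stop("record ", bad, " (", format(log$records$timestamp[bad]),
         ") predates the anchor date ", format(log$anchor_date))
  }
  log$records$week <- 1L + offset %/% 7L
  log
}

#' A tiny built-in example log
#'
#' Three synthetic utterances for one participant, handy for examples and
#' quick interactive checks.
#'
#' @return a `participant_log`.
#' @export
synthetic_example_log <- function() {
  records <- data.frame(
    timestamp = as.POSIXct(
      c("2023-01-02 08:00:00", "2023-01-02 08:00:05", "2023-01-09 19:30:00"),
      tz = "UTC"
    ),
    role = c("user", "assistant", "user"),
    text = c("alexa, tell me a joke",
             "Here is a joke: why did the chicken cross the road?",
             "alexa, goodnight"),
    week = NA_integer_,
    stringsAsFactors = FALSE
  )
  new_participant_log("P01", records)
}
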