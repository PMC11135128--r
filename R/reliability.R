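# Inter-coder reliability: percent agreement, Cohen's kappa, and triage of
# disagreements into program errors, human errors and coding-definition
# differences. Uncoded cases ("none") are treated as a code level in both
# agreement and kappa marginals, so n is never silently reduced.

#' Round half-up
#'
#' Base R's `round()` rounds half to even; reported percentages here follow
#' the half-up convention (e.g. 0.005 -> 0.01 at 2 digits).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

normalise_codes <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- "<none>"
  x
}

#' Percent agreement between two coders
#'
#' 100 times the number of agreeing cases divided by the number of cases,
#' rounded half-up to two decimals. A case where both coders left the code
#' empty counts as an agreement on "none".
#'
#' @param pairs data.frame with columns `code_a` and `code_b` (character;
#'   `NA` or `""` = uncoded).
#' @return percentage with two decimals.
#' @export
#' @examples
#' pairs <- data.frame(code_a = c("Joke", "Music"), code_b = c("Joke", "Calls"))
#' percent_agreement(pairs)
percent_agreement <- function(pairs) {
  if (nrow(pairs) == 0) stop("percent agreement is undefined for zero cases")
  a <- normalise_codes(pairs$code_a)
  b <- normalise_codes(pairs$code_b)
  round_half_up(100 * sum(a == b) / length(a), 2)
}

#' Cohen's kappa between two coders
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' \eqn{p_e = \sum_k m_a(k) m_b(k)} over the union of observed codes
#' (including "none"). When the expected agreement is 1 (both coders
#' degenerate on one code), kappa is defined as 1.
#'
#' @param pairs data.frame with columns `code_a`, `code_b`.
#' @return kappa in [-1, 1] (unrounded).
#' @export
cohens_kappa <- function(pairs) {
  if (nrow(pairs) == 0) stop("kappa is undefined for zero cases")
  a <- normalise_codes(pairs$code_a)
  b <- normalise_codes(pairs$code_b)
  n <- length(a)
  levels <- union(a, b)
  p_o <- sum(a == b) / n
  m_a <- table(factor(a, levels = levels)) / n
  m_b <- table(factor(b, levels = levels)) / n
  p_e <- sum(as.numeric(m_a) * as.numeric(m_b))
  if (1 - p_e < .Machine$double.eps^0.5) return(1)
  (p_o - p_e) / (1 - p_e)
}

DISCREPANCY_LABELS <- c("program_error", "human_error",
                        "definition_difference")

#' Reliability report with discrepancy triage
#'
#' Tabulates adjudicated disagreement causes. The labels are adjudication
#' input from the human-coder/programmer discussion (program error, human
#' error, or a difference in coding definitions); the report validates them
#' and computes counts and percentages of all cases, alongside percent
#' agreement and Cohen's kappa.
#'
#' @param pairs data.frame with columns `case_id`, `code_a`, `code_b` and
#'   `discrepancy_label` (blank/`NA` for agreeing cases; required on every
#'   disagreeing case).
#' @return an object of class `sva_reliability`: list with `n_cases`,
#'   `n_agree`, `percent_agreement`, `kappa`, and `breakdown` (data.frame of
#'   label, count, percent-of-cases rounded half-up to 2 decimals).
#' @export
triage_report <- function(pairs) {
  if (nrow(pairs) == 0) stop("reliability is undefined for zero cases")
  if (is.null(pairs$case_id)) pairs$case_id <- as.character(seq_len(nrow(pairs)))
  a <- normalise_codes(pairs$code_a)
  b <- normalise_codes(pairs$code_b)
  agree <- a == b
  lab <- as.character(pairs$discrepancy_label)
  lab[is.na(lab)] <- ""
  unlabeled <- !agree & !nzchar(lab)
  if (any(unlabeled)) {
    stop("disagreeing case(s) without a discrepancy label: ",
         paste(pairs$case_id[unlabeled], collapse = ", "))
  }
  bad <- !agree & !lab %in% DISCREPANCY_LABELS
  if (any(bad)) {
    stop("unknown discrepancy label(s): ",
         paste(unique(lab[bad]), collapse = ", "),
         " (expected ", paste(DISCREPANCY_LABELS, collapse = ", "), ")")
  }
  n <- nrow(pairs)
  counts <- vapply(DISCREPANCY_LABELS,
                   function(l) sum(!agree & lab == l), integer(1))
  breakdown <- data.frame(
    label = DISCREPANCY_LABELS,
    count = counts,
    percent = round_half_up(100 * counts / n, 2),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      n_cases = n,
      n_agree = sum(agree),
      percent_agreement = percent_agreement(pairs),
      kappa = cohens_kappa(pairs),
      breakdown = breakdown
    ),
    class = "sva_reliability"
  )
}

#' @export
print.sva_reliability <- function(x, ...) {
  cat("Inter-coder reliability over", x$n_cases, "cases\n")
  cat(sprintf("  agreement: %.2f%% (%d cases)\n",
              x$percent_agreement, x$n_agree))
  cat(sprintf("  Cohen's kappa: %.3f\n", x$kappa))
  n_dis <- x$n_cases - x$n_agree
  cat(sprintf("  discrepancies: %.2f%% (%d cases)\n",
              round_half_up(100 * n_dis / x$n_cases, 2), n_dis))
  for (i in seq_len(nrow(x$breakdown))) {
    cat(sprintf("    %-22s %5d  (%.2f%%)\n", x$breakdown$label[i],
                x$breakdown$count[i], x$breakdown$percent[i]))
  }
  invisible(x)
}

#' Read coded pairs from CSV
#'
#' Expected columns: `case_id`, `code_a`, `code_b`, `discrepancy_label`
#' (blank on agreeing cases).
#'
#' @param path CSV path.
#' @return data.frame of pairs.
#' @export
read_pairs <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(c("case_id", "code_a", "code_b"), names(df))
  if (length(missing) > 0) {
    stop("pairs file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(df$discrepancy_label)) df$discrepancy_label <- ""
  df
}

#' Serialise a reliability report to JSON
#'
#' @param report an `sva_reliability`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
reliability_to_json <- function(report, path = NULL) {
  obj <- list(
    n_cases = report$n_cases,
    n_agree = report$n_agree,
    percent_agreement = report$percent_agreement,
    kappa = report$kappa,
    breakdown = report$breakdown
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
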