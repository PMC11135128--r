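#' Weekly category crosstab
#'
#' Counts coded episodes per week and category. Weeks are rows and the 12
#' categories (in code order) are columns; a totals vector holds per-category
#' sums across all weeks, mirroring the total-frequency row appended to the
#' weekly frequency table.
#'
#' @param episodes an episode data.frame from [segment_episodes()] (or
#'   several participants' episodes bound together).
#' @param scope a participant id, or `"ALL"` (default) for every episode.
#' @param completed_only if `TRUE`, count only completed episodes.
#' @return an object of class `sva_crosstab`: list with `participant_id`,
#'   `weeks` (integer vector, min..max observed week, gaps zero-filled),
#'   `categories` (the 12 names in code order), `counts` (weeks x 12 integer
#'   matrix) and `totals` (named integer vector of column sums).
#' @export
#' @examples
#' eps <- data.frame(participant_id = "P01",
#'                   category = c("Music", "Music", "Joke"),
#'                   week = c(1L, 1L, 2L))
#' build_crosstab(eps)
build_crosstab <- function(episodes, scope = "ALL", completed_only = FALSE) {
  cats <- categories()
  if (!identical(scope, "ALL")) {
    episodes <- episodes[episodes$participant_id == scope, , drop = FALSE]
  }
  if (completed_only && "completed" %in% names(episodes)) {
    episodes <- episodes[episodes$completed, , drop = FALSE]
  }
  bad <- setdiff(unique(episodes$category), cats$name)
  if (length(bad) > 0) {
    stop("unknown categories in episodes: ", paste(bad, collapse = ", "))
  }
  if (nrow(episodes) == 0) {
    weeks <- integer(0)
    counts <- matrix(0L, nrow = 0, ncol = 12,
                     dimnames = list(NULL, cats$name))
  } else {
    weeks <- seq(min(episodes$week), max(episodes$week))
    counts <- matrix(0L, nrow = length(weeks), ncol = 12,
                     dimnames = list(as.character(weeks), cats$name))
    tab <- table(factor(episodes$week, levels = weeks),
                 factor(episodes$category, levels = cats$name))
    counts[] <- as.integer(tab)
  }
  totals <- colSums(counts)
  storage.mode(totals) <- "integer"
  structure(
    list(participant_id = scope, weeks = as.integer(weeks),
         categories = cats$name, counts = counts, totals = totals),
    class = "sva_crosstab"
  )
}

#' @export
print.sva_crosstab <- function(x, ...) {
  cat("<sva_crosstab> participant:", x$participant_id,
      "-", length(x$weeks), "week(s),", sum(x$totals), "episode(s)\n")
  if (length(x$weeks) > 0) print(x$counts)
  cat("totals:\n")
  print(x$totals)
  invisible(x)
}

#' Serialise a crosstab to XML
#'
#' Emits the hierarchical dialect
#' `<svacrosstab participant="..."><category name="Music" code="5">`
#' `<week index="1">2</week>...<total>2</total></category>...</svacrosstab>`:
#' all 12 categories in code order, weeks ascending inside each category, a
#' trailing `<total>` per category. Output is UTF-8 and byte-deterministic
#' for a given crosstab.
#'
#' @param ct an `sva_crosstab`.
#' @return a single string containing the XML document.
#' @export
crosstab_to_xml <- function(ct) {
  stopifnot(inherits(ct, "sva_crosstab"))
  cats <- categories()
  doc <- xml2::xml_new_root("svacrosstab",
                            participant = ct$participant_id)
  for (k in seq_len(12)) {
    node <- xml2::xml_add_child(doc, "category",
                                name = cats$name[k],
                                code = as.character(cats$code[k]))
    for (w in seq_along(ct$weeks)) {
      wk <- xml2::xml_add_child(node, "week",
                                index = as.character(ct$weeks[w]))
      xml2::xml_text(wk) <- as.character(ct$counts[w, k])
    }
    tot <- xml2::xml_add_child(node, "total")
    xml2::xml_text(tot) <- as.character(ct$totals[[k]])
  }
  as.character(doc)
}

#' Parse a crosstab from XML
#'
#' Inverse of [crosstab_to_xml()]: `crosstab_from_xml(crosstab_to_xml(x))`
#' reproduces `x`. The document is validated against the dialect; missing
#' totals, unknown categories or negative counts raise errors naming the
#' offending element.
#'
#' @param doc XML document string (or anything [xml2::read_xml()] accepts).
#' @return an `sva_crosstab`.
#' @export
crosstab_from_xml <- function(doc) {
  x <- xml2::read_xml(doc)
  if (xml2::xml_name(x) != "svacrosstab") {
    stop("schema error: root element must be <svacrosstab>, got <",
         xml2::xml_name(x), ">")
  }
  participant <- xml2::xml_attr(x, "participant")
  cats <- categories()
  cat_nodes <- xml2::xml_find_all(x, "category")
  got <- xml2::xml_attr(cat_nodes, "name")
  if (!identical(got, cats$name)) {
    stop("schema error: expected the 12 <category> elements in code order")
  }
  weeks <- NULL
  cols <- vector("list", 12)
  totals <- integer(12)
  for (k in seq_len(12)) {
    node <- cat_nodes[[k]]
    wk_nodes <- xml2::xml_find_all(node, "week")
    idx <- as.integer(xml2::xml_attr(wk_nodes, "index"))
    vals <- as.integer(xml2::xml_text(wk_nodes))
    if (anyNA(vals) || any(vals < 0)) {
      stop("validation error: negative or non-integer count under <category name=\"",
           cats$name[k], "\">")
    }
    tot_node <- xml2::xml_find_first(node, "total")
    if (is.na(xml2::xml_name(tot_node))) {
      stop("schema error: missing <total> under <category name=\"",
           cats$name[k], "\">")
    }
    tot <- as.integer(xml2::xml_text(tot_node))
    if (is.na(tot) || tot < 0) {
      stop("validation error: invalid <total> under <category name=\"",
           cats$name[k], "\">")
    }
    if (is.null(weeks)) {
      weeks <- idx
    } else if (!identical(weeks, idx)) {
      stop("schema error: week indices differ across categories")
    }
    cols[[k]] <- vals
    totals[k] <- tot
  }
  counts <- matrix(0L, nrow = length(weeks), ncol = 12,
                   dimnames = list(as.character(weeks), cats$name))
  for (k in seq_len(12)) counts[, k] <- cols[[k]]
  if (!identical(unname(colSums(counts)), as.numeric(totals))) {
    stop("validation error: totals do not equal column sums")
  }
  names(totals) <- cats$name
  structure(
    list(participant_id = participant, weeks = as.integer(weeks),
         categories = cats$name, counts = counts, totals = totals),
    class = "sva_crosstab"
  )
}

#' Write a crosstab as CSV
#'
#' Weeks as rows (column `week`), the 12 categories as columns, and a final
#' `TOTAL` row holding per-category sums.
#'
#' @param ct an `sva_crosstab`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crosstab_csv <- function(ct, path) {
  stopifnot(inherits(ct, "sva_crosstab"))
  df <- as.data.frame(ct$counts, check.names = FALSE)
  df <- cbind(week = as.character(ct$weeks), df, stringsAsFactors = FALSE)
  total_row <- c(week = "TOTAL", as.list(ct$totals))
  df <- rbind(df, as.data.frame(total_row, check.names = FALSE,
                                stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
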