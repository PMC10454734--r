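# Literature-screening pipeline: keyword retrieval over a local corpus,
# exact-duplicate removal, treatment-plan filtering, plan-combination
# grouping, and export of the provenance database.

#' Read a literature corpus
#'
#' The corpus is newline-delimited JSON, one record per line with fields
#' `id`, `title`, `abstract`, `year`, `authors` (a local stand-in for a
#' bibliographic-database export). Unreadable lines are skipped with a
#' warning and counted.
#'
#' @param path JSONL file path
#' @return data frame with columns `record_id`, `title`, `abstract`, `year`,
#'   `authors` and attribute `skipped` (number of unreadable lines)
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  skipped <- 0L
  recs <- list()
  for (ln in lines) {
    obj <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    if (is.null(obj) || is.null(obj$id) || is.null(obj$title)) {
      skipped <- skipped + 1L
      next
    }
    recs[[length(recs) + 1L]] <- data.frame(
      record_id = as.character(obj$id),
      title = as.character(obj$title %||% ""),
      abstract = as.character(obj$abstract %||% ""),
      year = as.integer(obj$year %||% NA_integer_),
      authors = as.character(obj$authors %||% ""),
      stringsAsFactors = FALSE
    )
  }
  if (skipped > 0L) {
    warning(skipped, " unreadable corpus line(s) skipped", call. = FALSE)
  }
  df <- if (length(recs)) do.call(rbind, recs) else data.frame(
    record_id = character(0), title = character(0), abstract = character(0),
    year = integer(0), authors = character(0), stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$record_id)) stop("duplicate record ids in corpus", call. = FALSE)
  attr(df, "skipped") <- skipped
  df
}

record_text <- function(records) paste(records$title, records$abstract)

#' Retrieve disease- and value-relevant records
#'
#' Keeps records whose title or abstract mentions the disease and at least
#' one value term; annotates matched value terms in a `matched_values`
#' list-column.
#'
#' @param records corpus data frame from [read_corpus()]
#' @param disease disease keyword
#' @param values character vector of value terms
#' @return filtered records with a `matched_values` list-column
#' @export
retrieve <- function(records, disease, values) {
  if (nrow(records) == 0L) {
    records$matched_values <- list()
    return(records)
  }
  txt <- record_text(records)
  hits <- lapply(txt, function(x) {
    if (length(find_mentions(x, disease)) == 0L) return(NULL)
    mv <- find_mentions(x, values)
    if (length(mv) == 0L) NULL else mv
  })
  keep <- !vapply(hits, is.null, logical(1))
  out <- records[keep, , drop = FALSE]
  out$matched_values <- hits[keep]
  rownames(out) <- NULL
  out
}

#' Remove exactly duplicated records
#'
#' Two records are duplicates when both title and abstract are identical
#' after case-folding and whitespace collapsing; the first occurrence (in
#' input order) is kept. No fuzzy matching is applied.
#'
#' @param records corpus data frame
#' @return records with duplicates removed
#' @export
dedupe <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(tolower(squish(records$title)), "\r",
               tolower(squish(records$abstract)))
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep records mentioning a treatment-plan keyword
#'
#' Scans title and abstract for the plan vocabulary (sub-keywords and
#' category names both count) and keeps records with at least one mention,
#' annotating the canonical matched plans in a `matched_plans` list-column.
#'
#' @param records corpus data frame
#' @param plans a `vbtr_plan_table`
#' @return filtered records with a `matched_plans` list-column
#' @export
filter_plans <- function(records, plans) {
  vocab <- plan_vocabulary(plans)
  if (nrow(records) == 0L) {
    records$matched_plans <- list()
    return(records)
  }
  txt <- record_text(records)
  hits <- lapply(txt, function(x) {
    mp <- find_mentions(x, vocab)
    if (length(mp) == 0L) NULL else sort(canonical_plan(mp))
  })
  keep <- !vapply(hits, is.null, logical(1))
  out <- records[keep, , drop = FALSE]
  out$matched_plans <- hits[keep]
  rownames(out) <- NULL
  out
}

#' Group records by their treatment-plan combination
#'
#' Partitions records by the sorted set of matched plans. Requires
#' [filter_plans()] to have run first; a record without matched plans is a
#' pipeline-order error.
#'
#' @param records records carrying a `matched_plans` list-column
#' @return named list: sorted plan combination (joined with `" + "`) ->
#'   record data frame
#' @export
group_by_combination <- function(records) {
  if (nrow(records) == 0L) return(stats::setNames(list(), character(0)))
  if (is.null(records$matched_plans) ||
      any(vapply(records$matched_plans, length, integer(1)) == 0L)) {
    stop("records without matched plans: run filter_plans() before grouping",
         call. = FALSE)
  }
  keys <- vapply(records$matched_plans,
                 function(p) paste(sort(p), collapse = " + "), character(1))
  idx <- split(seq_len(nrow(records)), keys)
  lapply(idx, function(i) {
    out <- records[i, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Run the full screening pipeline
#'
#' retrieve -> dedupe -> filter_plans -> group_by_combination, with stage
#' counts collected into a screening report.
#'
#' @param corpus corpus data frame or JSONL path
#' @param disease disease keyword
#' @param values character vector of value terms (e.g. [value_terms()] of a
#'   loaded taxonomy)
#' @param plans a `vbtr_plan_table`
#' @return object of class `vbtr_screening_report` with fields
#'   `retrieved_count`, `deduplicated_count`, `plan_filtered_count`,
#'   `group_count`, `groups`, `records`, `skipped`
#' @export
screen_corpus <- function(corpus, disease, values, plans) {
  records <- if (is.character(corpus)) read_corpus(corpus) else corpus
  skipped <- attr(records, "skipped") %||% 0L
  r <- retrieve(records, disease, values)
  d <- dedupe(r)
  f <- filter_plans(d, plans)
  g <- group_by_combination(f)
  structure(
    list(
      retrieved_count = nrow(r),
      deduplicated_count = nrow(d),
      plan_filtered_count = nrow(f),
      group_count = length(g),
      groups = g,
      records = f,
      skipped = skipped
    ),
    class = "vbtr_screening_report"
  )
}

#' @export
print.vbtr_screening_report <- function(x, ...) {
  cat("<screening report>\n")
  cat("  retrieved:     ", x$retrieved_count, "\n")
  cat("  after dedupe:  ", x$deduplicated_count, "\n")
  cat("  plan-filtered: ", x$plan_filtered_count, "\n")
  cat("  groups:        ", x$group_count, "\n")
  if (x$skipped > 0L) cat("  skipped lines: ", x$skipped, "\n")
  invisible(x)
}

#' Serialize a screening report to JSON
#'
#' @param report a `vbtr_screening_report`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_screening_report <- function(report, path) {
  stopifnot(inherits(report, "vbtr_screening_report"))
  obj <- list(
    retrieved_count = report$retrieved_count,
    deduplicated_count = report$deduplicated_count,
    plan_filtered_count = report$plan_filtered_count,
    group_count = report$group_count,
    skipped = report$skipped,
    groups = lapply(report$groups, function(g) g$record_id)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export / import the findings database
#'
#' The findings database joins screened records with manually extracted
#' findings (the manual-reading step is modelled as external input, not
#' automated). On disk it is a CSV with columns
#' `Index,AuthorYear,Title,Finding,Link`.
#'
#' @param records screened records (with `record_id`, `title`)
#' @param findings data frame with columns `record_id`, `author_year`,
#'   `finding`, `link`
#' @param path output CSV path
#' @return `export_database()` returns the written data frame invisibly;
#'   `import_findings()` returns the findings table
#' @export
export_database <- function(records, findings, path) {
  needed <- c("record_id", "author_year", "finding", "link")
  if (!all(needed %in% names(findings))) {
    stop("findings must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(findings$record_id, records$record_id)
  if (length(unknown)) {
    stop("findings reference unknown record id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  title <- records$title[match(findings$record_id, records$record_id)]
  out <- data.frame(
    Index = seq_len(nrow(findings)),
    AuthorYear = findings$author_year,
    Title = title,
    Finding = findings$finding,
    Link = findings$link,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out)
}

#' @rdname export_database
#' @export
import_findings <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  needed <- c("Index", "AuthorYear", "Title", "Finding", "Link")
  if (!all(needed %in% names(df))) {
    stop("findings database must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  df$Index <- as.integer(df$Index)
  if (anyDuplicated(df$Index)) stop("duplicate Index in findings database", call. = FALSE)
  df
}
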