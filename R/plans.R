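# Treatment-plan keyword table: plan categories with optional sub-keywords,
# flattened into the canonical plan list used for screening and scoring.

#' Load the treatment-plan keyword table
#'
#' Reads a CSV with columns `Category,Keyword`; a `"-"` keyword cell means
#' the category has no sub-keywords and is itself an operable plan.
#'
#' @param path CSV file path
#' @return an object of class `vbtr_plan_table`
#' @export
load_plan_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  if (!identical(sort(names(df)), sort(c("Category", "Keyword")))) {
    stop("plan table must have columns Category,Keyword", call. = FALSE)
  }
  df$Category <- squish(df$Category)
  df$Keyword <- squish(df$Keyword)
  if (any(!nzchar(df$Category))) stop("empty plan category", call. = FALSE)
  if (any(!nzchar(df$Keyword))) stop("empty plan keyword cell (use '-')", call. = FALSE)
  structure(list(entries = df), class = "vbtr_plan_table")
}

#' @export
print.vbtr_plan_table <- function(x, ...) {
  cat("<plan keyword table>", length(unique(x$entries$Category)), "categories,",
      length(canonical_plans(x)), "canonical plans\n")
  invisible(x)
}

#' Flatten the plan table into canonical plan names
#'
#' Emits every sub-keyword as a plan; emits each category whose keyword cell
#' is `"-"`; additionally emits categories named in `generic_categories`
#' (plans also offered generically, by default "Endocrine therapy"). Pure
#' umbrella categories with sub-keywords (e.g. "Surgery") are not emitted —
#' their sub-keywords are the operable plans. The result is deduplicated
#' under [plan_key()] and deterministic in table order.
#'
#' @param table a `vbtr_plan_table`
#' @param generic_categories categories that are plans in their own right in
#'   addition to their sub-keywords
#' @return character vector of canonical plan names
#' @export
canonical_plans <- function(table, generic_categories = "Endocrine therapy") {
  stopifnot(inherits(table, "vbtr_plan_table"))
  df <- table$entries
  out <- character(0)
  for (i in seq_len(nrow(df))) {
    out <- c(out, if (df$Keyword[i] == "-") df$Category[i] else df$Keyword[i])
  }
  gen <- df$Category[plan_key(df$Category) %in% plan_key(generic_categories) &
                     df$Keyword != "-"]
  out <- canonical_plan(c(out, unique(gen)))
  out[!duplicated(plan_key(out))]
}

#' Look up the category of a plan keyword
#'
#' @param table a `vbtr_plan_table`
#' @param keyword a keyword or category name (case-insensitive)
#' @return the category name, or `NA_character_` if unknown
#' @export
plan_category <- function(table, keyword) {
  stopifnot(inherits(table, "vbtr_plan_table"))
  df <- table$entries
  key <- plan_key(keyword)
  hit <- df$Category[plan_key(df$Keyword) == key]
  if (length(hit)) return(hit[1])
  hit <- df$Category[plan_key(df$Category) == key]
  if (length(hit)) return(hit[1])
  NA_character_
}

# Full keyword -> canonical-plan vocabulary used by the screening filter:
# every sub-keyword maps to itself, every category name to itself (umbrella
# names count as keywords when scanning text).
plan_vocabulary <- function(table) {
  stopifnot(inherits(table, "vbtr_plan_table"))
  df <- table$entries
  terms <- c(df$Keyword[df$Keyword != "-"], unique(df$Category))
  terms <- canonical_plan(terms)
  terms[!duplicated(plan_key(terms))]
}
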