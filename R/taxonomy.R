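# The six-category value taxonomy and the alias/extension vocabulary that
# connects evidence-table surface forms to taxonomy terms.

VALUE_CATEGORIES <- c("Activities", "Abilities", "Possessions", "Principles",
                      "Emotions", "Relationships")

#' Load the value taxonomy
#'
#' Reads a CSV with columns `Category,Term`. Exactly six categories are
#' recognized (Activities, Abilities, Possessions, Principles, Emotions,
#' Relationships); any other category label is a validation error. A term
#' listed under several categories is merged into a single term carrying the
#' union of its categories.
#'
#' @param path CSV file path
#' @return an object of class `vbtr_taxonomy`: a named list mapping each
#'   lower-cased term to its character vector of categories
#' @export
load_taxonomy <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  if (!identical(sort(names(df)), sort(c("Category", "Term")))) {
    stop("taxonomy table must have columns Category,Term", call. = FALSE)
  }
  df$Category <- trimws(df$Category)
  df$Term <- tolower(trimws(df$Term))
  bad <- setdiff(unique(df$Category), VALUE_CATEGORIES)
  if (length(bad)) {
    stop("unknown value category: ", paste(bad, collapse = ", "),
         " (recognized: ", paste(VALUE_CATEGORIES, collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(!nzchar(df$Term))) stop("empty value term in taxonomy", call. = FALSE)
  terms <- lapply(split(df$Category, df$Term), function(x) {
    VALUE_CATEGORIES[VALUE_CATEGORIES %in% x]
  })
  terms <- terms[unique(df$Term)]  # keep first-appearance order
  structure(list(terms = terms), class = "vbtr_taxonomy")
}

#' @export
print.vbtr_taxonomy <- function(x, ...) {
  cat("<value taxonomy>", length(x$terms), "terms across",
      length(taxonomy_categories(x)), "categories\n")
  invisible(x)
}

#' Query a taxonomy
#'
#' `value_terms()` lists the distinct terms; `taxonomy_categories()` the
#' categories in use; `term_categories()` the categories of one term.
#'
#' @param taxonomy a `vbtr_taxonomy`
#' @return character vectors
#' @export
value_terms <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "vbtr_taxonomy"))
  names(taxonomy$terms)
}

#' @rdname value_terms
#' @export
taxonomy_categories <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "vbtr_taxonomy"))
  VALUE_CATEGORIES[VALUE_CATEGORIES %in% unique(unlist(taxonomy$terms))]
}

#' @param term a term name
#' @rdname value_terms
#' @export
term_categories <- function(taxonomy, term) {
  stopifnot(inherits(taxonomy, "vbtr_taxonomy"))
  taxonomy$terms[[tolower(trimws(term))]] %||% character(0)
}

#' Load the value alias and extension vocabulary
#'
#' The evidence table and the taxonomy use slightly different surface forms
#' ("pregnancy later" vs "pregnancy", "cost" vs "expensive"). The alias file
#' (CSV columns `Alias,Target,Kind`) declares the mapping: rows with
#' `Kind=alias` map an alias onto a taxonomy term; rows with `Kind=extension`
#' declare terms admitted in the evidence base even though the taxonomy does
#' not list them.
#'
#' @param path CSV path; defaults to the packaged vocabulary
#' @return list with `map` (named character: alias -> taxonomy term) and
#'   `extensions` (character vector)
#' @export
load_value_aliases <- function(path = vbtr_extdata("value_aliases.csv")) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  stopifnot(all(c("Alias", "Target", "Kind") %in% names(df)))
  df$Alias <- tolower(trimws(df$Alias))
  df$Target <- tolower(trimws(df$Target))
  al <- df[df$Kind == "alias", , drop = FALSE]
  list(
    map = stats::setNames(al$Target, al$Alias),
    extensions = df$Alias[df$Kind == "extension"]
  )
}

#' Resolve value terms against taxonomy, aliases and extensions
#'
#' @param terms character vector of surface terms (case-insensitive)
#' @param taxonomy a `vbtr_taxonomy`
#' @param aliases result of [load_value_aliases()], or `NULL`
#' @param warn warn about unresolvable terms
#' @return character vector of resolved terms; `NA` where unresolvable
#' @export
resolve_value_terms <- function(terms, taxonomy, aliases = NULL, warn = TRUE) {
  terms <- tolower(trimws(terms))
  known <- value_terms(taxonomy)
  out <- vapply(terms, function(t) {
    if (t %in% known) return(t)
    if (!is.null(aliases)) {
      if (t %in% names(aliases$map)) return(unname(aliases$map[t]))
      if (t %in% aliases$extensions) return(t)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
  if (warn && anyNA(out)) {
    warning("unresolved value terms: ",
            paste(unique(terms[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}
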