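# Arguments: one unit of evidence linking a disease, an eligibility
# condition, optional required values, and a target plan with a signed
# weight. Clinical arguments come from guideline content; value arguments
# from the literature-derived value-evidence table.

#' Canonicalize a treatment-plan name
#'
#' Trims, collapses internal whitespace and removes spaces around `+`
#' ("Chemotherapy+ GnRHa" becomes "Chemotherapy+GnRHa"). Comparison between
#' plans is case-insensitive via [plan_key()].
#'
#' @param x character vector of plan names
#' @return canonicalized names
#' @export
canonical_plan <- function(x) {
  x <- squish(x)
  gsub("[[:space:]]*\\+[[:space:]]*", "+", x)
}

#' @rdname canonical_plan
#' @export
plan_key <- function(x) tolower(canonical_plan(x))

#' Construct an evidence argument
#'
#' @param id argument identifier
#' @param disease disease the argument applies to
#' @param condition a `vbtr_condition` (or a condition string, parsed)
#' @param plan target treatment plan; stored canonicalized
#' @param support_type `"positive"` (for) or `"negative"` (against); no other
#'   polarity is admitted
#' @param weight evidence weight, strictly positive
#' @param evidence_kind `"clinical"` or `"value"`; clinical arguments carry no
#'   required values, value arguments require at least one
#' @param required_values character vector of value-term names the patient
#'   must hold for the argument to activate (value arguments only)
#' @param provenance list with optional `source_index`, `author_year`, `link`
#' @return an object of class `vbtr_argument`
#' @export
argument <- function(id, disease, condition, plan, support_type, weight,
                     evidence_kind, required_values = character(0),
                     provenance = list()) {
  if (is.character(condition)) condition <- parse_condition(condition)
  stopifnot(inherits(condition, "vbtr_condition"))
  support_type <- as.character(support_type)
  if (!support_type %in% c("positive", "negative")) {
    stop("support_type must be 'positive' or 'negative', got '",
         support_type, "'", call. = FALSE)
  }
  evidence_kind <- match.arg(evidence_kind, c("clinical", "value"))
  if (!is_scalar_number(weight) || weight <= 0) {
    stop("argument weight must be a positive number", call. = FALSE)
  }
  required_values <- tolower(trimws(as.character(required_values)))
  if (evidence_kind == "clinical" && length(required_values) > 0L) {
    stop("clinical arguments must not carry required values", call. = FALSE)
  }
  if (evidence_kind == "value" && length(required_values) == 0L) {
    stop("value arguments must require at least one value term", call. = FALSE)
  }
  structure(
    list(
      id = as.character(id),
      disease = as.character(disease),
      condition = condition,
      required_values = required_values,
      plan = canonical_plan(plan),
      support_type = support_type,
      weight = as.numeric(weight),
      evidence_kind = evidence_kind,
      provenance = list(
        source_index = as.integer(provenance$source_index %||% NA_integer_),
        author_year = as.character(provenance$author_year %||% ""),
        link = as.character(provenance$link %||% "")
      )
    ),
    class = "vbtr_argument"
  )
}

#' @export
print.vbtr_argument <- function(x, ...) {
  sign <- if (x$support_type == "positive") "for" else "against"
  cat(sprintf("<argument %s> [%s] %s %s (w=%g) when %s", x$id, x$evidence_kind,
              sign, x$plan, x$weight, deparse_condition(x$condition)))
  if (length(x$required_values)) {
    cat(" & values {", paste(x$required_values, collapse = ", "), "}", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Load the value-evidence table
#'
#' Reads a CSV value-evidence table with columns
#' `Index,Condition,Value,Support,Oppose,Weight,SourceIndex` ("-" denotes an
#' empty cell). Each row yields one positive argument per non-"-" Support
#' cell and one negative argument per non-"-" Oppose cell; the two share the
#' row's condition, required values, weight and provenance, so a single piece
#' of value evidence can simultaneously support one plan and oppose another.
#' Multi-value cells split on commas and require all listed values.
#'
#' @param path CSV file path
#' @param disease disease name attached to every argument
#' @param findings optional provenance table from [import_findings()]; when
#'   given, `author_year` and `link` are joined on `SourceIndex`
#' @return list of `vbtr_argument` (all with `evidence_kind = "value"`);
#'   argument ids are `v<index>s` / `v<index>o` for the support / oppose
#'   directions of row `<index>`
#' @export
load_value_evidence <- function(path, disease = "breast cancer", findings = NULL) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  expected <- c("Index", "Condition", "Value", "Support", "Oppose", "Weight",
                "SourceIndex")
  extra <- setdiff(names(df), expected)
  missing <- setdiff(expected, names(df))
  if (length(extra) || length(missing)) {
    stop("value-evidence table schema mismatch; unknown columns: [",
         paste(extra, collapse = ", "), "], missing columns: [",
         paste(missing, collapse = ", "), "]", call. = FALSE)
  }
  args <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    weight <- suppressWarnings(as.numeric(row$Weight))
    if (is.na(weight) || weight <= 0) {
      stop("row ", row$Index, ": weight must be a positive number", call. = FALSE)
    }
    cond <- parse_condition(row$Condition)
    vals <- tolower(trimws(strsplit(row$Value, ",", fixed = TRUE)[[1]]))
    vals <- vals[nzchar(vals) & vals != "-"]
    if (length(vals) == 0L) {
      stop("row ", row$Index, ": value cell must name at least one value", call. = FALSE)
    }
    src_idx <- suppressWarnings(as.integer(row$SourceIndex))
    prov <- list(source_index = src_idx)
    if (!is.null(findings) && !is.na(src_idx)) {
      hit <- findings[findings$Index == src_idx, , drop = FALSE]
      if (nrow(hit) == 1L) {
        prov$author_year <- hit$AuthorYear
        prov$link <- hit$Link
      }
    }
    idx <- as.integer(row$Index)
    for (dir in c("Support", "Oppose")) {
      cell <- trimws(row[[dir]])
      if (cell == "-" || cell == "") next
      args[[length(args) + 1L]] <- argument(
        id = sprintf("v%d%s", idx, if (dir == "Support") "s" else "o"),
        disease = disease,
        condition = cond,
        plan = cell,
        support_type = if (dir == "Support") "positive" else "negative",
        weight = weight,
        evidence_kind = "value",
        required_values = vals,
        provenance = prov
      )
    }
  }
  args
}

#' Packaged value-evidence base
#'
#' Convenience loader for the value-evidence table, provenance findings and
#' disease shipped with the package.
#'
#' @return list of value arguments with provenance attached
#' @export
packaged_value_evidence <- function() {
  load_value_evidence(
    vbtr_extdata("value_evidence.csv"),
    disease = "breast cancer",
    findings = import_findings(vbtr_extdata("literature_findings.csv"))
  )
}
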