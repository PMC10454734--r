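# Eligibility-condition language: comma-separated conjunctions of atoms
# over a closed patient-fact schema ("premenopausal", "ER+", "age > 65",
# "age 18-49", ...).

# Canonical patient-fact schema. Categorical facts have closed domains;
# numeric facts take non-negative integers.
FACT_DOMAINS <- list(
  menopausal_status = c("pre", "post"),
  er                = c("positive", "negative"),
  her2              = c("positive", "negative"),
  node_status       = c("positive", "negative"),
  surgery_phase     = c("pre", "post", "none"),
  bmi_class         = c("normal", "overweight")
)
NUMERIC_FACTS <- c("age", "grade")

# Surface tokens with a fixed clinical meaning, mapped onto schema atoms.
FLAG_SYNONYMS <- list(
  "premenopausal"  = list(field = "menopausal_status", operand = "pre"),
  "postmenopausal" = list(field = "menopausal_status", operand = "post"),
  "node-positive"  = list(field = "node_status", operand = "positive"),
  "node positive"  = list(field = "node_status", operand = "positive"),
  "node-negative"  = list(field = "node_status", operand = "negative"),
  "node negative"  = list(field = "node_status", operand = "negative"),
  "pre-surgery"    = list(field = "surgery_phase", operand = "pre"),
  "pre surgery"    = list(field = "surgery_phase", operand = "pre"),
  "after surgery"  = list(field = "surgery_phase", operand = "post"),
  "post-surgery"   = list(field = "surgery_phase", operand = "post"),
  "overweight"     = list(field = "bmi_class", operand = "overweight"),
  "normal weight"  = list(field = "bmi_class", operand = "normal")
)

# Marker-style tokens ("ER+", "HER2-") map the marker name to a schema field.
MARKER_FIELDS <- c(er = "er", her2 = "her2")

# Preferred surface form when turning schema atoms back into text.
FLAG_SURFACE <- list(
  menopausal_status = c(pre = "premenopausal", post = "postmenopausal"),
  er                = c(positive = "ER+", negative = "ER-"),
  her2              = c(positive = "HER2+", negative = "HER2-"),
  node_status       = c(positive = "node-positive", negative = "node-negative"),
  surgery_phase     = c(pre = "pre-surgery", post = "after surgery"),
  bmi_class         = c(overweight = "overweight", normal = "normal weight")
)

new_condition_atom <- function(kind, field, operator, operand) {
  kind <- match.arg(kind, c("flag", "comparison", "range"))
  operator <- match.arg(operator, c("=", ">", "<", "within"))
  if (kind %in% c("comparison", "range") && !field %in% NUMERIC_FACTS) {
    stop("numeric atoms are only defined over numeric facts, not '", field, "'",
         call. = FALSE)
  }
  if (kind == "range") {
    if (length(operand) != 2L || any(is.na(operand)) || operand[1] > operand[2]) {
      stop("range atom needs an integer pair low <= high", call. = FALSE)
    }
    operand <- as.numeric(operand)
  }
  structure(
    list(kind = kind, field = field, operator = operator, operand = operand),
    class = "vbtr_atom"
  )
}

#' Construct a condition rule
#'
#' A condition rule is an ordered conjunction of eligibility atoms. The empty
#' rule matches every patient.
#'
#' @param atoms list of atoms, usually produced by [parse_condition()]
#' @return an object of class `vbtr_condition`
#' @export
condition_rule <- function(atoms = list()) {
  stopifnot(all(vapply(atoms, inherits, logical(1), "vbtr_atom")))
  structure(list(atoms = atoms), class = "vbtr_condition")
}

#' @export
print.vbtr_condition <- function(x, ...) {
  cat("<condition> ", deparse_condition(x), "\n", sep = "")
  invisible(x)
}

parse_atom <- function(token) {
  tok <- tolower(squish(token))
  if (!nzchar(tok)) stop("empty condition atom", call. = FALSE)

  syn <- FLAG_SYNONYMS[[tok]]
  if (!is.null(syn)) {
    return(new_condition_atom("flag", syn$field, "=", syn$operand))
  }

  m <- regmatches(tok, regexec("^([a-z][a-z0-9]*)([+-])$", tok))[[1]]
  if (length(m) == 3L) {
    field <- MARKER_FIELDS[m[2]]
    field <- if (is.na(field)) m[2] else unname(field)
    operand <- if (m[3] == "+") "positive" else "negative"
    return(new_condition_atom("flag", field, "=", operand))
  }

  m <- regmatches(tok, regexec("^([a-z][a-z_]*) *([<>]) *([0-9]+)$", tok))[[1]]
  if (length(m) == 4L) {
    return(new_condition_atom("comparison", m[2], m[3], as.numeric(m[4])))
  }

  m <- regmatches(tok, regexec("^([a-z][a-z_]*) +([0-9]+) *- *([0-9]+)$", tok))[[1]]
  if (length(m) == 4L) {
    lo <- as.numeric(m[3]); hi <- as.numeric(m[4])
    if (lo > hi) stop("malformed range atom '", token, "': low > high", call. = FALSE)
    return(new_condition_atom("range", m[2], "within", c(lo, hi)))
  }

  m <- regmatches(tok, regexec("^([a-z][a-z_]*) +([0-9]+)$", tok))[[1]]
  if (length(m) == 3L && m[2] %in% NUMERIC_FACTS) {
    return(new_condition_atom("comparison", m[2], "=", as.numeric(m[3])))
  }

  if (grepl("[<>0-9]", tok)) {
    stop("malformed numeric condition atom: '", trimws(token), "'", call. = FALSE)
  }

  # any other token is a generic presence flag
  new_condition_atom("flag", gsub(" ", "_", tok), "=", "true")
}

#' Parse a clinical condition expression
#'
#' Parses the comma-separated condition strings used in the value-evidence
#' table (e.g. `"ER+, pre-surgery"`, `"age 18-49, premenopausal"`) into a
#' [condition_rule()]. A `"-"` or empty string denotes the wildcard rule that
#' matches every patient. Both hyphen and en-dash are accepted in age ranges;
#' ranges are inclusive at both ends. Tokens with no recognised structure
#' become generic presence flags after case-folding.
#'
#' @param text a condition expression, or `"-"`
#' @return a `vbtr_condition`
#' @examples
#' parse_condition("age 18-49, premenopausal")
#' parse_condition("-")
#' @export
parse_condition <- function(text) {
  if (length(text) != 1L || is.na(text)) stop("condition must be a single string", call. = FALSE)
  text <- gsub("–|—", "-", text)
  text <- trimws(text)
  if (text == "" || text == "-") return(condition_rule())
  tokens <- strsplit(text, ",", fixed = TRUE)[[1]]
  condition_rule(lapply(tokens, parse_atom))
}

#' Render a condition rule back to text
#'
#' Inverse of [parse_condition()] over the canonical schema: the result
#' re-parses to an identical rule. The empty rule renders as `"-"`.
#'
#' @param rule a `vbtr_condition`
#' @return a single string
#' @export
deparse_condition <- function(rule) {
  stopifnot(inherits(rule, "vbtr_condition"))
  if (length(rule$atoms) == 0L) return("-")
  parts <- vapply(rule$atoms, function(a) {
    if (a$kind == "range") {
      return(sprintf("%s %d-%d", a$field, as.integer(a$operand[1]), as.integer(a$operand[2])))
    }
    if (a$kind == "comparison") {
      if (a$operator == "=") return(sprintf("%s %d", a$field, as.integer(a$operand)))
      return(sprintf("%s %s %d", a$field, a$operator, as.integer(a$operand)))
    }
    surf <- FLAG_SURFACE[[a$field]]
    if (!is.null(surf) && !is.na(surf[a$operand])) return(unname(surf[a$operand]))
    if (identical(a$operand, "true")) return(gsub("_", " ", a$field))
    stop("flag atom on '", a$field, "' = '", a$operand,
         "' has no textual surface form", call. = FALSE)
  }, character(1))
  paste(parts, collapse = ", ")
}

match_atom <- function(atom, facts) {
  val <- facts[[atom$field]]
  if (is.null(val) || (length(val) == 1L && is.na(val))) return(FALSE)
  if (atom$kind %in% c("comparison", "range")) {
    v <- suppressWarnings(as.numeric(val))
    if (is.na(v)) return(FALSE)
    return(switch(atom$operator,
      ">"      = v > atom$operand,
      "<"      = v < atom$operand,
      "="      = v == atom$operand,
      "within" = v >= atom$operand[1] && v <= atom$operand[2]
    ))
  }
  norm <- tolower(as.character(val))
  if (identical(atom$operand, "true")) {
    return(norm %in% c("true", "yes", "1"))
  }
  norm == atom$operand
}

#' Match a condition rule against a patient record
#'
#' Every atom of the rule must be satisfied by a fact present in the patient
#' record; a missing fact falsifies its atom (conservative non-activation).
#' The empty rule matches every patient. Total: never errors on patient
#' content.
#'
#' @param rule a `vbtr_condition`
#' @param patient a [patient_record()]
#' @return `TRUE` or `FALSE`
#' @export
match_condition <- function(rule, patient) {
  stopifnot(inherits(rule, "vbtr_condition"))
  facts <- if (inherits(patient, "vbtr_patient")) patient$facts else patient
  for (atom in rule$atoms) {
    if (!match_atom(atom, facts)) return(FALSE)
  }
  TRUE
}
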