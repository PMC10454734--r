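# Structured patient records: clinical facts over the canonical schema,
# occupation, and a value profile (value term -> importance weight in [0,1]).

#' Construct a patient record
#'
#' @param disease disease name (matched case-insensitively against evidence)
#' @param facts named list of clinical facts over the canonical schema
#'   (`menopausal_status`, `er`, `her2`, `node_status`, `grade`, `age`,
#'   `surgery_phase`, `bmi_class`); additional facts are allowed and matched
#'   as generic presence flags. Facts may be partially populated; atoms over
#'   a missing fact simply do not match.
#' @param occupation occupation label used for value pre-configuration, or ""
#' @param values named numeric vector: value term -> importance weight in
#'   \[0, 1\]
#' @return an object of class `vbtr_patient`
#' @examples
#' patient_record("breast cancer",
#'   facts = list(menopausal_status = "pre", age = 32),
#'   values = c("pregnancy later" = 1)
#' )
#' @export
patient_record <- function(disease, facts = list(), occupation = "",
                           values = numeric(0)) {
  p <- structure(
    list(
      disease = as.character(disease),
      facts = as.list(facts),
      occupation = as.character(occupation),
      values = values
    ),
    class = "vbtr_patient"
  )
  validate_patient(p)
  p
}

#' Validate a patient record
#'
#' Checks the canonical fact domains, `age >= 0`, and that all value-profile
#' weights lie in \[0, 1\]. Unknown facts are permitted (they participate
#' only in generic flag atoms).
#'
#' @param patient a `vbtr_patient`
#' @return the patient, invisibly; errors on violation
#' @export
validate_patient <- function(patient) {
  stopifnot(inherits(patient, "vbtr_patient"))
  if (!nzchar(patient$disease)) stop("patient disease must be non-empty", call. = FALSE)
  facts <- patient$facts
  if (length(facts) && is.null(names(facts))) {
    stop("patient facts must be named", call. = FALSE)
  }
  for (nm in names(facts)) {
    val <- facts[[nm]]
    if (nm %in% names(FACT_DOMAINS)) {
      if (!as.character(val) %in% FACT_DOMAINS[[nm]]) {
        stop("fact '", nm, "' must be one of: ",
             paste(FACT_DOMAINS[[nm]], collapse = ", "), call. = FALSE)
      }
    } else if (nm %in% NUMERIC_FACTS) {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v) || v < 0) stop("fact '", nm, "' must be a non-negative number", call. = FALSE)
    }
  }
  vals <- patient$values
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
      stop("value profile must be a named numeric vector", call. = FALSE)
    }
    if (!is.numeric(vals) || any(is.na(vals)) || any(vals < 0 | vals > 1)) {
      stop("value-profile weights must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(patient)
}

#' @export
print.vbtr_patient <- function(x, ...) {
  cat("<patient> disease:", x$disease, "\n")
  if (nzchar(x$occupation)) cat("  occupation:", x$occupation, "\n")
  if (length(x$facts)) {
    cat("  facts:", paste(names(x$facts), unlist(lapply(x$facts, as.character)),
                          sep = "=", collapse = ", "), "\n")
  }
  if (length(x$values)) {
    cat("  values:", paste0(names(x$values), " (", format(x$values), ")",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write patient records as JSON
#'
#' The on-disk form is a JSON object with keys `disease`, `facts`,
#' `occupation` and `values`.
#'
#' @param path file path
#' @return `read_patient()` returns a validated `vbtr_patient`
#' @export
read_patient <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  vals <- unlist(obj$values %||% list())
  if (is.null(vals)) vals <- numeric(0)
  patient_record(
    disease = obj$disease %||% "",
    facts = as.list(obj$facts %||% list()),
    occupation = obj$occupation %||% "",
    values = vals
  )
}

#' @param patient a `vbtr_patient`
#' @rdname read_patient
#' @export
write_patient <- function(patient, path) {
  validate_patient(patient)
  obj <- list(
    disease = patient$disease,
    facts = patient$facts,
    occupation = patient$occupation,
    values = as.list(patient$values)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
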