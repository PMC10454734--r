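# Turtle serialization of the five-part argument structure.
#
# Each argument is one subject in the `vbtr:` vocabulary with properties
# vbtr:disease, vbtr:condition (eligibility rule as text), vbtr:requiresValue
# (repeated), vbtr:plan, vbtr:support_type, vbtr:weight, vbtr:evidence_kind
# and optional provenance (vbtr:sourceIndex, vbtr:source, vbtr:link).
# The reader/writer covers exactly this vocabulary; it is not a general
# Turtle engine.

VBTR_NS <- "http://vbtr.example.org/ns#"

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub("\"", "\\\"", x, fixed = TRUE)
}

ttl_unescape <- function(x) {
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

format_weight <- function(w) {
  if (w == round(w)) sprintf("%d", as.integer(w)) else as.character(w)
}

#' Write arguments to RDF/Turtle
#'
#' Serializes a list of arguments in the `vbtr:` vocabulary. The condition
#' rule is stored in its textual surface form (see [deparse_condition()]),
#' so `read_arguments_rdf(write_arguments_rdf(x))` reproduces `x` exactly.
#'
#' @param arguments list of `vbtr_argument`
#' @param path optional file path; when given the document is also written
#' @return the Turtle document as a character scalar, invisibly when `path`
#'   is given
#' @export
write_arguments_rdf <- function(arguments, path = NULL) {
  stopifnot(all(vapply(arguments, inherits, logical(1), "vbtr_argument")))
  lines <- c(sprintf("@prefix vbtr: <%s> .", VBTR_NS), "")
  for (a in arguments) {
    subj <- sprintf("vbtr:arg_%s", gsub("[^A-Za-z0-9_]", "_", a$id))
    props <- c(
      "a vbtr:Argument",
      sprintf("vbtr:disease \"%s\"", ttl_escape(a$disease)),
      sprintf("vbtr:condition \"%s\"", ttl_escape(deparse_condition(a$condition))),
      vapply(a$required_values,
             function(v) sprintf("vbtr:requiresValue \"%s\"", ttl_escape(v)),
             character(1)),
      sprintf("vbtr:plan \"%s\"", ttl_escape(a$plan)),
      sprintf("vbtr:support_type \"%s\"", a$support_type),
      sprintf("vbtr:weight %s", format_weight(a$weight)),
      sprintf("vbtr:evidence_kind \"%s\"", a$evidence_kind)
    )
    if (!is.na(a$provenance$source_index)) {
      props <- c(props, sprintf("vbtr:sourceIndex %d", a$provenance$source_index))
    }
    if (nzchar(a$provenance$author_year)) {
      props <- c(props, sprintf("vbtr:source \"%s\"", ttl_escape(a$provenance$author_year)))
    }
    if (nzchar(a$provenance$link)) {
      props <- c(props, sprintf("vbtr:link \"%s\"", ttl_escape(a$provenance$link)))
    }
    body <- paste0("    ", props, collapse = " ;\n")
    lines <- c(lines, paste0(subj, "\n", body, " ."), "")
  }
  doc <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

# Tokenize a Turtle document into strings, numbers, qnames and punctuation.
ttl_tokenize <- function(doc) {
  chars <- strsplit(doc, "", fixed = TRUE)[[1]]
  tokens <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "#") {  # comment to end of line
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      buf <- character(0)
      while (j <= n) {
        if (chars[j] == "\\" && j < n) {
          buf <- c(buf, chars[j], chars[j + 1L]); j <- j + 2L
        } else if (chars[j] == "\"") {
          break
        } else {
          buf <- c(buf, chars[j]); j <- j + 1L
        }
      }
      if (j > n) stop("unterminated string literal in Turtle document", call. = FALSE)
      tokens <- c(tokens, paste0("\"", paste(buf, collapse = "")))
      i <- j + 1L
      next
    }
    if (ch %in% c(";", ",")) { tokens <- c(tokens, ch); i <- i + 1L; next }
    if (ch == "<") {
      j <- i
      while (j <= n && chars[j] != ">") j <- j + 1L
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
      next
    }
    # bare token: qname, number, '.', '@prefix', 'a'
    j <- i
    while (j <= n && !grepl("[[:space:]]", chars[j]) &&
           !chars[j] %in% c(";", ",", "\"")) {
      j <- j + 1L
    }
    tok <- paste(chars[i:(j - 1L)], collapse = "")
    # statement-terminating '.' may be glued to nothing (we emit it spaced)
    tokens <- c(tokens, tok)
    i <- j
  }
  tokens
}

#' Read arguments from RDF/Turtle
#'
#' Parses a Turtle document in the `vbtr:` argument vocabulary and
#' reconstructs the argument list. Every argument invariant is re-validated
#' on read; a node missing `vbtr:support_type` or `vbtr:weight`, or carrying
#' a support type other than `"positive"`/`"negative"`, raises a schema
#' error naming the offending node.
#'
#' @param x file path or Turtle text
#' @return list of `vbtr_argument`
#' @export
read_arguments_rdf <- function(x) {
  doc <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    paste(readLines(x, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  tokens <- ttl_tokenize(doc)
  # drop prefix declarations: "@prefix", "vbtr:", "<...>", "."
  i <- 1L
  subjects <- list()
  order <- character(0)
  cur <- NULL
  pred <- NULL
  expect <- "subject"
  while (i <= length(tokens)) {
    tok <- tokens[i]
    if (tok == "@prefix") { i <- i + 4L; next }
    if (expect == "subject") {
      cur <- tok
      if (is.null(subjects[[cur]])) { subjects[[cur]] <- list(); order <- c(order, cur) }
      expect <- "predicate"
    } else if (expect == "predicate") {
      pred <- tok
      expect <- "object"
    } else if (expect == "object") {
      val <- if (startsWith(tok, "\"")) ttl_unescape(substring(tok, 2)) else tok
      subjects[[cur]][[pred]] <- c(subjects[[cur]][[pred]], val)
      i <- i + 1L
      if (i > length(tokens)) stop("truncated Turtle statement", call. = FALSE)
      sep <- tokens[i]
      if (sep == ";") {
        expect <- "predicate"
      } else if (sep == ".") {
        expect <- "subject"
      } else if (sep == ",") {
        expect <- "object"
        next_pred <- pred  # object list continues the same predicate
        pred <- next_pred
      } else {
        stop("unexpected token '", sep, "' in Turtle document", call. = FALSE)
      }
    }
    i <- i + 1L
  }

  out <- list()
  for (subj in order) {
    props <- subjects[[subj]]
    if (!identical(unname(props[["a"]]), "vbtr:Argument")) next
    need <- function(p) {
      v <- props[[p]]
      if (is.null(v)) {
        stop("argument node ", subj, " is missing required property ", p,
             call. = FALSE)
      }
      v
    }
    st <- need("vbtr:support_type")
    if (!st %in% c("positive", "negative")) {
      stop("argument node ", subj, " has invalid support_type '", st,
           "' (only 'positive' and 'negative' are admitted)", call. = FALSE)
    }
    w <- suppressWarnings(as.numeric(need("vbtr:weight")))
    if (is.na(w)) stop("argument node ", subj, " has a non-numeric weight", call. = FALSE)
    kind <- props[["vbtr:evidence_kind"]] %||%
      (if (is.null(props[["vbtr:requiresValue"]])) "clinical" else "value")
    src_idx <- props[["vbtr:sourceIndex"]]
    out[[length(out) + 1L]] <- argument(
      id = sub("^vbtr:arg_", "", subj),
      disease = need("vbtr:disease"),
      condition = parse_condition(need("vbtr:condition")),
      plan = need("vbtr:plan"),
      support_type = st,
      weight = w,
      evidence_kind = kind,
      required_values = props[["vbtr:requiresValue"]] %||% character(0),
      provenance = list(
        source_index = if (is.null(src_idx)) NA_integer_ else as.integer(src_idx),
        author_year = props[["vbtr:source"]] %||% "",
        link = props[["vbtr:link"]] %||% ""
      )
    )
  }
  out
}
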