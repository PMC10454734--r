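# Flat key/value configuration files (TOML-style `key = value` lines).

#' Read a configuration file
#'
#' Lines have the form `key = value`; `#` starts a comment; values that look
#' numeric are coerced. Recognized keys are `lambda`, `mode`, `tau`,
#' `alpha` and `data_dir`, but any key is retained.
#'
#' @param path configuration file
#' @return named list of settings
#' @export
read_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_.]*)[[:space:]]*=[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed configuration line: '", ln, "'", call. = FALSE)
    val <- gsub("^[\"']|[\"']$", "", trimws(m[3]))
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num) && grepl("^[-+0-9.eE]+$", val)) num else val
  }
  out
}

#' Default engine settings
#'
#' @return named list of the built-in defaults (`lambda = 0.5`,
#'   `mode = "literal"`, `tau = 0`, `alpha = 0.25`)
#' @export
default_config <- function() {
  list(lambda = 0.5, mode = "literal", tau = 0, alpha = 0.25)
}
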