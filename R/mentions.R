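# Vocabulary-term detection in free text: case-insensitive, hyphen/space
# normalized, longest-match over overlapping spans.

normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[-–—/]", " ", x)
  squish(x)
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Find vocabulary-term mentions in text
#'
#' Detects occurrences of vocabulary terms as whole-word sequences in
#' `text`, case-insensitively; hyphens are normalized to spaces so
#' "cost-effective" matches the term "cost effective". When a longer term
#' matches, shorter vocabulary terms wholly contained in the same span are
#' suppressed ("cost" is not reported inside a "cost effective" match,
#' though it is still reported if it occurs on its own elsewhere).
#'
#' @param text a single character string
#' @param vocabulary character vector of terms
#' @return character vector of matched terms (a subset of `vocabulary`),
#'   in vocabulary order
#' @export
find_mentions <- function(text, vocabulary) {
  if (length(text) != 1L || is.na(text)) return(character(0))
  txt <- normalize_text(text)
  if (!nzchar(txt) || length(vocabulary) == 0L) return(character(0))
  vocabulary <- unique(vocabulary)
  spans <- list()
  for (term in vocabulary) {
    t_norm <- normalize_text(term)
    if (!nzchar(t_norm)) next
    pat <- paste0("\\b", regex_escape(t_norm), "\\b")
    m <- gregexpr(pat, txt, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      spans[[length(spans) + 1L]] <- list(
        term = term,
        start = as.integer(m[k]),
        end = as.integer(m[k]) + attr(m, "match.length")[k] - 1L
      )
    }
  }
  if (length(spans) == 0L) return(character(0))
  # suppress matches strictly contained in a longer match
  keep <- vapply(seq_along(spans), function(i) {
    si <- spans[[i]]
    !any(vapply(seq_along(spans), function(j) {
      if (i == j) return(FALSE)
      sj <- spans[[j]]
      sj$start <= si$start && si$end <= sj$end &&
        (sj$end - sj$start) > (si$end - si$start)
    }, logical(1)))
  }, logical(1))
  matched <- unique(vapply(spans[keep], `[[`, character(1), "term"))
  vocabulary[vocabulary %in% matched]
}
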