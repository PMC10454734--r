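# Population-based value pre-configuration: occupation-indexed preset
# weights for how strongly treatment side effects threaten values typical of
# that occupation, with adaptive adjustment from recorded patient
# fine-tuning.

#' Load a value pre-configuration table
#'
#' Reads a CSV with columns `Occupation,Related,Item,Weight`; weights must
#' lie in \[0, 1\] and each (occupation, item) pair must be unique.
#' Observation counts start at zero and the adjustment log empty.
#'
#' @param path CSV file path
#' @return an object of class `vbtr_preconfig`
#' @export
load_preconfig <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  needed <- c("Occupation", "Related", "Item", "Weight")
  if (!all(needed %in% names(df))) {
    stop("pre-configuration table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  w <- suppressWarnings(as.numeric(df$Weight))
  if (any(is.na(w)) || any(w < 0 | w > 1)) {
    stop("pre-configuration weights must lie in [0, 1]", call. = FALSE)
  }
  entries <- data.frame(
    occupation = squish(df$Occupation),
    related = squish(df$Related),
    item = squish(df$Item),
    preset_weight = w,
    observation_count = 0L,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(entries[c("occupation", "item")])) {
    stop("duplicate (occupation, item) pair in pre-configuration table",
         call. = FALSE)
  }
  structure(
    list(
      entries = entries,
      log = data.frame(occupation = character(0), item = character(0),
                       observed_weight = numeric(0), order_index = integer(0),
                       stringsAsFactors = FALSE)
    ),
    class = "vbtr_preconfig"
  )
}

#' @export
print.vbtr_preconfig <- function(x, ...) {
  cat("<value pre-configuration>", nrow(x$entries), "entries,",
      length(unique(x$entries$occupation)), "occupations,",
      nrow(x$log), "recorded adjustments\n")
  invisible(x)
}

#' Preset side-effect/value profile for an occupation
#'
#' Returns the preset weights for every item recorded for the occupation
#' (case-insensitive match). An unknown occupation yields an empty profile
#' with a logged notice, and the engine then relies solely on explicitly
#' declared patient values.
#'
#' @param preconfig a `vbtr_preconfig`
#' @param occupation occupation label
#' @return named numeric vector item -> preset weight
#' @export
preset_profile <- function(preconfig, occupation) {
  stopifnot(inherits(preconfig, "vbtr_preconfig"))
  hit <- preconfig$entries[
    tolower(preconfig$entries$occupation) == tolower(squish(occupation)), ,
    drop = FALSE
  ]
  if (nrow(hit) == 0L) {
    message("no value pre-configuration for occupation '", occupation,
            "'; relying on explicit patient values only")
    return(stats::setNames(numeric(0), character(0)))
  }
  stats::setNames(hit$preset_weight, hit$item)
}

#' Record a patient fine-tuning adjustment
#'
#' Updates the preset weight of one (occupation, item) entry toward an
#' observed patient weight using an exponential moving average:
#' `preset <- (1 - alpha) * preset + alpha * observed`. The update is convex,
#' so presets stay in \[0, 1\]; repeated adjustment toward a constant
#' observation converges to it. The adjustment is appended to the
#' (append-only) log and the entry's observation count incremented.
#'
#' @param preconfig a `vbtr_preconfig`
#' @param occupation occupation label
#' @param item side-effect/value item name
#' @param observed observed patient weight in \[0, 1\]
#' @param alpha learning rate in (0, 1\]; default 0.25
#' @return the updated `vbtr_preconfig` (functional update; the input is not
#'   modified)
#' @export
record_adjustment <- function(preconfig, occupation, item, observed,
                              alpha = 0.25) {
  stopifnot(inherits(preconfig, "vbtr_preconfig"))
  if (!is_scalar_number(observed) || observed < 0 || observed > 1) {
    stop("observed weight must lie in [0, 1]", call. = FALSE)
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  i <- which(tolower(preconfig$entries$occupation) == tolower(squish(occupation)) &
             tolower(preconfig$entries$item) == tolower(squish(item)))
  if (length(i) != 1L) {
    stop("no pre-configuration entry for (", occupation, ", ", item, ")",
         call. = FALSE)
  }
  preconfig$entries$preset_weight[i] <-
    (1 - alpha) * preconfig$entries$preset_weight[i] + alpha * observed
  preconfig$entries$observation_count[i] <-
    preconfig$entries$observation_count[i] + 1L
  preconfig$log <- rbind(preconfig$log, data.frame(
    occupation = preconfig$entries$occupation[i],
    item = preconfig$entries$item[i],
    observed_weight = observed,
    order_index = nrow(preconfig$log) + 1L,
    stringsAsFactors = FALSE
  ))
  preconfig
}

#' Load the side-effect -> value-term mapping
#'
#' The pre-configuration table mixes concrete side effects ("Alopecia") with
#' values; the engine needs them expressed as taxonomy value terms. The
#' mapping is an explicit, editable CSV (`Item,ValueTerm`), not inferred.
#'
#' @param path CSV path; defaults to the packaged mapping
#' @return named character vector item (lower-cased) -> value term
#' @export
load_side_effect_map <- function(path = vbtr_extdata("side_effect_values.csv")) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  stopifnot(all(c("Item", "ValueTerm") %in% names(df)))
  stats::setNames(tolower(trimws(df$ValueTerm)), tolower(squish(df$Item)))
}

#' Preset patient value weights for an occupation
#'
#' Translates an occupation's preset side-effect profile into value-term
#' weights via the side-effect mapping. When several items map to the same
#' value term, the strongest preset wins. These weights serve as defaults
#' for value terms the patient has not set explicitly.
#'
#' @param preconfig a `vbtr_preconfig`
#' @param occupation occupation label
#' @param mapping result of [load_side_effect_map()]
#' @return named numeric vector value term -> preset weight
#' @export
preset_value_weights <- function(preconfig, occupation,
                                 mapping = load_side_effect_map()) {
  prof <- preset_profile(preconfig, occupation)
  if (length(prof) == 0L) return(stats::setNames(numeric(0), character(0)))
  terms <- mapping[tolower(names(prof))]
  keep <- !is.na(terms) & nzchar(terms)
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  agg <- tapply(prof[keep], terms[keep], max)
  stats::setNames(as.numeric(agg), names(agg))
}
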