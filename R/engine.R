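# Recommendation engine: match patient facts and values against the unified
# evidence base, aggregate signed weights per treatment plan, blend the
# clinical and value channels, rank, and explain.
#
# Channel semantics:
#   clinical: an argument activates iff the disease matches and the
#     condition rule holds; a positive argument adds +weight to its plan,
#     a negative one adds -weight.
#   value: activation additionally requires every required value term to be
#     held by the patient with weight > tau. With v = min patient weight
#     over the required terms, negative arguments contribute -weight * v;
#     positive arguments contribute +weight in the default "literal" mode
#     (the asymmetry stated for the method) or +weight * v in "symmetric"
#     mode.

empty_activations <- function() {
  data.frame(
    argument_id = character(0), plan = character(0), channel = character(0),
    signed_contribution = numeric(0), stringsAsFactors = FALSE
  )
}

disease_matches <- function(argument, patient) {
  tolower(squish(argument$disease)) == tolower(squish(patient$disease))
}

# Effective patient weight for one value term: the explicit profile first
# (directly, then through the alias map in either direction), then the
# occupation preset. NA when the patient does not hold the value at all.
lookup_value_weight <- function(term, profile, preset = NULL, aliases = NULL) {
  candidates <- term
  if (!is.null(aliases)) {
    if (term %in% names(aliases$map)) {
      candidates <- c(candidates, unname(aliases$map[term]))
    }
    back <- names(aliases$map)[aliases$map == term]
    candidates <- unique(c(candidates, back))
  }
  for (cand in candidates) {
    if (!is.null(profile) && cand %in% names(profile)) return(unname(profile[cand]))
  }
  for (cand in candidates) {
    if (!is.null(preset) && cand %in% names(preset)) return(unname(preset[cand]))
  }
  NA_real_
}

channel_result <- function(scores, activations) {
  structure(list(scores = scores, activations = activations),
            class = "vbtr_channel")
}

#' Score the clinical channel
#'
#' A clinical argument activates iff its disease matches the patient's and
#' its condition rule holds on the patient's facts. Activated positive
#' arguments add `+weight` to their plan, negative arguments add `-weight`;
#' non-activated arguments contribute nothing.
#'
#' @param patient a `vbtr_patient`
#' @param arguments list of clinical arguments (`evidence_kind = "clinical"`;
#'   passing a value argument is a contract violation)
#' @return list with `scores` (named numeric by canonical plan, only plans
#'   mentioned in the arguments) and `activations` (data frame of activated
#'   arguments with signed contributions)
#' @export
score_clinical <- function(patient, arguments) {
  validate_patient(patient)
  kinds <- vapply(arguments, `[[`, character(1), "evidence_kind")
  if (any(kinds != "clinical")) {
    stop("score_clinical() received value arguments; use score_value()",
         call. = FALSE)
  }
  plans <- unique(vapply(arguments, `[[`, character(1), "plan"))
  scores <- stats::setNames(numeric(length(plans)), plans)
  acts <- list()
  for (a in arguments) {
    if (!disease_matches(a, patient)) next
    if (!match_condition(a$condition, patient)) next
    contrib <- if (a$support_type == "positive") a$weight else -a$weight
    scores[a$plan] <- scores[a$plan] + contrib
    acts[[length(acts) + 1L]] <- data.frame(
      argument_id = a$id, plan = a$plan, channel = "clinical",
      signed_contribution = contrib, stringsAsFactors = FALSE
    )
  }
  channel_result(scores, if (length(acts)) do.call(rbind, acts) else empty_activations())
}

#' Score the value channel
#'
#' A value argument activates iff its disease matches, its condition rule
#' holds, and every required value term is held by the patient with weight
#' strictly greater than `tau`. Let `v` be the minimum patient weight over
#' the required terms (weakest-link conjunction). Negative arguments
#' contribute `-weight * v`. Positive arguments contribute `+weight` in
#' `"literal"` mode (the default) or `+weight * v` in `"symmetric"` mode.
#' Patient weights default from the occupation preset (`preset`) for terms
#' the patient has not set explicitly.
#'
#' @param patient a `vbtr_patient`
#' @param arguments list of value arguments (`evidence_kind = "value"`)
#' @param mode `"literal"` or `"symmetric"`
#' @param tau activation threshold on patient value weights; default 0
#' @param preset named numeric of preset value weights (see
#'   [preset_value_weights()]), or `NULL`
#' @param aliases alias vocabulary from [load_value_aliases()], or `NULL`;
#'   lets an argument requiring "pregnancy later" activate on a patient who
#'   declared "pregnancy"
#' @return list with `scores` (named numeric by plan) and `activations`
#'   (data frame; `triggering_values` is a list-column of named weights)
#' @export
score_value <- function(patient, arguments, mode = c("literal", "symmetric"),
                        tau = 0, preset = NULL, aliases = NULL) {
  validate_patient(patient)
  mode <- match.arg(mode)
  kinds <- vapply(arguments, `[[`, character(1), "evidence_kind")
  if (any(kinds != "value")) {
    stop("score_value() received clinical arguments; use score_clinical()",
         call. = FALSE)
  }
  plans <- unique(vapply(arguments, `[[`, character(1), "plan"))
  scores <- stats::setNames(numeric(length(plans)), plans)
  acts <- list()
  trig <- list()
  for (a in arguments) {
    if (!disease_matches(a, patient)) next
    if (!match_condition(a$condition, patient)) next
    w <- vapply(a$required_values, lookup_value_weight, numeric(1),
                profile = patient$values, preset = preset, aliases = aliases)
    if (anyNA(w) || any(w <= tau)) next
    v <- min(w)
    contrib <- if (a$support_type == "negative") {
      -a$weight * v
    } else if (mode == "literal") {
      a$weight
    } else {
      a$weight * v
    }
    scores[a$plan] <- scores[a$plan] + contrib
    acts[[length(acts) + 1L]] <- data.frame(
      argument_id = a$id, plan = a$plan, channel = "value",
      signed_contribution = contrib, stringsAsFactors = FALSE
    )
    trig[[length(trig) + 1L]] <- stats::setNames(w, a$required_values)
  }
  activations <- if (length(acts)) do.call(rbind, acts) else empty_activations()
  activations$triggering_values <- trig
  channel_result(scores, activations)
}

#' Blend clinical and value scores
#'
#' `blended = (1 - lambda) * clinical + lambda * value`. `lambda` is the
#' clinical/value proportion slider: 0 is purely clinical, 1 purely
#' value-driven.
#'
#' @param clinical_score,value_score numeric (vectorized)
#' @param lambda blend coefficient in \[0, 1\]
#' @return blended scores
#' @export
blend <- function(clinical_score, value_score, lambda) {
  if (!is_scalar_number(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]", call. = FALSE)
  }
  (1 - lambda) * clinical_score + lambda * value_score
}

#' Rank treatment plans for a patient
#'
#' Runs the clinical and value channels over the full evidence base, blends
#' them, and returns plans ranked by blended score (descending; ties broken
#' lexicographically by canonical plan name). Every plan mentioned anywhere
#' in the evidence is scored; plans with no activated argument score 0.
#'
#' @param patient a `vbtr_patient`
#' @param evidence list of `vbtr_argument` (clinical and value mixed)
#' @param lambda blend coefficient in \[0, 1\]; default 0.5
#' @param mode value-channel mode, `"literal"` (default) or `"symmetric"`
#' @param tau value-activation threshold; default 0
#' @param preconfig optional `vbtr_preconfig` for occupation presets
#' @param mapping side-effect mapping used with `preconfig`
#' @param aliases alias vocabulary from [load_value_aliases()], or `NULL`
#' @param stages optional named character vector plan -> stage
#'   (`"pre-surgery"`, `"surgery"`, `"post-surgery"`) for the staged view
#' @return an object of class `vbtr_recommendation`: fields `disease`,
#'   `lambda_used`, `mode`, `ranked` (data frame plan/clinical_score/
#'   value_score/blended_score), `breakdown` (activated arguments),
#'   `stage_view`
#' @export
recommend <- function(patient, evidence, lambda = 0.5,
                      mode = c("literal", "symmetric"), tau = 0,
                      preconfig = NULL, mapping = NULL, aliases = NULL,
                      stages = NULL) {
  validate_patient(patient)
  mode <- match.arg(mode)
  if (!is_scalar_number(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]", call. = FALSE)
  }
  kinds <- vapply(evidence, `[[`, character(1), "evidence_kind")
  relevant <- vapply(evidence, function(a) {
    tolower(squish(a$disease)) == tolower(squish(patient$disease))
  }, logical(1))
  if (length(evidence) > 0L && !any(relevant)) {
    message("no evidence base for disease '", patient$disease,
            "'; returning an empty recommendation")
  }
  preset <- NULL
  if (!is.null(preconfig) && nzchar(patient$occupation)) {
    if (is.null(mapping)) mapping <- load_side_effect_map()
    preset <- preset_value_weights(preconfig, patient$occupation, mapping)
  }
  clin <- score_clinical(patient, evidence[kinds == "clinical"])
  val <- score_value(patient, evidence[kinds == "value"], mode = mode,
                     tau = tau, preset = preset, aliases = aliases)
  plans <- unique(c(names(clin$scores), names(val$scores)))
  ranked <- data.frame(
    plan = plans,
    clinical_score = ifelse(plans %in% names(clin$scores),
                            clin$scores[plans], 0),
    value_score = ifelse(plans %in% names(val$scores), val$scores[plans], 0),
    stringsAsFactors = FALSE
  )
  ranked$clinical_score[is.na(ranked$clinical_score)] <- 0
  ranked$value_score[is.na(ranked$value_score)] <- 0
  ranked$blended_score <- blend(ranked$clinical_score, ranked$value_score, lambda)
  ord <- order(-ranked$blended_score, ranked$plan, method = "radix")
  ranked <- ranked[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  breakdown <- rbind(
    clin$activations[, c("argument_id", "plan", "channel", "signed_contribution")],
    val$activations[, c("argument_id", "plan", "channel", "signed_contribution")]
  )
  breakdown$triggering_values <- c(
    rep(list(NULL), nrow(clin$activations)),
    val$activations$triggering_values %||% list()
  )
  stage_view <- NULL
  if (!is.null(stages)) {
    stage_view <- lapply(
      stats::setNames(nm = c("pre-surgery", "surgery", "post-surgery")),
      function(s) {
        sub <- ranked[ranked$plan %in% names(stages)[stages == s], , drop = FALSE]
        rownames(sub) <- NULL
        sub
      }
    )
  }
  structure(
    list(
      disease = patient$disease,
      lambda_used = lambda,
      mode = mode,
      ranked = ranked,
      breakdown = breakdown,
      stage_view = stage_view,
      evidence = evidence
    ),
    class = "vbtr_recommendation"
  )
}

#' @export
print.vbtr_recommendation <- function(x, ...) {
  cat("<recommendation> disease:", x$disease,
      sprintf("(lambda = %g, %s mode)\n", x$lambda_used, x$mode))
  if (nrow(x$ranked) == 0L) {
    cat("  no plans scored (empty evidence base)\n")
    return(invisible(x))
  }
  df <- x$ranked
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %d. %-28s blended %7.3f (clinical %7.3f, value %7.3f)\n",
                i, df$plan[i], df$blended_score[i], df$clinical_score[i],
                df$value_score[i]))
  }
  invisible(x)
}

#' Render a recommendation as a human-readable explanation
#'
#' For every ranked plan, lists the activated arguments with their signed
#' contributions, the triggering conditions and values, and the literature
#' provenance (author/year and link) where available. The report is a pure
#' function of the recommendation object.
#'
#' @param recommendation a `vbtr_recommendation`
#' @return character vector of report lines
#' @export
explain <- function(recommendation) {
  stopifnot(inherits(recommendation, "vbtr_recommendation"))
  x <- recommendation
  by_id <- stats::setNames(x$evidence,
                           vapply(x$evidence, `[[`, character(1), "id"))
  lines <- c(
    sprintf("Treatment ranking for %s (lambda = %g, %s value mode)",
            x$disease, x$lambda_used, x$mode),
    ""
  )
  if (nrow(x$ranked) == 0L) {
    return(c(lines, "No evidence base available: nothing to rank."))
  }
  for (i in seq_len(nrow(x$ranked))) {
    row <- x$ranked[i, ]
    lines <- c(lines, sprintf(
      "%d. %s  [blended %.3f = (1-%g)*%.3f clinical + %g*%.3f value]",
      i, row$plan, row$blended_score, x$lambda_used, row$clinical_score,
      x$lambda_used, row$value_score))
    acts <- x$breakdown[x$breakdown$plan == row$plan, , drop = FALSE]
    if (nrow(acts) == 0L) {
      lines <- c(lines, "   no supporting or opposing evidence", "")
      next
    }
    for (j in seq_len(nrow(acts))) {
      a <- by_id[[acts$argument_id[j]]]
      dir <- if (acts$signed_contribution[j] >= 0) "supports" else "opposes"
      ln <- sprintf("   %+.3f  %s argument %s %s %s (condition: %s)",
                    acts$signed_contribution[j], acts$channel[j],
                    acts$argument_id[j], dir, row$plan,
                    deparse_condition(a$condition))
      tv <- acts$triggering_values[[j]]
      if (!is.null(tv) && length(tv)) {
        ln <- paste0(ln, sprintf("; values: %s",
                                 paste0(names(tv), "=", format(tv), collapse = ", ")))
      }
      lines <- c(lines, ln)
      if (nzchar(a$provenance$author_year) || nzchar(a$provenance$link)) {
        lines <- c(lines, sprintf("           source: %s %s",
                                  a$provenance$author_year, a$provenance$link))
      }
    }
    lines <- c(lines, "")
  }
  if (!is.null(x$stage_view)) {
    lines <- c(lines, "Staged view:")
    for (s in names(x$stage_view)) {
      sub <- x$stage_view[[s]]
      top <- if (nrow(sub)) sub$plan[1] else "(no tagged plan)"
      lines <- c(lines, sprintf("  %s: %s", s, top))
    }
  }
  lines
}
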