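# Seeded synthetic generators: a literature corpus with planted keyword
# occurrences (so screening counts are known by construction) and
# schema-valid patient records, including the two illustrative presets.

# Filler vocabulary chosen to avoid the disease, value and plan terms used
# in the screening fixtures.
FILLER_TOPICS <- c("soil microbiome", "glacier mass balance", "urban noise",
                   "river sediment", "pollinator foraging", "stellar spectra")
FILLER_VERBS <- c("was quantified", "was profiled", "was modelled",
                  "was sampled", "was surveyed")

#' Generate a synthetic literature corpus with planted screening counts
#'
#' Builds a corpus in which exactly `n_disease_hits` records mention the
#' disease together with at least one value term, `n_duplicates` of those
#' are exact duplicates (title and abstract identical up to letter case) of
#' other hit records, and exactly `n_plan_hits` of the post-deduplication
#' hits mention a treatment-plan keyword. Running [screen_corpus()] on the
#' result must therefore report
#' `(n_disease_hits, n_disease_hits - n_duplicates, n_plan_hits)`. The same
#' seed yields a byte-identical corpus file.
#'
#' @param n_records total corpus size
#' @param n_disease_hits records mentioning disease + value
#' @param n_duplicates duplicated records among the disease hits (requires
#'   at least one unique hit to duplicate)
#' @param n_plan_hits unique hit records that also mention a plan keyword;
#'   at most `n_disease_hits - n_duplicates`
#' @param seed integer RNG seed
#' @param disease disease keyword planted in hits
#' @param values value vocabulary to plant from
#' @param plans plan-keyword vocabulary to plant from
#' @return list with `records` (corpus data frame), `truth` (list
#'   `retrieved`, `deduplicated`, `plan_filtered`) and `seed`
#' @export
generate_corpus <- function(n_records, n_disease_hits, n_duplicates,
                            n_plan_hits, seed,
                            disease = "breast cancer",
                            values = c("pain", "appearance", "fracture",
                                       "depression", "family"),
                            plans = c("Tamoxifen", "Chemotherapy",
                                      "Radiotherapy", "Mastectomy")) {
  stopifnot(n_records >= 0, n_disease_hits >= 0, n_duplicates >= 0,
            n_plan_hits >= 0)
  if (n_disease_hits > n_records) {
    stop("n_disease_hits must not exceed n_records", call. = FALSE)
  }
  if (n_duplicates > n_disease_hits) {
    stop("n_duplicates must not exceed n_disease_hits", call. = FALSE)
  }
  n_unique <- n_disease_hits - n_duplicates
  if (n_duplicates > 0L && n_unique == 0L) {
    stop("duplicates need at least one unique hit record to copy", call. = FALSE)
  }
  if (n_plan_hits > n_unique) {
    stop("n_plan_hits must not exceed n_disease_hits - n_duplicates",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  recs <- vector("list", n_records)
  # unique disease hits; the first n_plan_hits also carry a plan keyword
  for (i in seq_len(n_unique)) {
    val <- sample(values, 1L)
    abstract <- sprintf(
      "We studied %s patients and their concerns about %s during follow up.",
      disease, val)
    if (i <= n_plan_hits) {
      abstract <- paste(abstract, sprintf("Management with %s was assessed.",
                                          sample(plans, 1L)))
    }
    recs[[i]] <- list(
      title = sprintf("A %s cohort study, series %d", disease, i),
      abstract = abstract
    )
  }
  # duplicates: copy a unique hit, toggling case so the duplication is only
  # visible after normalization
  if (n_duplicates > 0L) {
    src <- sample(n_unique, n_duplicates, replace = TRUE)
    for (k in seq_len(n_duplicates)) {
      orig <- recs[[src[k]]]
      recs[[n_unique + k]] <- list(
        title = toupper(orig$title),
        abstract = orig$abstract
      )
    }
  }
  # filler records: no disease mention at all
  for (i in seq_len(n_records - n_disease_hits)) {
    recs[[n_disease_hits + i]] <- list(
      title = sprintf("%s survey, part %d", sample(FILLER_TOPICS, 1L), i),
      abstract = sprintf("The site %s across three seasons.",
                         sample(FILLER_VERBS, 1L))
    )
  }
  perm <- sample.int(n_records)
  df <- data.frame(
    record_id = sprintf("rec%04d", seq_len(n_records)),
    title = vapply(recs[perm], `[[`, character(1), "title"),
    abstract = vapply(recs[perm], `[[`, character(1), "abstract"),
    year = sample(1995:2023, n_records, replace = TRUE),
    authors = sprintf("Author%02d et al.", sample.int(40, n_records, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  if (n_records == 0L) {
    df <- data.frame(record_id = character(0), title = character(0),
                     abstract = character(0), year = integer(0),
                     authors = character(0), stringsAsFactors = FALSE)
  }
  list(
    records = df,
    truth = list(retrieved = n_disease_hits, deduplicated = n_unique,
                 plan_filtered = n_plan_hits),
    seed = seed
  )
}

#' Write a corpus data frame as JSON lines
#'
#' @param records corpus data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_corpus <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    line <- jsonlite::toJSON(list(
      id = records$record_id[i], title = records$title[i],
      abstract = records$abstract[i], year = records$year[i],
      authors = records$authors[i]
    ), auto_unbox = TRUE)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Generate a synthetic patient record
#'
#' `preset = "random"` draws schema-valid facts and a value profile from the
#' taxonomy vocabulary. The `"lisa"` preset emulates a performer who values
#' a future pregnancy, short treatment duration and appearance, tolerates
#' pain, and is premenopausal; `"mata"` emulates an assembly-line worker who
#' prioritizes treatment outcome and cost and strongly avoids pain. The same
#' seed yields an identical record.
#'
#' @param seed integer RNG seed
#' @param preset `"random"`, `"lisa"` or `"mata"`
#' @param disease disease name
#' @return a validated `vbtr_patient`
#' @export
generate_patient <- function(seed = 1L, preset = c("random", "lisa", "mata"),
                             disease = "breast cancer") {
  preset <- match.arg(preset)
  if (preset == "lisa") {
    return(patient_record(
      disease,
      facts = list(menopausal_status = "pre", er = "positive",
                   her2 = "negative", age = 32L, grade = 2L,
                   surgery_phase = "pre", bmi_class = "normal"),
      occupation = "Actor",
      values = c("pregnancy later" = 0.95, "treatment duration" = 0.9,
                 "appearance" = 0.9, "convenience" = 0.7, "pain" = 0.2)
    ))
  }
  if (preset == "mata") {
    return(patient_record(
      disease,
      facts = list(menopausal_status = "pre", er = "positive",
                   her2 = "negative", age = 32L, grade = 2L,
                   surgery_phase = "pre", bmi_class = "normal"),
      occupation = "Assembly line worker",
      values = c("treatment outcome" = 0.95, "cost" = 0.9, "pain" = 0.9,
                 "cost effective" = 0.85, "treatment duration" = 0.2)
    ))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  facts <- list()
  for (nm in names(FACT_DOMAINS)) {
    if (runif(1) < 0.8) facts[[nm]] <- sample(FACT_DOMAINS[[nm]], 1L)
  }
  if (runif(1) < 0.9) facts$age <- sample(18:90, 1L)
  if (runif(1) < 0.7) facts$grade <- sample(1:3, 1L)
  vocab <- c("pain", "appearance", "fracture", "depression", "family",
             "pregnancy later", "treatment duration", "cost", "convenience",
             "recurrence", "risk", "weight", "cost effective",
             "treatment outcome", "survival", "walking")
  n_vals <- sample(0:8, 1L)
  vals <- if (n_vals > 0L) {
    stats::setNames(round(runif(n_vals), 3), sample(vocab, n_vals))
  } else numeric(0)
  occ <- sample(c("", "Actor", "Writer", "Assembly line worker", "Teacher"), 1L)
  patient_record(disease, facts = facts, occupation = occ, values = vals)
}
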