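# Randomized fixture builders shared by the property-style tests. All draws
# go through the caller's RNG state, so tests wrap them in set.seed().

COND_SURFACES <- c(
  "premenopausal", "postmenopausal", "ER+", "ER-", "HER2+", "HER2-",
  "node-positive", "node-negative", "pre-surgery", "after surgery",
  "overweight", "normal weight", "diabetic", "smoker"
)
PLAN_POOL <- c("Endocrine therapy", "Chemotherapy", "Radiotherapy",
               "Tamoxifen", "Anastrozole", "Chemotherapy+GnRHa",
               "Mastectomy", "Targeted Therapy")
VALUE_POOL <- c("pain", "appearance", "fracture", "depression", "family",
                "pregnancy later", "treatment duration", "cost",
                "convenience", "recurrence", "risk", "weight",
                "cost effective", "survival")

random_condition_text <- function(max_atoms = 3) {
  n <- sample(0:max_atoms, 1)
  if (n == 0) return("-")
  atoms <- character(n)
  for (i in seq_len(n)) {
    kind <- sample(c("flag", "cmp", "range", "grade"), 1,
                   prob = c(0.6, 0.2, 0.1, 0.1))
    atoms[i] <- switch(kind,
      flag = sample(COND_SURFACES, 1),
      cmp = sprintf("age %s %d", sample(c(">", "<"), 1), sample(30:80, 1)),
      range = { a <- sort(sample(18:80, 2)); sprintf("age %d-%d", a[1], a[2]) },
      grade = sprintf("grade %d", sample(1:3, 1))
    )
  }
  paste(atoms, collapse = ", ")
}

random_argument <- function(id, kind = c("clinical", "value"),
                            disease = "breast cancer") {
  kind <- if (length(kind) > 1) sample(kind, 1) else kind
  req <- if (kind == "value") {
    sample(VALUE_POOL, sample(1:2, 1))
  } else {
    character(0)
  }
  argument(
    id = id,
    disease = disease,
    condition = parse_condition(random_condition_text()),
    plan = sample(PLAN_POOL, 1),
    support_type = sample(c("positive", "negative"), 1),
    weight = round(runif(1, 0.5, 4), 3),
    evidence_kind = kind,
    required_values = req,
    provenance = if (runif(1) < 0.5) {
      list(source_index = sample(1:20, 1), author_year = "Someone/2020",
           link = sprintf("%d/", sample(1e6:2e6, 1)))
    } else {
      list()
    }
  )
}

random_evidence <- function(n, kind = c("clinical", "value")) {
  lapply(seq_len(n), function(i) random_argument(sprintf("a%03d", i), kind))
}

random_test_patient <- function(disease = "breast cancer") {
  facts <- list()
  for (nm in names(vbtr:::FACT_DOMAINS)) {
    if (runif(1) < 0.7) facts[[nm]] <- sample(vbtr:::FACT_DOMAINS[[nm]], 1)
  }
  if (runif(1) < 0.85) facts$age <- sample(18:90, 1)
  if (runif(1) < 0.6) facts$grade <- sample(1:3, 1)
  if (runif(1) < 0.3) facts$diabetic <- TRUE
  if (runif(1) < 0.3) facts$smoker <- "yes"
  n_vals <- sample(0:length(VALUE_POOL), 1)
  vals <- if (n_vals > 0) {
    stats::setNames(round(runif(n_vals), 3), sample(VALUE_POOL, n_vals))
  } else {
    numeric(0)
  }
  patient_record(disease, facts = facts, values = vals)
}

# Random value-evidence table written to a temp CSV; returns path plus the
# expected argument count by the row-splitting rule.
random_evidence_table <- function(n_rows) {
  support <- ifelse(runif(n_rows) < 0.35, "-", sample(PLAN_POOL, n_rows, replace = TRUE))
  oppose <- ifelse(runif(n_rows) < 0.35, "-", sample(PLAN_POOL, n_rows, replace = TRUE))
  # a row with neither direction would carry no argument; force at least one
  both_empty <- support == "-" & oppose == "-"
  support[both_empty] <- sample(PLAN_POOL, sum(both_empty), replace = TRUE)
  df <- data.frame(
    Index = seq_len(n_rows),
    Condition = vapply(seq_len(n_rows), function(i) random_condition_text(), character(1)),
    Value = vapply(seq_len(n_rows), function(i) {
      paste(sample(VALUE_POOL, sample(1:2, 1)), collapse = ", ")
    }, character(1)),
    Support = support,
    Oppose = oppose,
    Weight = sample(1:4, n_rows, replace = TRUE),
    SourceIndex = sample(1:16, n_rows, replace = TRUE),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  list(path = path, expected_n = sum(support != "-") + sum(oppose != "-"))
}

packaged <- function(file) system.file("extdata", file, package = "vbtr")
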