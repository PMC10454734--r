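make_records <- function(titles, abstracts) {
  data.frame(
    record_id = sprintf("r%02d", seq_along(titles)),
    title = titles, abstract = abstracts,
    year = 2020L, authors = "A et al.", stringsAsFactors = FALSE
  )
}

test_that("retrieval requires a disease mention plus at least one value", {
  recs <- make_records(
    c("breast cancer and pain management",           # hit (title)
      "breast cancer outcomes",                      # disease, no value
      "a study of knee injuries",                    # neither
      "Breast Cancer follow-up",                     # hit via abstract value
      "unrelated title"),
    c("", "", "pain was common", "patients reported pain", "pain everywhere")
  )
  out <- retrieve(recs, "breast cancer", c("pain", "appearance"))
  expect_equal(out$record_id, c("r01", "r04"))
  expect_equal(out$matched_values[[1]], "pain")

  # disease in the title only is enough (title OR abstract rule)
  solo <- make_records("breast cancer screening", "patients valued appearance")
  expect_equal(nrow(retrieve(solo, "breast cancer", "appearance")), 1)

  none <- make_records("knee surgery", "pain")
  expect_equal(nrow(retrieve(none, "breast cancer", "pain")), 0)
})

test_that("dedupe removes exact duplicates up to case and whitespace", {
  recs <- make_records(
    c("A Study", "a  study", "A Study", "A Study"),
    c("same abstract", "Same Abstract", "different abstract", "same abstract")
  )
  out <- dedupe(recs)
  # r01/r02/r04 collapse (first kept); r03 differs in abstract
  expect_equal(out$record_id, c("r01", "r03"))
  # all-unique input is untouched
  uniq <- make_records(c("t1", "t2"), c("a1", "a2"))
  expect_equal(dedupe(uniq), uniq)
})

test_that("plan filtering annotates canonical plans from keywords and categories", {
  pt <- load_plan_table(packaged("plan_keywords.csv"))
  recs <- make_records(
    c("breast cancer and Tamoxifen", "breast cancer lifestyle",
      "chemotherapy with mastectomy"),
    c("adjuvant options", "diet and exercise", "combined approach")
  )
  out <- filter_plans(recs, pt)
  expect_equal(out$record_id, c("r01", "r03"))
  expect_equal(out$matched_plans[[1]], "Tamoxifen")
  expect_setequal(out$matched_plans[[2]], c("Chemotherapy", "Mastectomy"))
})

test_that("grouping partitions by the sorted plan combination", {
  recs <- make_records(c("t1", "t2", "t3"), c("a1", "a2", "a3"))
  recs$matched_plans <- list("A", "A", c("A", "B"))
  g <- group_by_combination(recs)
  expect_length(g, 2)
  expect_setequal(names(g), c("A", "A + B"))
  expect_equal(nrow(g[["A"]]), 2)

  single <- recs[3, , drop = FALSE]
  expect_length(group_by_combination(single), 1)
  expect_length(group_by_combination(recs[0, , drop = FALSE]), 0)

  recs$matched_plans <- NULL
  expect_error(group_by_combination(recs), "filter_plans")
})

test_that("screening counts recover planted ground truth across seeds", {
  tax <- load_taxonomy(packaged("value_taxonomy.csv"))
  pt <- load_plan_table(packaged("plan_keywords.csv"))
  set.seed(2024)
  for (seed in sample.int(1e6, 25)) {
    n <- sample(10:120, 1)
    hits <- sample(0:n, 1)
    dups <- if (hits > 1) sample(0:(hits - 1), 1) else 0
    plan_hits <- sample(0:(hits - dups), 1)
    gen <- generate_corpus(n, hits, dups, plan_hits, seed = seed)
    rep <- screen_corpus(gen$records, "breast cancer", value_terms(tax), pt)
    expect_equal(rep$retrieved_count, gen$truth$retrieved)
    expect_equal(rep$deduplicated_count, gen$truth$deduplicated)
    expect_equal(rep$plan_filtered_count, gen$truth$plan_filtered)
    expect_equal(rep$plan_filtered_count,
                 sum(vapply(rep$groups, nrow, integer(1))))
    # pipeline monotonicity
    expect_true(rep$retrieved_count >= rep$deduplicated_count)
    expect_true(rep$deduplicated_count >= rep$plan_filtered_count)
  }
})

test_that("screening is deterministic and order-independent in its counts", {
  tax <- load_taxonomy(packaged("value_taxonomy.csv"))
  pt <- load_plan_table(packaged("plan_keywords.csv"))
  gen <- generate_corpus(40, 15, 3, 8, seed = 99)
  r1 <- screen_corpus(gen$records, "breast cancer", value_terms(tax), pt)
  set.seed(5)
  shuffled <- gen$records[sample.int(nrow(gen$records)), , drop = FALSE]
  r2 <- screen_corpus(shuffled, "breast cancer", value_terms(tax), pt)
  expect_equal(r1$retrieved_count, r2$retrieved_count)
  expect_equal(r1$deduplicated_count, r2$deduplicated_count)
  expect_equal(r1$plan_filtered_count, r2$plan_filtered_count)
  expect_equal(r1$group_count, r2$group_count)
})

test_that("unreadable corpus lines are skipped with a warning and counted", {
  f <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"a","title":"breast cancer and pain","abstract":"x","year":2020,"authors":"A"}',
    'this is not json',
    '{"id":"b","title":"soil survey","abstract":"y","year":2019,"authors":"B"}'
  ), f)
  expect_warning(recs <- read_corpus(f), "skipped")
  expect_equal(nrow(recs), 2)
  expect_equal(attr(recs, "skipped"), 1L)
  unlink(f)
})

test_that("the findings database exports and re-imports unchanged", {
  recs <- make_records(c("Title One", "Title Two", "Title Three"),
                       c("a", "b", "c"))
  findings <- data.frame(
    record_id = c("r01", "r02", "r03"),
    author_year = c("A/2020", "B/2019", "C/2018"),
    finding = c("finding, with comma", "plain", "another"),
    link = c("111/", "222/", "333/"),
    stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".csv")
  out <- export_database(recs, findings, f)
  expect_equal(nrow(out), 3)
  back <- import_findings(f)
  expect_equal(back$AuthorYear, findings$author_year)
  expect_equal(back$Finding, findings$finding)
  expect_equal(back$Title, recs$title)

  # empty findings: header-only file
  export_database(recs, findings[0, ], f)
  expect_equal(nrow(import_findings(f)), 0)

  findings$record_id[2] <- "r99"
  expect_error(export_database(recs, findings, f), "r99")
  unlink(f)

  # the packaged findings database round-trips
  pf <- import_findings(packaged("literature_findings.csv"))
  expect_equal(nrow(pf), 16)
  expect_equal(pf$Link[1], "32104064/")
})
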