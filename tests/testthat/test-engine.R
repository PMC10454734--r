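lisa_like <- function(values = c("pregnancy later" = 1.0)) {
  patient_record("breast cancer",
                 facts = list(menopausal_status = "pre"),
                 values = values)
}

test_that("clinical scoring adds +weight for, -weight against, 0 otherwise", {
  pos <- argument("c1", "breast cancer", "ER+", "Endocrine therapy",
                  "positive", 2, "clinical")
  neg <- argument("c2", "breast cancer", "ER+", "Endocrine therapy",
                  "negative", 2, "clinical")
  far <- argument("c3", "breast cancer", "age > 65", "Chemotherapy",
                  "positive", 3, "clinical")
  p <- patient_record("breast cancer", facts = list(er = "positive", age = 40))
  res <- score_clinical(p, list(pos))
  expect_equal(unname(res$scores["Endocrine therapy"]), 2)
  res <- score_clinical(p, list(neg))
  expect_equal(unname(res$scores["Endocrine therapy"]), -2)
  res <- score_clinical(p, list(pos, neg, far))
  expect_equal(unname(res$scores["Endocrine therapy"]), 0)
  expect_equal(unname(res$scores["Chemotherapy"]), 0)
  # disease mismatch deactivates everything
  other <- patient_record("lung cancer", facts = list(er = "positive"))
  expect_equal(sum(abs(score_clinical(other, list(pos))$scores)), 0)
  # channel contract
  val <- argument("v", "breast cancer", "-", "Chemotherapy", "positive", 2,
                  "value", required_values = "pain")
  expect_error(score_clinical(p, list(val)), "value")
  expect_error(score_value(p, list(pos)), "clinical")
})

test_that("value scoring reproduces the packaged evidence-table semantics", {
  ev <- packaged_value_evidence()
  res <- score_value(lisa_like(), ev)
  expect_equal(unname(res$scores["Endocrine therapy"]), 2)
  expect_equal(unname(res$scores["Chemotherapy"]), -2)
  expect_setequal(res$activations$argument_id, c("v1s", "v1o"))

  # a declared-but-zero value weight does not activate
  res0 <- score_value(lisa_like(c("pregnancy later" = 0)), ev)
  expect_equal(nrow(res0$activations), 0)
  expect_true(all(res0$scores == 0))

  # negative contributions scale with the patient's value weight
  resh <- score_value(lisa_like(c("pregnancy later" = 0.5)), ev)
  expect_equal(unname(resh$scores["Chemotherapy"]), -1)        # 2 * 0.5
  expect_equal(unname(resh$scores["Endocrine therapy"]), 2)    # literal mode
  ress <- score_value(lisa_like(c("pregnancy later" = 0.5)), ev,
                      mode = "symmetric")
  expect_equal(unname(ress$scores["Endocrine therapy"]), 1)    # 2 * 0.5
})

test_that("multi-value arguments use weakest-link conjunction", {
  ev <- packaged_value_evidence()
  p <- patient_record("breast cancer",
                      facts = list(menopausal_status = "post"),
                      values = c(mobility = 0.9, survival = 0.4))
  res <- score_value(p, ev)
  # row 16 opposes Hormone therapy with weight 2; v = min(0.9, 0.4)
  expect_equal(unname(res$scores["Hormone therapy"]), -2 * 0.4)
  # dropping one required value deactivates the argument
  p2 <- patient_record("breast cancer",
                       facts = list(menopausal_status = "post"),
                       values = c(mobility = 0.9))
  expect_equal(nrow(score_value(p2, ev)$activations), 0)
})

test_that("preset occupation weights back-fill undeclared patient values", {
  ev <- packaged_value_evidence()
  pc <- load_preconfig(packaged("preconfig.csv"))
  preset <- preset_value_weights(pc, "Assembly line worker")
  p <- patient_record("breast cancer", occupation = "Assembly line worker")
  # patient declares nothing; 'pain' (0.86 preset) activates row 2
  res <- score_value(p, ev, preset = preset)
  expect_equal(unname(res$scores["Endocrine therapy"]), -2 * 0.86)
  # an explicit patient value overrides the preset
  p2 <- patient_record("breast cancer", occupation = "Assembly line worker",
                       values = c(pain = 0.5))
  res2 <- score_value(p2, ev, preset = preset)
  expect_equal(unname(res2$scores["Endocrine therapy"]), -2 * 0.5)
})

test_that("blending is the convex combination of the two channels", {
  expect_equal(blend(4, -2, 0), 4)
  expect_equal(blend(4, -2, 1), -2)
  expect_equal(blend(4, -2, 0.5), 1)
  expect_error(blend(1, 1, 1.3), "lambda")
  expect_error(blend(1, 1, -0.1), "lambda")
})

test_that("recommend matches the brute-force oracle on random instances", {
  set.seed(101)
  aliases <- NULL
  for (rep in 1:120) {
    ev <- random_evidence(sample(1:50, 1))
    p <- random_test_patient()
    lambda <- runif(1)
    mode <- sample(c("literal", "symmetric"), 1)
    rec <- recommend(p, ev, lambda = lambda, mode = mode)
    orc <- oracle_plan_scores(p, ev, mode = mode)
    for (i in seq_len(nrow(rec$ranked))) {
      plan <- rec$ranked$plan[i]
      expect_equal(rec$ranked$clinical_score[i], unname(orc$clinical[plan]))
      expect_equal(rec$ranked$value_score[i], unname(orc$value[plan]))
      expect_equal(rec$ranked$blended_score[i],
                   (1 - lambda) * unname(orc$clinical[plan]) +
                     lambda * unname(orc$value[plan]))
    }
    # ranking is a permutation of all mentioned plans, sorted by blend
    expect_setequal(rec$ranked$plan,
                    unique(vapply(ev, `[[`, character(1), "plan")))
    expect_true(all(diff(rec$ranked$blended_score) <= 1e-12))
  }
})

test_that("recommendations are invariant under evidence permutation", {
  set.seed(202)
  ev <- random_evidence(30)
  p <- random_test_patient()
  r1 <- recommend(p, ev, lambda = 0.4)
  r2 <- recommend(p, ev[sample.int(length(ev))], lambda = 0.4)
  expect_equal(r1$ranked, r2$ranked)
})

test_that("ties in blended score break lexicographically by plan name", {
  ev <- list(
    argument("a", "breast cancer", "-", "Zeta plan", "positive", 2, "clinical"),
    argument("b", "breast cancer", "-", "Alpha plan", "positive", 2, "clinical")
  )
  rec <- recommend(patient_record("breast cancer"), ev)
  expect_equal(rec$ranked$plan, c("Alpha plan", "Zeta plan"))
})

test_that("a null patient activates only wildcard clinical arguments", {
  set.seed(303)
  p <- patient_record("breast cancer")
  for (rep in 1:40) {
    ev <- random_evidence(20)
    rec <- recommend(p, ev, lambda = 0.5)
    wildcard_clinical <- Filter(function(a) {
      a$evidence_kind == "clinical" && length(a$condition$atoms) == 0
    }, ev)
    expect_setequal(rec$breakdown$argument_id,
                    vapply(wildcard_clinical, `[[`, character(1), "id"))
    expect_true(all(rec$ranked$value_score == 0))
  }
})

test_that("removing one argument shifts scores by exactly its contribution", {
  set.seed(404)
  for (rep in 1:25) {
    ev <- random_evidence(sample(5:30, 1))
    p <- random_test_patient()
    rec <- recommend(p, ev, lambda = 0.5)
    k <- sample(length(ev), 1)
    removed <- ev[[k]]
    contrib <- rec$breakdown$signed_contribution[
      rec$breakdown$argument_id == removed$id]
    contrib <- if (length(contrib)) contrib else 0
    rec2 <- recommend(p, ev[-k], lambda = 0.5)
    plan <- removed$plan
    before <- rec$ranked$clinical_score[rec$ranked$plan == plan] +
      rec$ranked$value_score[rec$ranked$plan == plan]
    after_row <- rec2$ranked[rec2$ranked$plan == plan, , drop = FALSE]
    after <- if (nrow(after_row)) {
      after_row$clinical_score + after_row$value_score
    } else 0
    expect_equal(before - after, contrib)
  }
})

test_that("blended scores are affine in lambda", {
  set.seed(505)
  ev <- random_evidence(30)
  p <- random_test_patient()
  lams <- c(0, 0.25, 0.5, 0.75, 1)
  recs <- lapply(lams, function(l) recommend(p, ev, lambda = l))
  plans <- recs[[1]]$ranked$plan
  for (plan in plans) {
    sc <- vapply(recs, function(r) {
      r$ranked$blended_score[r$ranked$plan == plan]
    }, numeric(1))
    c0 <- recs[[1]]$ranked$clinical_score[recs[[1]]$ranked$plan == plan]
    v1 <- recs[[5]]$ranked$value_score[recs[[5]]$ranked$plan == plan]
    expect_equal(sc, (1 - lams) * c0 + lams * v1)
  }
})

test_that("raising a value weight moves symmetric-mode scores monotonically", {
  ev <- packaged_value_evidence()
  # Endocrine therapy is opposed via 'pain' (row 2): raising the pain weight
  # must not increase its value score
  lo <- score_value(lisa_like(c(pain = 0.2)), ev, mode = "symmetric")
  hi <- score_value(lisa_like(c(pain = 0.9)), ev, mode = "symmetric")
  expect_lte(unname(hi$scores["Endocrine therapy"]),
             unname(lo$scores["Endocrine therapy"]))
  # Chemotherapy+GnRHa is only supported via 'family cost effective' (row 12)
  p_lo <- patient_record("breast cancer",
                         facts = list(age = 30, menopausal_status = "pre"),
                         values = c("family cost effective" = 0.3))
  p_hi <- patient_record("breast cancer",
                         facts = list(age = 30, menopausal_status = "pre"),
                         values = c("family cost effective" = 0.9))
  s_lo <- score_value(p_lo, ev, mode = "symmetric")
  s_hi <- score_value(p_hi, ev, mode = "symmetric")
  expect_gte(unname(s_hi$scores["Chemotherapy+GnRHa"]),
             unname(s_lo$scores["Chemotherapy+GnRHa"]))
})

test_that("empty evidence yields an empty ranking and a notice for foreign diseases", {
  p <- patient_record("breast cancer")
  rec <- recommend(p, list())
  expect_equal(nrow(rec$ranked), 0)
  ev <- list(argument("c", "lung cancer", "-", "Chemotherapy", "positive", 2,
                      "clinical"))
  expect_message(rec2 <- recommend(p, ev), "no evidence base")
  expect_true(all(rec2$ranked$blended_score == 0))
})

test_that("explanations are consistent with the scores and carry provenance", {
  ev <- packaged_value_evidence()
  p <- lisa_like()
  rec <- recommend(p, ev, lambda = 1)
  txt <- explain(rec)
  expect_true(any(grepl("no supporting or opposing evidence", txt)))
  expect_true(any(grepl("32104064/", txt)))  # row 1 provenance link
  # breakdown sums reproduce the per-plan channel scores
  for (plan in rec$ranked$plan) {
    acts <- rec$breakdown[rec$breakdown$plan == plan, , drop = FALSE]
    expect_equal(sum(acts$signed_contribution),
                 rec$ranked$clinical_score[rec$ranked$plan == plan] +
                   rec$ranked$value_score[rec$ranked$plan == plan])
  }
  # pure function of the recommendation
  expect_identical(txt, explain(rec))
})

test_that("alias vocabulary bridges evidence terms and patient declarations", {
  ev <- packaged_value_evidence()
  aliases <- load_value_aliases()
  # patient declares the taxonomy form 'pregnancy'; row 1 requires the
  # evidence surface 'pregnancy later'
  p <- patient_record("breast cancer",
                      facts = list(menopausal_status = "pre"),
                      values = c(pregnancy = 1.0))
  res <- score_value(p, ev, aliases = aliases)
  expect_equal(unname(res$scores["Endocrine therapy"]), 2)
  # without the alias map the argument cannot activate
  res0 <- score_value(p, ev)
  expect_equal(nrow(res0$activations), 0)
})

test_that("staged views subset the ranking by plan stage tags", {
  ev <- packaged_value_evidence()
  stages <- c("Endocrine therapy" = "post-surgery",
              "Chemotherapy" = "pre-surgery",
              "Radiotherapy" = "post-surgery")
  rec <- recommend(lisa_like(), ev, stages = stages)
  expect_named(rec$stage_view, c("pre-surgery", "surgery", "post-surgery"))
  expect_equal(rec$stage_view[["pre-surgery"]]$plan, "Chemotherapy")
  expect_true("Endocrine therapy" %in% rec$stage_view[["post-surgery"]]$plan)
  expect_equal(nrow(rec$stage_view[["surgery"]]), 0)
})
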