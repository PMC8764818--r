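test_that("the criterion catalog enumerates the 28 codes with prefix defaults", {
  cat <- criterion_catalog()
  expect_equal(nrow(cat), 28)
  expect_equal(anyDuplicated(cat$code), 0)
  expect_equal(sum(cat$direction == "pathogenic"), 16)
  expect_equal(sum(cat$direction == "benign"), 12)
  # defaults follow the code prefix
  expect_equal(cat$default_strength[cat$code == "PVS1"], "VeryStrong")
  expect_true(all(cat$default_strength[grepl("^PS", cat$code)] == "Strong"))
  expect_true(all(cat$default_strength[grepl("^PM", cat$code)] == "Moderate"))
  expect_true(all(cat$default_strength[grepl("^PP", cat$code)] == "Supporting"))
  expect_equal(cat$default_strength[cat$code == "BA1"], "StandAlone")
  expect_true(all(cat$default_strength[grepl("^BS", cat$code)] == "Strong"))
  expect_true(all(cat$default_strength[grepl("^BP", cat$code)] == "Supporting"))
  # every code maps to exactly one of the four criterion tabs
  expect_false(any(is.na(cat$tab)))
  expect_equal(cat$tab[cat$code == "PP1"], "CaseSegregation")
  expect_equal(cat$tab[cat$code == "PS3"], "Experimental")
  expect_equal(cat$tab[cat$code == "BA1"], "Population")
  expect_equal(cat$tab[cat$code == "PP3"], "VariantType")
  expect_true(all(nzchar(cat$description)))
})

test_that("allowed strengths match the pulldown rules per criterion", {
  # PP1 may be applied at Supporting (default), Moderate or Strong
  expect_setequal(allowed_strengths("PP1"), c("Strong", "Moderate", "Supporting", "VeryStrong"))
  expect_true(all(c("Supporting", "Moderate", "Strong") %in% allowed_strengths("PP1")))
  # BA1 is the stand-alone benign criterion, no other strength applies
  expect_equal(allowed_strengths("BA1"), "StandAlone")
  # other benign codes move between Strong and Supporting
  expect_setequal(allowed_strengths("BS3"), c("Strong", "Supporting"))
  expect_setequal(allowed_strengths("BP4"), c("Strong", "Supporting"))
  # pathogenic codes span VeryStrong..Supporting
  expect_true(all(c("VeryStrong", "Strong", "Moderate", "Supporting") %in%
                    allowed_strengths("PVS1")))
  expect_error(allowed_strengths("PX9"), class = "vc_UnknownCriterion")
})

test_that("allowed-strength table is overridable via a rule-set file", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "custom", allowed_strengths = list(
    PP1 = list("Supporting", "Moderate")
  )), cfg)
  rs <- load_ruleset(cfg)
  expect_equal(rs$name, "custom")
  expect_setequal(allowed_strengths("PP1", rs), c("Supporting", "Moderate"))
  expect_error(
    criterion_evaluation("PP1", "Met", strength = "Strong", ruleset = rs),
    class = "vc_StrengthNotAllowed"
  )
})

test_that("effective counts tally only Met evaluations at effective strength", {
  expect_equal(sum(effective_counts(list())$pathogenic), 0)
  expect_equal(sum(effective_counts(list())$benign), 0)

  evs <- list(
    PVS1 = unclass(criterion_evaluation("PVS1", "Met")),
    PS3 = unclass(criterion_evaluation("PS3", "Met")),
    PP3 = unclass(criterion_evaluation("PP3", "NotMet"))
  )
  tally <- effective_counts(evs)
  expect_equal(unname(tally$pathogenic["VeryStrong"]), 1L)
  expect_equal(unname(tally$pathogenic["Strong"]), 1L)
  expect_equal(unname(tally$pathogenic["Supporting"]), 0L)
  expect_equal(sum(tally$benign), 0L)

  # strength-modified counting: PP1 applied at Strong lands in the Strong tier
  evs2 <- list(
    PP1 = unclass(criterion_evaluation("PP1", "Met", strength = "Strong")),
    PM2 = unclass(criterion_evaluation("PM2", "Met"))
  )
  tally2 <- effective_counts(evs2)
  expect_equal(unname(tally2$pathogenic["Strong"]), 1L)
  expect_equal(unname(tally2$pathogenic["Moderate"]), 1L)
  expect_equal(unname(tally2$pathogenic["Supporting"]), 0L)
})

test_that("classification follows the default combining table on frozen cases", {
  classify <- function(...) compute_classification(strength_tally(...))
  expect_equal(classify()$category, "Uncertain significance")
  expect_false(classify()$conflict_flag)
  expect_equal(classify(ba = 1)$category, "Benign")
  expect_equal(classify(vs = 1, s = 1)$category, "Pathogenic")
  expect_equal(classify(vs = 1)$category, "Uncertain significance")
  expect_equal(classify(s = 1, m = 2)$category, "Likely pathogenic")
  expect_equal(classify(s = 2)$category, "Pathogenic")
  expect_equal(classify(m = 3)$category, "Likely pathogenic")
  expect_equal(classify(bs = 1, bp = 1)$category, "Likely benign")
  expect_equal(classify(bp = 2)$category, "Likely benign")
  # a second very-strong criterion satisfies the strong-tier requirement
  expect_equal(classify(vs = 2)$category, "Pathogenic")
  # both sides firing is contradictory evidence
  conflicted <- classify(s = 2, bs = 2)
  expect_equal(conflicted$category, "Uncertain significance")
  expect_true(conflicted$conflict_flag)
  # a lone strong pathogenic criterion fires no category, so it does not
  # contradict a benign call
  expect_equal(classify(s = 1, bs = 2)$category, "Benign")
  expect_false(classify(s = 1, bs = 2)$conflict_flag)
})

test_that("BA1 dominance switch resolves conflicts in favour of Benign", {
  rs <- default_ruleset(ba1_standalone_wins = TRUE)
  tally <- strength_tally(vs = 1, s = 1, ba = 1)
  expect_equal(compute_classification(tally)$category, "Uncertain significance")
  expect_true(compute_classification(tally)$conflict_flag)
  expect_equal(compute_classification(tally, rs)$category, "Benign")
  expect_false(compute_classification(tally, rs)$conflict_flag)
})

test_that("engine agrees with the brute-force table over a sampled grid", {
  set.seed(11)
  for (k in 1:200) {
    cnt <- sample(0:3, 7, replace = TRUE)
    got <- compute_classification(strength_tally(
      vs = cnt[1], s = cnt[2], m = cnt[3], p = cnt[4],
      ba = cnt[5], bs = cnt[6], bp = cnt[7]))
    want <- oracle_classify(cnt[1], cnt[2], cnt[3], cnt[4], cnt[5], cnt[6], cnt[7])
    expect_equal(got$category, want$category,
                 info = paste(cnt, collapse = ","))
    expect_equal(got$conflict_flag, want$conflict,
                 info = paste(cnt, collapse = ","))
  }
})

test_that("saving an evaluation recomputes the classification immediately", {
  set.seed(1)
  store <- local_store()
  rec <- make_record(store)
  expect_equal(rec$computed_classification, "Uncertain significance")

  rec <- evaluate(rec, "PS1", "Met", store = store)
  rec <- evaluate(rec, "PM1", "Met", store = store)
  rec <- evaluate(rec, "PM2", "Met", store = store)
  expect_equal(rec$computed_classification, "Likely pathogenic")

  # a Not Met evaluation contributes nothing
  before <- rec$computed_classification
  rec <- evaluate(rec, "PM5", "NotMet", store = store)
  expect_equal(rec$computed_classification, before)

  # strength modification at save time
  rec <- evaluate(rec, "PP1", "Met", strength = "Strong", store = store)
  tally <- effective_counts(rec$evaluations)
  expect_equal(unname(tally$pathogenic["Strong"]), 2L)
  expect_equal(rec$computed_classification, "Pathogenic")

  expect_error(evaluate(rec, "BA1", "Met", strength = "Strong", store = store),
               class = "vc_StrengthNotAllowed")
  expect_error(evaluate(rec, "XYZ", "Met", store = store),
               class = "vc_UnknownCriterion")
  stranger <- make_owner("user-Z")
  expect_error(evaluate(rec, "PM2", "Met", actor = stranger, store = store),
               class = "vc_NotOwner")
})

test_that("the criteria bar reports one display state per catalog code", {
  set.seed(2)
  store <- local_store()
  rec <- make_record(store)
  bar <- criteria_bar(rec)
  expect_equal(nrow(bar), 28)
  expect_true(all(bar$display_state == "NotEvaluated"))

  rec <- evaluate(rec, "PM2", "Met", store = store)
  rec <- evaluate(rec, "BP4", "NotMet", store = store)
  bar <- criteria_bar(rec)
  expect_equal(bar$display_state[bar$code == "PM2"], "Met")
  expect_equal(bar$display_state[bar$code == "BP4"], "NotMet")
  counts <- table(factor(bar$display_state,
                         levels = c("Met", "NotMet", "NotEvaluated")))
  expect_equal(sum(counts), 28)
  expect_equal(unname(counts["Met"]), 1)
  expect_equal(unname(counts["NotMet"]), 1)
})

test_that("manual override preserves the computed value and needs a rationale", {
  set.seed(3)
  store <- local_store()
  rec <- make_record(store)
  expect_error(override_classification(rec, "Likely pathogenic", "", store = store),
               class = "vc_EmptyRationale")
  rec <- override_classification(rec, "Likely pathogenic",
                                 "expert consensus on mechanism", store = store)
  expect_equal(asserted_classification(rec), "Likely pathogenic")
  expect_equal(rec$computed_classification, "Uncertain significance")
  # clearing restores asserted = computed
  rec <- override_classification(rec, NULL, store = store)
  expect_equal(asserted_classification(rec), "Uncertain significance")
})
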