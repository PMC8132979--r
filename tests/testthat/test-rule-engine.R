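toy_rules <- function(...) {
  compile_ruleset(dplyr::bind_rows(...))
}

rule_row <- function(rule_id, attribute, target_class, pattern, weight,
                     case_sensitive = FALSE) {
  tibble::tibble(
    rule_id = rule_id, attribute = attribute, target_class = target_class,
    pattern = pattern, weight = weight, case_sensitive = case_sensitive
  )
}

test_that("compile_ruleset validates patterns, ids, attributes and classes", {
  ok <- toy_rules(rule_row("r1", "hemorrhage", "present", "hemorrhage", 2))
  expect_s3_class(ok, "stroke_ruleset")
  expect_equal(nrow(ok), 1)

  expect_error(
    toy_rules(rule_row("bad", "hemorrhage", "present", "(", 2)),
    "does not compile.*bad|bad.*does not compile"
  )
  expect_error(
    toy_rules(
      rule_row("dup", "hemorrhage", "present", "a", 2),
      rule_row("dup", "hemorrhage", "present", "b", 1)
    ),
    "duplicate"
  )
  expect_error(
    toy_rules(rule_row("r", "stenosis", "present", "a", 2)),
    "unknown attribute"
  )
  expect_error(
    toy_rules(rule_row("r", "hemorrhage", "massive", "a", 2)),
    "not valid"
  )
  expect_error(
    toy_rules(rule_row("r", "hemorrhage", "present", "a", 0)),
    "nonzero"
  )
})

test_that("matching is sentence-scoped, capped at one match per rule-sentence pair", {
  rs <- toy_rules(
    rule_row("neg", "hemorrhage", "present", "no evidence of", -4),
    rule_row("occ", "lvo", "present", "occlusion", 2)
  )
  m1 <- match_rules(segment_sentences("There is no evidence of occlusion."), rs)
  expect_equal(sum(m1$rule_id == "neg"), 1)

  # three occurrences in one sentence still contribute exactly one match
  m2 <- match_rules(segment_sentences("Occlusion occlusion occlusion."), rs)
  expect_equal(nrow(m2[m2$rule_id == "occ", ]), 1)

  # but one match per sentence across sentences
  m3 <- match_rules(segment_sentences("Occlusion here. Occlusion there."), rs)
  expect_equal(nrow(m3[m3$rule_id == "occ", ]), 2)
})

test_that("case-sensitive rules ignore the lowercase homonym", {
  rs <- toy_rules(
    rule_row("aspect_cs", "ischemia", "present", "ASPECT", 2, case_sensitive = TRUE)
  )
  m <- match_rules(
    segment_sentences("the posterior aspect of the vessel is calcified"), rs
  )
  expect_equal(nrow(m), 0)
  m2 <- match_rules(segment_sentences("ASPECT score low"), rs)
  expect_equal(nrow(m2), 1)
})

test_that("signed weights sum and map through the logistic", {
  rs <- toy_rules(
    rule_row("pos", "hemorrhage", "present", "hematoma", 2),
    rule_row("neg", "hemorrhage", "present", "chronic", -4)
  )
  sch <- stroke_schema()

  b1 <- score_attribute(
    match_rules(segment_sentences("There is a hematoma."), rs), "hemorrhage"
  )
  expect_equal(b1$scores[["present"]], 2)
  expect_equal(b1$probability, 1 / (1 + exp(-2)))

  b2 <- score_attribute(
    match_rules(segment_sentences("There is a chronic hematoma."), rs), "hemorrhage"
  )
  expect_equal(b2$scores[["present"]], -2)
  expect_equal(b2$probability, 1 / (1 + exp(2)))

  b0 <- score_attribute(
    match_rules(segment_sentences("Unremarkable study."), rs), "hemorrhage"
  )
  expect_equal(b0$scores[["present"]], 0)
  expect_equal(b0$probability, 0.5)

  # p > 0.5 iff s > 0; logistic symmetry p(s) + p(-s) = 1
  for (s in c(-3, -1, -0.2, 0, 0.2, 1, 3)) {
    expect_equal(stats::plogis(s) + stats::plogis(-s), 1)
    expect_identical(stats::plogis(s) > 0.5, s > 0)
  }
})

test_that("classification thresholds and tie-breaks", {
  sch <- stroke_schema()
  expect_identical(classify_score(c(present = 3, absent = 0), sch$lvo), "present")
  expect_identical(classify_score(c(present = 0, absent = 0), sch$lvo), "absent")
  expect_identical(classify_score(c(present = -2, absent = 0), sch$lvo), "absent")
  # categorical: positive max wins; ties broken worst-first
  expect_identical(
    classify_score(
      c(not_reported = 0, poor = 2, intermediate = 0, good = 2),
      sch$collaterals
    ),
    "poor"
  )
  expect_identical(
    classify_score(
      c(not_reported = 0, poor = 1, intermediate = 0, good = 2),
      sch$collaterals
    ),
    "good"
  )
  expect_identical(
    classify_score(
      c(not_reported = 0, poor = 0, intermediate = 0, good = 0),
      sch$collaterals
    ),
    "not_reported"
  )
})

test_that("ASPECTS extraction bands values, guards range and homonym", {
  cases <- list(
    list("ASPECTS is 8.", "ge5", 8L),
    list("ASPECTS of 3 with large MCA territory infarct.", "lt5", 3L),
    list("Calcification along the lateral aspect of the cavernous carotid.", "not_reported", NA_integer_),
    list("ASPECTS 12", "not_reported", NA_integer_),
    list("ASPECT score 4.", "lt5", 4L),
    list("aspect score of 9 on the initial study.", "ge5", 9L),
    list("ASPECTS 0.", "lt5", 0L),
    list("", "not_reported", NA_integer_)
  )
  for (cs in cases) {
    res <- extract_aspects(segment_sentences(cs[[1]]))
    expect_identical(res$class, cs[[2]], label = cs[[1]])
    expect_identical(res$value, cs[[3]], label = cs[[1]])
  }
  # first valid mention in document order wins
  res <- extract_aspects(segment_sentences("ASPECTS is 3. Repeat ASPECTS is 9."))
  expect_identical(res$value, 3L)
  # an out-of-range mention is skipped in favor of a later valid one
  res2 <- extract_aspects(segment_sentences("ASPECTS 99 was a typo. ASPECTS is 6."))
  expect_identical(res2$value, 6L)
})

test_that("predict_report: empty text defaults everywhere", {
  p <- predict_report(list(id = "r0", text = ""))
  for (a in binary_attrs) expect_identical(p[[a]], "absent")
  expect_identical(p$aspects, "not_reported")
  expect_identical(p$collaterals, "not_reported")
})

test_that("documented proximal-occlusion behaviors of the default rules", {
  # M1 wording alone suffices, even without "MCA"/"middle cerebral artery"
  p1 <- predict_report(list(id = "a", text = "Occlusion of the M1 segment."))
  expect_identical(p1$lvo, "present")
  # ICA-to-M2 extension is missed: keywords only, no vascular anatomy model
  p2 <- predict_report(list(
    id = "b",
    text = "There is an occlusion extending from the internal carotid artery to the M2 segment."
  ))
  expect_identical(p2$lvo, "absent")
  expect_identical(p2$distal_occlusion, "present")
})

test_that("score additivity and positive-rule monotonicity across sentences", {
  rs <- default_rules()
  sch <- stroke_schema()
  s1 <- "Acute intraparenchymal hemorrhage in the left basal ganglia."
  s2 <- "There is a small subdural haematoma along the right convexity."
  per_sentence <- vapply(c(s1, s2), function(txt) {
    score_attribute(match_rules(segment_sentences(txt), rs), "hemorrhage")$scores[["present"]]
  }, numeric(1))
  joint <- score_attribute(
    match_rules(segment_sentences(paste(s1, s2)), rs), "hemorrhage"
  )$scores[["present"]]
  expect_equal(joint, sum(per_sentence))

  # appending a sentence matching only positive-weight hemorrhage rules never
  # lowers the hemorrhage score nor disturbs other attributes
  base <- "Occlusion of the left M1 segment."
  for (at in names(sch)[names(sch) != "aspects"]) {
    b0 <- score_attribute(match_rules(segment_sentences(base), rs), at)$scores
    b1 <- score_attribute(match_rules(segment_sentences(paste(base, s1)), rs), at)$scores
    if (at == "hemorrhage") {
      expect_gte(b1[["present"]], b0[["present"]])
    } else {
      expect_equal(b1, b0)
    }
  }
})

test_that("evidence split across sentences produces no joint match", {
  rs <- default_rules()
  one_sentence <- "Occlusion involving the M1 segment."
  two_sentences <- "There is an occlusion. The M1 segment is noted."
  p1 <- predict_report(list(id = "x", text = one_sentence), rs)
  p2 <- predict_report(list(id = "y", text = two_sentences), rs)
  expect_identical(p1$lvo, "present")
  expect_identical(p2$lvo, "absent")
})

test_that("prediction is deterministic and corpus order is preserved", {
  corpus <- tibble::tibble(
    id = c("r2", "r1"),
    text = c("Occlusion of the right M1 segment.", "No evidence of hemorrhage.")
  )
  p1 <- predict_corpus(corpus)
  p2 <- predict_corpus(corpus)
  expect_identical(p1[names(p1) != "trace"], p2[names(p2) != "trace"])
  expect_identical(p1$id, c("r2", "r1"))
  expect_error(
    predict_corpus(tibble::tibble(id = c("a", "a"), text = c("x", "y"))),
    "duplicate"
  )
})
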