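test_that("confusion counts a hand-enumerable example and degenerate cases", {
  cm <- confusion(
    c("present", "present", "absent", "absent"),
    c("present", "absent", "absent", "present")
  )
  expect_equal(unlist(cm[1, c("tp", "fn", "tn", "fp")]), c(tp = 1, fn = 1, tn = 1, fp = 1))

  gold <- sample(c("present", "absent"), 20, replace = TRUE)
  cm2 <- confusion(gold, gold)
  expect_equal(cm2$fp + cm2$fn, 0)

  cm3 <- confusion(rep("absent", 10), rep("absent", 10))
  expect_equal(unlist(cm3[1, ]), c(tp = 0, fp = 0, tn = 10, fn = 0))

  expect_error(confusion(c("a", "b"), "a"), "length")
})

test_that("binary metrics recompute a validation-style confusion matrix", {
  # 399 reports, 50 positive: tp=45 fn=5 tn=340 fp=9
  lab <- labels_from_counts(tp = 45, fp = 9, tn = 340, fn = 5)
  met <- binary_metrics(confusion(lab$gold, lab$pred))
  orc <- oracle_binary(lab$gold, lab$pred)
  expect_equal(met$sensitivity, orc$sensitivity)
  expect_equal(met$specificity, orc$specificity)
  expect_equal(met$ppv, orc$ppv)
  expect_equal(met$npv, orc$npv)
  expect_equal(met$accuracy, orc$accuracy)
  # presentation rounding reproduces the table style
  fm <- format_metrics(met)
  expect_equal(fm$sensitivity, 90.0)
  expect_equal(fm$specificity, 97.4)
  expect_equal(fm$ppv, 83.3)
  expect_equal(fm$npv, 98.6)
  expect_equal(fm$accuracy, 96.5)
})

test_that("zero denominators yield NA, never an exception or a coerced 0/100", {
  lab <- labels_from_counts(tp = 0, fp = 0, tn = 10, fn = 0)
  met <- binary_metrics(confusion(lab$gold, lab$pred))
  expect_true(is.na(met$sensitivity))
  expect_true(is.na(met$ppv))
  expect_equal(met$specificity, 100)
  expect_equal(met$accuracy, 100)
  expect_error(binary_metrics(tibble::tibble(tp = 0, fp = 0, tn = 0, fn = 0)), "empty")

  perfect <- binary_metrics(confusion(
    rep(c("present", "absent"), 5), rep(c("present", "absent"), 5)
  ))
  expect_true(all(unlist(perfect[c(
    "sensitivity", "specificity", "ppv", "npv", "accuracy"
  )]) == 100))
})

test_that("binary metrics agree with the brute-force oracle on random pairs", {
  withr::with_seed(101, {
    for (i in 1:200) {
      lab <- random_label_pairs(sample(2:60, 1))
      met <- binary_metrics(confusion(lab$gold, lab$pred))
      orc <- oracle_binary(lab$gold, lab$pred)
      for (f in c("tp", "fp", "tn", "fn", "sensitivity", "specificity", "ppv", "npv", "accuracy")) {
        expect_equal(met[[f]], orc[[f]], label = f)
      }
    }
  })
})

test_that("accuracy equals sens*prev + spec*(1-prev) whenever defined", {
  withr::with_seed(77, {
    for (i in 1:100) {
      lab <- random_label_pairs(sample(5:80, 1))
      met <- binary_metrics(confusion(lab$gold, lab$pred))
      if (is.na(met$sensitivity) || is.na(met$specificity)) next
      prev <- mean(lab$gold == "present")
      expect_equal(met$accuracy, met$sensitivity * prev + met$specificity * (1 - prev))
    }
  })
})

test_that("categorical metrics: one-vs-rest equals relabel-then-confusion", {
  classes <- c("not_reported", "lt5", "ge5")
  withr::with_seed(55, {
    for (i in 1:50) {
      n <- sample(3:50, 1)
      gold <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
      cm <- categorical_metrics(gold, pred, classes)
      for (cl in classes) {
        g2 <- ifelse(gold == cl, "pos", "rest")
        p2 <- ifelse(pred == cl, "pos", "rest")
        orc <- oracle_binary(g2, p2, "pos")
        row <- cm[cm$class == cl, ]
        expect_equal(row$tp, orc$tp)
        expect_equal(row$sensitivity, orc$sensitivity)
        expect_equal(row$ppv, orc$ppv)
      }
      expect_equal(attr(cm, "overall_accuracy"), 100 * sum(gold == pred) / n)
    }
  })
})

test_that("categorical overall accuracy: exact-match fraction, relabel-invariant", {
  cm <- categorical_metrics(c("a", "b", "c"), c("a", "b", "b"), c("a", "b", "c"))
  expect_equal(attr(cm, "overall_accuracy"), 100 * 2 / 3)
  perfect <- categorical_metrics(c("a", "b", "c"), c("a", "b", "c"), c("a", "b", "c"))
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]) == 100))
  expect_equal(attr(perfect, "overall_accuracy"), 100)
  # relabeling both vectors leaves overall accuracy unchanged
  relab <- c(a = "x", b = "y", c = "z")
  cm2 <- categorical_metrics(
    relab[c("a", "b", "c")], relab[c("a", "b", "b")], c("x", "y", "z")
  )
  expect_equal(attr(cm2, "overall_accuracy"), attr(cm, "overall_accuracy"))
})

test_that("prevalence reproduces printed count/percent pairs", {
  p <- prevalence(rep(c("present", "absent"), c(161, 1320 - 161)))
  expect_equal(p$count, 161)
  expect_equal(p$percent, 12.2)
  p2 <- prevalence(rep(c("present", "absent"), c(384, 1320 - 384)))
  expect_equal(p2$percent, 29.1)
  p0 <- prevalence(rep("absent", 10))
  expect_equal(unlist(p0), c(count = 0, percent = 0))
})

test_that("percent agreement: symmetric exact-match percentage", {
  a <- c("P", "A", "A", "A", "A")
  b <- c("A", "A", "A", "A", "A")
  expect_equal(percent_agreement(a, b), 80)
  expect_equal(percent_agreement(a, a), 100)
  expect_equal(percent_agreement(a, b), percent_agreement(b, a))
  expect_error(percent_agreement(a, b[1:3]), "length")
})

test_that("split_corpus: exact sizes, disjoint, exhaustive, seed-deterministic", {
  corpus <- tibble::tibble(id = sprintf("r%04d", 1:1320), text = "")
  sp <- split_corpus(corpus, 921 / 1320, seed = 8)
  expect_equal(nrow(sp$train), 921)
  expect_equal(nrow(sp$validation), 399)
  expect_length(intersect(sp$train$id, sp$validation$id), 0)
  expect_setequal(c(sp$train$id, sp$validation$id), corpus$id)

  sp2 <- split_corpus(corpus, 921 / 1320, seed = 8)
  expect_identical(sp, sp2)

  partitions <- vapply(1:10, function(s) {
    paste(split_corpus(corpus, 921 / 1320, seed = s)$train$id, collapse = ",")
  }, character(1))
  expect_gte(length(unique(partitions)), 9)

  expect_error(split_corpus(corpus, 1.2, 1), "between 0 and 1")
})

test_that("discrepancy report lists each mismatch with its rule trace", {
  corpus <- generate_corpus(sim_config(n_reports = 120, seed = 23))
  pred <- predict_corpus(corpus)
  expect_equal(nrow(discrepancy_report(corpus, pred)), 0)

  fx <- stroke_fixtures()
  fcorp <- tibble::tibble(id = fx$fixture_id, text = fx$text)
  sch <- stroke_schema()
  for (at in names(sch)) fcorp[[at]] <- vapply(fx$gold, `[[`, character(1), at)
  fpred <- predict_corpus(fcorp)
  d <- discrepancy_report(fcorp, fpred)
  # record count equals the sum of per-attribute fp+fn
  total <- 0
  for (at in names(sch)) {
    if (sch[[at]]$kind == "binary") {
      cmx <- confusion(fcorp[[at]], fpred[[at]])
      total <- total + cmx$fp + cmx$fn
    } else {
      total <- total + sum(fcorp[[at]] != fpred[[at]])
    }
  }
  expect_equal(nrow(d), total)
  expect_true(all(d$gold != d$predicted))
  expect_true(all(d$resolution == "unresolved"))
  # the same-sentence false positive names the proximal-occlusion rule
  cav <- d[d$report_id == "cavernous_reconstitution" & d$attribute == "lvo", ]
  expect_equal(nrow(cav), 1)
  expect_true("lvo_proximal_occlusion" %in% cav$trace[[1]]$rule_id)
})

test_that("evaluate_predictions wires metrics, tidy, glance and errors", {
  corpus <- generate_corpus(sim_config(n_reports = 80, seed = 31))
  pred <- predict_corpus(corpus)
  ev <- evaluate_predictions(corpus, pred, cohort = "derivation")
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c(
    "cohort", "attribute", "class", "prevalence_n", "prevalence_pct",
    "sensitivity", "specificity", "ppv", "npv", "accuracy"
  ))
  expect_equal(unique(td$cohort), "derivation")
  # 5 binary rows + (3 aspects + 1 overall) + (4 collaterals + 1 overall)
  expect_equal(nrow(td), 5 + 4 + 5)
  gl <- glance(ev)
  expect_equal(gl$n, 80)
  expect_equal(gl$n_discrepancies, 0)

  unlabeled <- corpus[, c("id", "text")]
  expect_error(evaluate_predictions(unlabeled, pred), "no gold labels")
})
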