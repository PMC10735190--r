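test_that("the five designs produce the documented splits on the reference cohort", {
  man <- reference_manifest()
  e1 <- make_design("E1", man)
  expect_length(e1$train_subject_ids, 20L)
  expect_length(e1$test_subject_ids, 16L)
  expect_length(intersect(e1$train_subject_ids, e1$test_subject_ids), 0L)

  e3 <- make_design("E3", man)
  expect_length(e3$train_subject_ids, 10L)
  expect_length(e3$test_subject_ids, 26L)
  expect_true(all(man$X[man$subject_id %in% e3$train_subject_ids] <= 10))
  expect_length(intersect(e3$train_subject_ids, e3$test_subject_ids), 0L)

  e4 <- make_design("E4", man)
  expect_length(e4$train_subject_ids, 10L)
  expect_length(e4$test_subject_ids, 16L)
  # ascending-X construction: train ("Average_GOOD") max below test min
  xtr <- man$X[man$subject_id %in% e4$train_subject_ids]
  xte <- man$X[man$subject_id %in% e4$test_subject_ids]
  expect_true(all(xtr > 10))
  expect_lte(max(xtr), min(xte))

  e5 <- make_design("E5", man)
  expect_length(e5$train_subject_ids, 18L)
  expect_length(e5$test_subject_ids, 36L)
  expect_false(e5$disjoint)   # deliberately non-disjoint, like E2
  expect_false(make_design("E2", man)$disjoint)
  expect_true(all(make_design("E2", man)$train_subject_ids %in%
                    make_design("E2", man)$test_subject_ids))

  expect_error(make_design("E9", man), "unknown design")
})

test_that("run_experiment trains on both conditions and labels every test subject", {
  ft <- toy_feature_table()
  man <- toy_manifest()
  des <- make_design("E3", man)
  tab <- run_experiment(des, ft, man)
  expect_identical(tab$subject_id, des$test_subject_ids)
  expect_true(all(tab$comment %in%
                    c("correct", "Reversed", "Both_as_class_1", "Both_as_class_2")))
  # easy margin: everything correct
  expect_true(all(tab$comment == "correct"))
  # deterministic rerun
  expect_identical(tab, run_experiment(des, ft, man))
})

test_that("an empty test set gives an empty prediction table", {
  ft <- toy_feature_table()
  man <- toy_manifest()
  des <- make_design("E1", man)
  des$test_subject_ids <- character(0)
  tab <- run_experiment(des, ft, man)
  expect_equal(nrow(tab), 0L)
  expect_identical(names(tab), c("subject_id", "X", "group",
                                 "pred_rest", "pred_task", "comment"))
})

test_that("labeled-set construction enforces one rest and one task per subject", {
  ft <- toy_feature_table()
  man <- toy_manifest()
  des <- make_design("E3", man)
  expect_error(run_experiment(des, ft[ft$condition == "rest", ], man),
               "exactly one rest and one task")
  expect_error(run_experiment(des, ft[ft$subject_id != "T01", ], man),
               "T01")
})

test_that("order_sweep matches run_experiment and is reproducible", {
  ft <- toy_feature_table()
  man <- toy_manifest()
  des <- make_design("E5", man)
  sw <- order_sweep(ft, des, man, orders = 4L)
  ev <- evaluate_prediction_table(run_experiment(des, ft, man, order = 4L))
  expect_equal(sw$overall_accuracy, ev$overall_accuracy)

  sw2 <- order_sweep(ft, des, man, orders = 1:3)
  expect_true(all(sw2$overall_accuracy >= 0 & sw2$overall_accuracy <= 100))
  expect_identical(sw2, order_sweep(ft, des, man, orders = 1:3))
  expect_error(order_sweep(ft, des, man, orders = integer(0)), "at least one")
})

test_that("baseline comparison reports the five standard classifiers", {
  ft <- toy_feature_table(margin = 6)
  man <- toy_manifest()
  des <- make_design("E1", man)
  des$train_subject_ids <- man$subject_id[1:5]
  des$test_subject_ids <- man$subject_id[6:8]
  tab <- baseline_comparison(des, ft, man)
  expect_identical(tab$classifier, c("LDA", "SVM", "kNN", "Tree", "NaiveBayes"))
  expect_true(all(tab$overall_accuracy >= 90))
  expect_identical(tab, baseline_comparison(des, ft, man))
})
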