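test_that("stratified splits are disjoint, exhaustive and seeded", {
  ms <- small_fixture()
  sp <- stratified_split(ms, test_fraction = 0.2, seed = 4)
  expect_equal(length(sp$train) + length(sp$test), length(ms))
  expect_length(intersect(sp$train$records$mol_id, sp$test$records$mol_id), 0L)
  expect_true(all(sp$test$records$set_tag == "test"))
  sp2 <- stratified_split(ms, test_fraction = 0.2, seed = 4)
  expect_identical(sp$test$records$mol_id, sp2$test$records$mol_id)
  # class balance is preserved within a tolerance of a couple of points
  p_all <- mean(ms$records$ames_label == "mutagen")
  p_test <- mean(sp$test$records$ames_label == "mutagen")
  expect_lt(abs(p_all - p_test), 0.06)
  # overall test share is near the target
  expect_lt(abs(length(sp$test) / length(ms) - 0.2), 0.05)
})

test_that("alert-profile stratification keys are accepted", {
  ms <- small_fixture()
  sp <- stratified_split(ms, 0.25, seed = 9, rulebase = default_rulebase())
  expect_equal(length(sp$train) + length(sp$test), length(ms))
  expect_lt(abs(length(sp$test) / length(ms) - 0.25), 0.08)
})

test_that("confusion3 tallies counts and tracks unpredicted separately", {
  cm <- confusion3(c("mutagen", "nonmutagen"),
                   c("mutagenic", "suspicious"))
  expect_equal(cm$counts["mutagen", "mutagenic"], 1L)
  expect_equal(cm$counts["nonmutagen", "suspicious"], 1L)
  expect_equal(sum(cm$counts), 2L)

  truths <- rep(c("mutagen", "nonmutagen"), each = 5)
  preds <- c(rep("mutagenic", 4), "unpredicted",
             rep("nonmutagenic", 4), "suspicious")
  cm2 <- confusion3(truths, preds)
  expect_equal(sum(cm2$counts) + sum(cm2$unpredicted), length(truths))
  expect_equal(unname(cm2$unpredicted["mutagen"]), 1L)
  expect_error(confusion3(c("mutagen", "weird"), rep("mutagenic", 2)),
               "true labels")
  expect_error(confusion3("mutagen", "positive"), "prediction")
})

test_that("policy statistics fold the suspicious column correctly", {
  cm <- confusion3_from_counts(mutagen = c(10, 2, 3),
                               nonmutagen = c(4, 20, 1))
  sa <- stats_under_policy(cm, "max_accuracy")
  expect_equal(c(sa$tp, sa$fn, sa$tn, sa$fp), c(10L, 5L, 21L, 4L))
  expect_equal(sa$accuracy, 31 / 40)
  sm <- stats_under_policy(cm, "min_fn")
  expect_equal(c(sm$tp, sm$fn, sm$tn, sm$fp), c(13L, 2L, 20L, 5L))
  expect_equal(sm$sensitivity, 13 / 15)
  expect_equal(sm$fn_rate, 1 - sm$sensitivity)
  # a perfect matrix gives all-ones statistics
  perf <- stats_under_policy(confusion3_from_counts(c(7, 0, 0), c(0, 9, 0)))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
})

test_that("folding suspicious into positives helps sensitivity, hurts specificity", {
  set.seed(8)
  for (i in 1:25) {
    cm <- confusion3_from_counts(sample(0:30, 3, TRUE), sample(0:30, 3, TRUE))
    if (sum(cm$counts["mutagen", ]) == 0 || sum(cm$counts["nonmutagen", ]) == 0)
      next
    sa <- stats_under_policy(cm, "max_accuracy")
    sm <- stats_under_policy(cm, "min_fn")
    expect_gte(sm$sensitivity, sa$sensitivity)
    expect_lte(sm$specificity, sa$specificity)
  }
})

test_that("empty classes yield NaN statistics, never silent zeroes", {
  cm <- confusion3_from_counts(c(0, 0, 0), c(1, 5, 0))
  s <- stats_under_policy(cm)
  expect_true(is.nan(s$sensitivity))
  expect_true(is.nan(s$fn_rate))
  expect_false(is.nan(s$specificity))
})

test_that("fn_reduction compares like with like", {
  ref <- stats_under_policy(confusion3_from_counts(c(391, 74, 0),
                                                   c(83, 289, 0)))
  casc <- stats_under_policy(confusion3_from_counts(c(403, 48, 14),
                                                    c(88, 268, 16)), "min_fn")
  expect_equal(fn_reduction(ref, casc), (74 - 48) / 74)
  expect_equal(fn_reduction(ref, ref), 0)
  perfect <- stats_under_policy(confusion3_from_counts(c(5, 0, 0), c(0, 5, 0)))
  expect_true(is.nan(fn_reduction(perfect, perfect)))
})

test_that("evaluate_cascade packages matrices, stats and reductions", {
  ev <- evaluate_cascade(small_fit(), small_fixture())
  expect_s3_class(ev, "cascade_evaluation")
  expect_equal(sum(ev$confusion$counts) + sum(ev$confusion$unpredicted),
               length(small_fixture()))
  expect_true(all(c("max_accuracy", "min_fn", "svm") %in% names(ev$stats)))
  expect_output(print(ev), "FN reduction")
  js <- cascade_evaluation_json(ev)
  rt <- jsonlite::fromJSON(jsonlite::toJSON(js, auto_unbox = TRUE, digits = NA))
  expect_equal(rt$stats$min_fn$tp, ev$stats$min_fn$tp)
})
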