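test_that("a fitted cascade carries every component of the pipeline", {
  fit <- small_fit()
  expect_s3_class(fit, "ames_cascade")
  expect_equal(fit$C, 8)
  expect_equal(fit$gamma, 16)
  expect_length(fit$scaling, 25L)
  expect_equal(length(fit$descriptor_order), 25L)
  expect_s3_class(fit$rulebase, "alert_rulebase")
  expect_equal(nrow(fit$audits), 30L)
  expect_true(fit$cv_accuracy > 0.5)
  expect_output(print(fit), "C-SVC/RBF")
  expect_output(summary(fit), "Rule audit")
})

test_that("prediction labels, stages and fired alerts are mutually consistent", {
  fit <- small_fit()
  pred <- predict(fit, small_fixture())
  expect_equal(nrow(pred), length(small_fixture()))
  expect_true(all(pred$label %in% c("mutagenic", "suspicious",
                                    "nonmutagenic", "unpredicted")))
  # label <-> stage correspondence
  expect_true(all(pred$stage[pred$label == "mutagenic"] %in%
                    c("svm", "checkpoint1")))
  expect_true(all(pred$stage[pred$label == "suspicious"] == "checkpoint2"))
  expect_true(all(pred$stage[pred$label == "nonmutagenic"] == "passthrough"))
  expect_true(all(pred$stage[pred$label == "unpredicted"] == "failed"))
  # alerts are only reported at the checkpoints
  expect_true(all(pred$fired_alerts[pred$stage %in%
                                      c("svm", "passthrough")] == ""))
  expect_true(all(pred$fired_alerts[pred$stage %in%
                                      c("checkpoint1", "checkpoint2")] != ""))
})

test_that("an SVM-positive compound never reaches the checkpoints", {
  fit <- small_fit()
  pred <- predict(fit, small_fixture())
  pred_svm <- predict(fit, small_fixture(), use_alerts = FALSE)
  svm_pos <- pred_svm$label == "mutagenic"
  expect_true(all(pred$stage[svm_pos] == "svm"))
})

test_that("emptying the alert partition reduces the cascade to the bare SVM", {
  fit <- small_fit()
  fit_bare <- fit
  fit_bare$rulebase <- set_partition(fit$rulebase)
  p1 <- predict(fit_bare, small_fixture())
  p2 <- predict(fit, small_fixture(), use_alerts = FALSE)
  expect_identical(p1$label, p2$label)
  expect_true(all(p1$stage %in% c("svm", "passthrough", "failed")))
})

test_that("checkpoints only move compounds towards the mutagen side", {
  fit <- small_fit()
  ms <- small_fixture()
  truth <- ms$records$ames_label
  pred <- predict(fit, ms)
  bare <- predict(fit, ms, use_alerts = FALSE)
  fn_of <- function(labels, pol) {
    sum(truth == "mutagen" & binarize_labels(labels, pol) == "nonmutagen")
  }
  fp_of <- function(labels, pol) {
    sum(truth == "nonmutagen" & binarize_labels(labels, pol) == "mutagen")
  }
  # FNs: min_fn <= max_accuracy <= bare SVM; FPs reversed
  expect_lte(fn_of(pred$label, "min_fn"), fn_of(pred$label, "max_accuracy"))
  expect_lte(fn_of(pred$label, "max_accuracy"), fn_of(bare$label, "max_accuracy"))
  expect_gte(fp_of(pred$label, "min_fn"), fp_of(pred$label, "max_accuracy"))
  expect_gte(fp_of(pred$label, "max_accuracy"), fp_of(bare$label, "max_accuracy"))
})

test_that("the suspicious label binarizes according to the chosen policy", {
  expect_equal(binarize_labels("suspicious", policy("max_accuracy")),
               "nonmutagen")
  expect_equal(binarize_labels("suspicious", policy("min_fn")), "mutagen")
  expect_equal(binarize_labels(c("mutagenic", "nonmutagenic", "unpredicted"),
                               policy("min_fn")),
               c("mutagen", "nonmutagen", "unpredicted"))
  fit <- small_fit()
  pred <- predict(fit, small_fixture()[1:5], policy = "min_fn")
  expect_true("binary_min_fn" %in% names(pred))
})

test_that("unparseable structures surface as unpredicted, never guessed", {
  fit <- small_fit()
  pred <- predict(fit, c("CCO", "this_is_not_a_molecule", "c1ccccc1"))
  expect_equal(nrow(pred), 3L)
  expect_equal(pred$label[2], "unpredicted")
  expect_equal(pred$stage[2], "failed")
  expect_true(all(pred$label[-2] != "unpredicted"))
})

test_that("model bundles round-trip through disk with identical predictions", {
  fit <- small_fit()
  tf <- tempfile(fileext = ".rds")
  save_cascade(fit, tf)
  back <- load_cascade(tf)
  sub <- small_fixture()[1:20]
  expect_identical(predict(back, sub), predict(fit, sub))
  expect_equal(back$version, fit$version)
  expect_error(load_cascade(tempfile()), "no model bundle")
})

test_that("a cascade can be trained from a precomputed descriptor table", {
  ms <- small_fixture()
  desc <- compute_descriptors(ms)
  fit <- ames_cascade(desc, labels = ms$records$ames_label, seed = 101)
  expect_null(fit$rulebase)
  pred <- predict(fit, desc)
  expect_true(all(pred$label %in% c("mutagenic", "nonmutagenic")))
  expect_gt(mean((pred$label == "mutagenic") ==
                   (ms$records$ames_label == "mutagen")), 0.8)
  expect_error(ames_cascade(desc), "labels")
})

test_that("tuning picks grid points and records the calibration", {
  ms <- small_fixture()[1:60]
  fit <- ames_cascade(ms, tune = TRUE, C_grid = c(1, 8), gamma_grid = c(4, 16),
                      folds = 3, seed = 5, select_rules = FALSE)
  expect_true(fit$C %in% c(1, 8))
  expect_true(fit$gamma %in% c(4, 16))
  expect_false(is.null(fit$tuning))
})
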