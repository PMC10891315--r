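# Balanced subsampling, LOOCV, confusion matrices, the metric suite,
# AUC, and the classifier registry.

test_that("balanced subsampling returns exactly n per group, reproducibly", {
  set.seed(1)
  fm <- make_fm(n_per_group = 50)
  sub <- subsample_balanced(fm, 50, seed = 3)
  expect_identical(sub, fm)  # groups of exactly 50: identity selection

  fm2 <- rbind(make_fm(27), make_fm(3))  # 77/53/79 is checked end-to-end
  fm2$participant_id <- sprintf("P%03d", seq_len(nrow(fm2)))
  s1 <- subsample_balanced(fm2, 20, seed = 5)
  s2 <- subsample_balanced(fm2, 20, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(table(s1$group) == 20))
  expect_error(subsample_balanced(fm, 60, seed = 1),
               class = "sptask_error_insufficient_group")
})

test_that("LOOCV separates well-separated clouds and stays at chance when permuted", {
  set.seed(10)
  x <- rbind(matrix(rnorm(50 * 10, 0), 50), matrix(rnorm(50 * 10, 6), 50))
  y <- rep(c("A", "B"), each = 50)
  cv <- loocv_predict(x, y, "svm")
  expect_gte(mean(cv$predicted == y), 0.95)

  # permuted labels must never beat chance (no leakage); LOOCV with
  # exactly balanced classes can fall *below* chance (the held-out
  # sample's class is always the training-fold minority), so the
  # chance bound is one-sided
  se3 <- 3 * sqrt(0.25 / 100)
  for (i in 1:3) {
    yp <- sample(y)
    acc_null <- mean(loocv_predict(x, yp, "svm")$predicted == yp)
    expect_lt(acc_null, 0.5 + se3)
  }
})

test_that("the smallest legal LOOCV input runs, flagging its degenerate folds", {
  x <- matrix(c(0, 0.1, 5), ncol = 1)
  expect_warning(
    cv <- loocv_predict(x, c("A", "A", "B"), "svm"),
    class = "sptask_warning_degenerate_fold")
  expect_length(cv$predicted, 3L)
})

test_that("fold standardization uses training-fold statistics, not full-data ones", {
  # one extreme row: its fold mean (computed without it) must differ from
  # the full-data mean, or the held-out row would be leaking into scaling
  x <- matrix(c(rep(0, 4), rep(1, 4), 1000), ncol = 1)
  y <- c(rep("A", 4), rep("B", 5))
  cv <- loocv_predict(x, y, "svm", return_fold_stats = TRUE)
  full_mean <- mean(x)
  expect_false(isTRUE(all.equal(cv$fold_means[9, 1], full_mean)))
  expect_equal(cv$fold_means[9, 1], mean(x[1:8, 1]))
})

test_that("confusion matrices count correctly and reject foreign labels", {
  truth <- rep(c("MDD", "HC"), c(50, 50))
  pred <- c(rep("MDD", 37), rep("HC", 13), rep("MDD", 9), rep("HC", 41))
  cm <- confusion(truth, pred, classes = c("MDD", "HC"))
  expect_identical(unclass(cm)[, ],
                   matrix(c(37L, 13L, 9L, 41L), 2, byrow = TRUE,
                          dimnames = list(true = c("MDD", "HC"),
                                          predicted = c("MDD", "HC")))[, ])
  perfect <- confusion(truth, truth, c("MDD", "HC"))
  expect_true(all(perfect == diag(c(50L, 50L))))
  expect_error(confusion(character(), character()),
               class = "sptask_error_insufficient_data")
  expect_error(confusion(c("A", "B"), c("A", "X"), c("A", "B")),
               class = "sptask_error_unknown_label")
})

test_that("binary metrics follow their definitions, including the degenerate rule", {
  cm <- reference_confusions()$mdd_hc
  rep <- report_binary(cm, positive = "MDD")
  m <- rep$metrics
  expect_equal(unname(m["sensitivity"]), 37 / 50)
  expect_equal(unname(m["specificity"]), 41 / 50)
  expect_equal(unname(m["accuracy"]), 78 / 100)
  expect_equal(unname(m["precision"]), 37 / 46)
  expect_equal(unname(m["f1"]),
               2 * (37 / 46) * (37 / 50) / (37 / 46 + 37 / 50))

  ideal <- confusion(rep(c("A", "B"), each = 50), rep(c("A", "B"), each = 50))
  expect_true(all(report_binary(ideal)$metrics[1:5] == 1))

  degen <- confusion(rep("B", 4), rep("B", 4), classes = c("A", "B"))
  expect_warning(r0 <- report_binary(degen, positive = "A"),
                 "zero denominator")
  expect_equal(unname(r0$metrics["sensitivity"]), 0)
  expect_true("sensitivity" %in% r0$zero_denominator)
})

test_that("macro averaging reproduces its identities", {
  cm <- reference_confusions()$three_class
  r <- report_multiclass_macro(cm)
  expect_equal(unname(r$metrics["accuracy"]), 88 / 150)
  expect_equal(unname(r$metrics["sensitivity"]),
               mean(c(24 / 50, 31 / 50, 33 / 50)))
  expect_equal(unname(r$metrics["specificity"]),
               mean(c(75 / 100, 87 / 100, 76 / 100)))
  expect_equal(unname(r$metrics["precision"]),
               mean(c(24 / 49, 31 / 44, 33 / 57)))

  diag3 <- confusion(rep(c("A", "B", "C"), each = 50),
                     rep(c("A", "B", "C"), each = 50))
  expect_true(all(report_multiclass_macro(diag3)$metrics[1:5] == 1))

  all_one <- confusion(rep(c("A", "B", "C"), each = 50),
                       rep("A", 150), c("A", "B", "C"))
  expect_warning(r1 <- report_multiclass_macro(all_one))
  expect_equal(unname(r1$metrics["sensitivity"]), 1 / 3)
  expect_equal(unname(r1$metrics["accuracy"]), 1 / 3)

  # K = 2 identity: macro sensitivity = (sens + spec) / 2
  b <- report_binary(reference_confusions()$bpd_hc, "BPD")$metrics
  per <- c(b["sensitivity"], b["specificity"])
  expect_equal(unname(mean(per)), unname((b["sensitivity"] + b["specificity"]) / 2))
  # F1 lies between precision and recall
  expect_true(b["f1"] >= min(b["precision"], b["sensitivity"]) &&
                b["f1"] <= max(b["precision"], b["sensitivity"]))
})

test_that("consistent relabeling permutes the confusion matrix and fixes macro metrics", {
  set.seed(6)
  truth <- sample(c("BPD", "MDD", "HC"), 120, TRUE)
  pred <- sample(c("BPD", "MDD", "HC"), 120, TRUE)
  cm1 <- confusion(truth, pred, c("BPD", "MDD", "HC"))
  map <- c(BPD = "X", MDD = "Y", HC = "Z")
  cm2 <- confusion(unname(map[truth]), unname(map[pred]), c("X", "Y", "Z"))
  expect_equal(unname(unclass(cm1)), unname(unclass(cm2)))
  expect_equal(report_multiclass_macro(cm1)$metrics,
               report_multiclass_macro(cm2)$metrics)
})

test_that("rank AUC matches exhaustive pair counting and its edge cases", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c("P", "P", "N", "N"), "P"), 1)
  # brute-force oracle over all positive-negative pairs, ties count half
  pair_auc <- function(s, y, pos) {
    ps <- s[y == pos]; ns <- s[y != pos]
    mean(outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(3)
  for (i in 1:25) {
    y <- sample(c("P", "N"), 12, TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(1:6, 12, TRUE)  # plenty of ties
    expect_equal(roc_auc(s, y, "P"), pair_auc(s, y, "P"))
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c("P", "N", "P", "N"), "P"),
               pair_auc(c(1, 2, 3, 4), c("P", "N", "P", "N"), "P"))
  expect_error(roc_auc(1:3, rep("P", 3)), class = "sptask_error_insufficient_data")

  set.seed(13)
  s <- rnorm(500); y <- sample(c("P", "N"), 500, TRUE)
  se3 <- 3 * sqrt(1 / (12 * sum(y == "P")) + 1 / (12 * sum(y == "N")))
  expect_lt(abs(roc_auc(s, y, "P") - 0.5), se3)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  s <- rnorm(80)
  y <- ifelse(s + rnorm(80) > 0, "P", "N")
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = s, levels = c("N", "P"), direction = "<"))))
  expect_equal(roc_auc(s, y, "P"), ref, tolerance = 1e-12)
})

test_that("the registry exposes the five models and rejects unknown names", {
  spec <- classifier_registry("svm", svm_config())
  expect_equal(spec$name, "svm")
  expect_equal(svm_config()$cost, 1.3)
  expect_equal(svm_config()$gamma, 0.0085)
  expect_equal(svm_config()$kernel, "radial")

  err <- tryCatch(classifier_registry("rf"),
                  sptask_error_unknown_classifier = function(e) e)
  expect_s3_class(err, "sptask_error_unknown_classifier")
  for (nm in c("svm", "knn", "lda", "logistic", "gbdt")) {
    expect_match(conditionMessage(err), nm)
  }

  # every registered model runs on simple separable data
  set.seed(19)
  x <- rbind(matrix(rnorm(20 * 4, 0), 20), matrix(rnorm(20 * 4, 4), 20))
  y <- rep(c("A", "B"), each = 20)
  for (nm in c("knn", "lda", "logistic", "gbdt")) {
    cv <- loocv_predict(x, y, nm)
    expect_gte(mean(cv$predicted == y), 0.8)
  }
})

test_that("the four discriminant analyses run, separate, and stay at chance on nulls", {
  set.seed(27)
  fm <- make_fm(n_per_group = 25, shift_cols = feature_columns(), shifts = 4)
  disc <- run_discriminations(fm, n_per_group = 20, seed = 2)
  expect_named(disc$analyses, c("mdd_hc", "bpd_hc", "bpd_mdd", "three_class"))
  for (nm in names(disc$analyses)) {
    expect_gte(disc$analyses[[nm]]$report$metrics["accuracy"], 0.9)
  }
  for (nm in c("mdd_hc", "bpd_hc", "bpd_mdd")) {
    expect_gte(disc$analyses[[nm]]$report$metrics["auc"], 0.95)
  }

  fm0 <- make_fm(n_per_group = 25)
  disc0 <- run_discriminations(fm0, n_per_group = 20, seed = 3)
  se3_bin <- 3 * sqrt(0.25 / 40)
  for (nm in c("mdd_hc", "bpd_hc", "bpd_mdd")) {
    expect_lt(abs(disc0$analyses[[nm]]$report$metrics["accuracy"] - 0.5),
              se3_bin)
  }
  se3_ter <- 3 * sqrt((1 / 3) * (2 / 3) / 60)
  expect_lt(abs(disc0$analyses$three_class$report$metrics["accuracy"] - 1 / 3),
            se3_ter)

  expect_error(run_discriminations(fm[fm$group != "HC", ], n_per_group = 20),
               class = "sptask_error_insufficient_group")
})
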