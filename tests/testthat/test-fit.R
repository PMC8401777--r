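separable_toy <- function() {
  fps <- list(
    mmpcliff:::new_mmp_fp(core = c(1, 2), sub = c(10, 11)),
    mmpcliff:::new_mmp_fp(core = c(1, 2, 3), sub = c(10, 12)),
    mmpcliff:::new_mmp_fp(core = c(1, 2), sub = c(20, 21)),
    mmpcliff:::new_mmp_fp(core = c(1, 3), sub = c(20, 22)))
  list(fps = fps, labels = c("AC", "AC", "NON_AC", "NON_AC"))
}

test_that("a separable toy set is fit to zero training error", {
  toy <- separable_toy()
  fit <- ac_svm(toy$fps, toy$labels, C = 10)
  expect_s3_class(fit, "ac_svm")
  expect_identical(predict(fit, toy$fps), toy$labels)
  # dual coefficient signs match the class labels and respect the box
  lab_sv <- toy$labels[fit$sv_index]
  expect_true(all(sign(fit$dual_coef) == ifelse(lab_sv == "AC", 1, -1)))
  expect_true(all(abs(fit$dual_coef) <= 10 + 1e-8))
})

test_that("decision sign and predicted class always agree", {
  mm <- fixture_mmps()
  fit <- ac_svm(mm, C = c(1, 10), seed = 5)
  d <- predict(fit, mm, type = "decision")
  cl <- predict(fit, mm, type = "class")
  expect_identical(cl, ifelse(d > 0, "AC", "NON_AC"))
  # manual evaluation of the decision function reproduces predict()
  sv <- fit$fps[fit$sv_index]
  K <- mmp_gram(mmp_fingerprints(mm), sv)
  expect_equal(as.numeric(K %*% fit$dual_coef - fit$b), d, tolerance = 1e-10)
})

test_that("the C search is seeded and reproducible", {
  mm <- fixture_mmps()
  f1 <- ac_svm(mm, C = c(0.1, 1, 10), seed = 7)
  f2 <- ac_svm(mm, C = c(0.1, 1, 10), seed = 7)
  expect_equal(f1$C, f2$C)
  expect_equal(f1$dual_coef, f2$dual_coef)
  expect_equal(f1$cv, f2$cv)
  # a length-1 grid skips the search entirely
  f3 <- ac_svm(mm, C = 1)
  expect_null(f3$cv)
  expect_equal(f3$C, 1)
})

test_that("single-class training sets are rejected", {
  toy <- separable_toy()
  expect_error(ac_svm(toy$fps[1:2], toy$labels[1:2], C = 1),
               "single class")
})

test_that("metrics match hand-computed confusion values", {
  # TP=3 FN=1 FP=1 TN=5: recall 0.75, MCC 14/24
  y_true <- c(rep("AC", 4), rep("NON_AC", 6))
  y_pred <- c("AC", "AC", "AC", "NON_AC", "AC", rep("NON_AC", 5))
  m <- classification_metrics(y_true, y_pred)
  expect_equal(m$recall, 0.75)
  expect_equal(m$mcc, 14 / 24)
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(3, 1, 1, 5))

  # perfect separation
  d <- c(2, 1, -1, -2)
  yt <- c("AC", "AC", "NON_AC", "NON_AC")
  m2 <- classification_metrics(yt, yt, d)
  expect_equal(unlist(m2[c("recall", "auc_roc", "mcc")]),
               c(recall = 1, auc_roc = 1, mcc = 1))

  # degenerate denominator: MCC is 0 by convention
  m3 <- classification_metrics(yt, rep("AC", 4))
  expect_equal(m3$mcc, 0)
})

test_that("series-wise LOO evaluates disjoint series fully", {
  mm <- fixture_mmps()
  ser <- group_into_mms(mm)
  ev <- mms_loo_evaluate(ser, C = 1, seed = 3)
  expect_s3_class(ev, "ac_eval")
  # all series here are compound-disjoint: every MMP gets evaluated
  expect_equal(nrow(ev$predictions), sum(vapply(ser, nrow, integer(1))))
  expect_length(ev$skipped, 0)
  # confusion counts sum to the number of evaluated MMPs
  m <- ev$metrics
  expect_equal(m$tp + m$fn + m$fp + m$tn, nrow(ev$predictions))
})

test_that("LOO never leaks cores or compounds into a fold's test set", {
  mm <- fixture_mmps()
  ser <- group_into_mms(mm)
  ev <- mms_loo_evaluate(ser, C = 1, seed = 3)
  for (f in unique(ev$predictions$fold)) {
    te <- ev$predictions[ev$predictions$fold == f, ]
    tr <- do.call(rbind, ser[-f])
    expect_false(any(te$core %in% tr$core))
    expect_false(any(c(te$cid_low, te$cid_high) %in%
                       c(tr$cid_low, tr$cid_high)))
  }
})

test_that("test MMPs sharing a compound with training are eliminated", {
  mm <- fixture_mmps()
  ser <- group_into_mms(mm)
  # plant an overlap: one pair of the first series reuses a compound id
  # that occurs in the second series
  ser[[1]]$cid_low[1] <- ser[[2]]$cid_low[1]
  ev <- mms_loo_evaluate(ser, C = 1, seed = 3)
  te1 <- ev$predictions[ev$predictions$fold == 1, ]
  expect_false(ser[[2]]$cid_low[1] %in% c(te1$cid_low, te1$cid_high))
  expect_equal(nrow(te1), nrow(ser[[1]]) - 1)
})
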