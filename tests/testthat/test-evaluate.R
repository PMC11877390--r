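# brute-force metric recount from raw (truth, prediction) label pairs
brute_metrics <- function(truth, pred) {
  tp <- sum(truth == "alcohol" & pred == "alcohol")
  fn <- sum(truth == "alcohol" & pred == "no alcohol")
  fp <- sum(truth == "no alcohol" & pred == "alcohol")
  tn <- sum(truth == "no alcohol" & pred == "no alcohol")
  sdiv <- function(a, b) if (b > 0) a / b else NA_real_
  pr <- sdiv(tp, tp + fp); se <- sdiv(tp, tp + fn)
  list(accuracy = (tp + tn) / length(truth), precision = pr,
       sensitivity = se, specificity = sdiv(tn, tn + fp),
       f1 = if (is.na(pr) || is.na(se) || pr + se == 0) NA_real_
            else 2 * pr * se / (pr + se))
}

test_that("metric formulas match a brute-force recount on fuzzed data", {
  # perfect classifier
  expect_identical(metrics_from_counts(10, 0, 10, 0),
                   list(accuracy = 1, precision = 1, sensitivity = 1,
                        specificity = 1, f1 = 1))
  # degenerate denominators yield NA, never an error
  m0 <- metrics_from_counts(0, 0, 5, 3)
  expect_true(is.na(m0$precision) && is.na(m0$f1))
  expect_identical(m0$specificity, 1)
  expect_error(metrics_from_counts(-1, 0, 0, 1), "non-negative")
  expect_error(metrics_from_counts(0, 0, 0, 0), "positive")

  set.seed(17)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    truth <- sample(c("alcohol", "no alcohol"), n, replace = TRUE)
    pred <- sample(c("alcohol", "no alcohol"), n, replace = TRUE)
    cc <- confusion_counts(truth, pred,
                           classes = c("no alcohol", "alcohol"))
    got <- metrics_from_counts(cc$tp, cc$fp, cc$tn, cc$fn)
    expect_identical(got, brute_metrics(truth, pred))
  }
})

test_that("confusion matrix uses rows = true, columns = predicted", {
  truth <- c("alcohol", "alcohol", "alcohol", "no alcohol")
  pred <- c("alcohol", "no alcohol", "no alcohol", "no alcohol")
  cc <- confusion_counts(truth, pred, classes = c("no alcohol", "alcohol"))
  expect_identical(cc$counts["alcohol", "no alcohol"], 2L)  # FN cell
  expect_identical(cc$counts["no alcohol", "alcohol"], 0L)  # FP cell
  expect_identical(c(cc$tp, cc$fp, cc$tn, cc$fn), c(1L, 0L, 1L, 2L))
  # row sums define TP+FN and TN+FP; a swapped convention breaks this
  expect_identical(cc$tp + cc$fn, sum(truth == "alcohol"))
  expect_identical(cc$tn + cc$fp, sum(truth == "no alcohol"))
  expect_equal(unname(rowSums(cc$row_percent)), c(100, 100))
  swapped <- confusion_counts(pred, truth,
                              classes = c("no alcohol", "alcohol"))
  expect_false(swapped$tp + swapped$fn == sum(truth == "alcohol") &&
                 swapped$fn == cc$fn)
})

test_that("F1 is bounded by precision and sensitivity", {
  set.seed(23)
  for (i in 1:200) {
    counts <- sample(0:30, 4, replace = TRUE)
    if (sum(counts) == 0) next
    m <- metrics_from_counts(counts[1], counts[2], counts[3], counts[4])
    if (is.na(m$f1)) next
    expect_lte(m$f1, max(m$precision, m$sensitivity) + 1e-12)
    if (m$precision == m$sensitivity)
      expect_equal(m$f1, m$precision)
  }
})

test_that("ROC sweep and AUC behave like the rank statistic they are", {
  # perfectly separating scores
  truth <- rep(c("alcohol", "no alcohol"), each = 20)
  scores <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  r <- roc_curve(scores, truth)
  expect_equal(r$auc, 1)
  expect_identical(range(r$points$fpr), c(0, 1))
  expect_identical(range(r$points$tpr), c(0, 1))

  # invariance under strictly increasing transforms
  r2 <- roc_curve(qlogis(scores * 0.98 + 0.01), truth)
  expect_equal(r2$auc, r$auc)

  # independent scores: AUC ~ 0.5 within Monte-Carlo error at n = 2000
  set.seed(29)
  truth_big <- sample(c("alcohol", "no alcohol"), 2000, replace = TRUE)
  r3 <- roc_curve(runif(2000), truth_big)
  expect_lt(abs(r3$auc - 0.5), 0.03)

  expect_error(roc_curve(runif(5), rep("alcohol", 5)), "both classes")
})

test_that("model evaluation assembles counts, metrics and ROC coherently", {
  tr5 <- synthetic_feature_table(30, time_labels(), n_features = 5,
                                 seed = 61L, separable = TRUE)
  va5 <- synthetic_feature_table(12, time_labels(), n_features = 5,
                                 seed = 62L, separable = TRUE)
  m <- tune_and_train(tr5, va5, label_scheme("binary_C"), trials = 2,
                      seed = 5L)
  rep <- evaluate_model(m, va5)

  expect_identical(rep$n, nrow(va5))
  expect_identical(sum(rep$confusion$counts), nrow(va5))
  # separable world: every chunk correct, diagonal sums to n
  expect_identical(rep$accuracy, 1)
  expect_identical(sum(diag(rep$confusion$counts)), nrow(va5))
  # TP + FN equals the number of post-consumption chunks by construction
  expect_identical(rep$confusion$tp + rep$confusion$fn,
                   sum(va5$time_label != "before drinking"))
  expect_identical(rep$metrics$percent$f1, 100L)
  expect_gte(rep$auc$macro, 0.99)
  expect_output(print(rep), "accuracy: 100%")

  missing_col <- va5[, setdiff(names(va5), "x__f1")]
  expect_error(evaluate_model(m, missing_col), "x__f1")
})

test_that("percent rounding is half-up as in reported tables", {
  expect_identical(percent_round(0.865), 87L)
  expect_identical(percent_round(0.864999), 86L)
  expect_identical(percent_round(c(0.405, NA)), c(41L, NA))
})
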