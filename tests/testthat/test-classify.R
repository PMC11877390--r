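test_that("label schemes implement the published merges", {
  labs <- time_labels()

  expect_identical(apply_scheme(labs, label_scheme("binary_C")),
                   c("no alcohol", "alcohol", "alcohol", "alcohol",
                     "alcohol"))
  expect_identical(apply_scheme(labs, label_scheme("binary_A")),
                   c("no alcohol", "no alcohol", "no alcohol", "alcohol",
                     "alcohol"))
  expect_identical(apply_scheme(labs, label_scheme("binary_B")),
                   c("no alcohol", "no alcohol", "alcohol", "alcohol",
                     "alcohol"))
  expect_identical(apply_scheme(labs, label_scheme("five")), labs)
  expect_identical(apply_scheme(labs, label_scheme("three_case1")),
                   c("no alcohol", "no alcohol", "30 min", "alcohol",
                     "alcohol"))
  expect_identical(apply_scheme(labs, label_scheme("three_case2")),
                   c("no alcohol", "0 and 30 min", "0 and 30 min",
                     "alcohol", "alcohol"))

  for (nm in c("binary_A", "binary_B", "binary_C")) {
    sch <- label_scheme(nm)
    expect_setequal(sch$classes, c("no alcohol", "alcohol"))
    expect_identical(sch$positive_class, "alcohol")
  }
  expect_true(is.na(label_scheme("five")$positive_class))

  expect_error(apply_scheme(c("0 min", "nightcap"), label_scheme("five")),
               "nightcap")
})

test_that("boosted trees learn non-linear boundaries and stay deterministic", {
  set.seed(7)
  n <- 400
  x <- matrix(runif(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- ifelse(xor(x[, 1] > 0.5, x[, 2] > 0.5), "p", "q")  # needs depth >= 2
  m <- gbt_fit(x, y, n_trees = 60, max_depth = 3, learning_rate = 0.3)

  expect_gt(mean(predict(m, x, type = "class") == y), 0.99)
  prob <- predict(m, x, type = "prob")
  expect_identical(colnames(prob), c("p", "q"))
  expect_true(all(abs(rowSums(prob) - 1) < 1e-12))
  expect_true(all(prob >= 0 & prob <= 1))

  m2 <- gbt_fit(x, y, n_trees = 60, max_depth = 3, learning_rate = 0.3)
  expect_identical(predict(m, x), predict(m2, x))

  expect_error(gbt_fit(x, rep("p", n), n_trees = 5), "single class")

  # multiclass probabilities track a 3-class linear problem
  y3 <- cut(x[, 1] + 0.05 * rnorm(n), c(-Inf, 0.33, 0.66, Inf),
            labels = c("lo", "mid", "hi"))
  m3 <- gbt_fit(x, y3, n_trees = 80, max_depth = 3, learning_rate = 0.2)
  expect_gt(mean(predict(m3, x, type = "class") == as.character(y3)), 0.9)
})

test_that("hyperparameter search maximizes held-out accuracy reproducibly", {
  # linearly separable features: any searched configuration nails it
  tr5 <- synthetic_feature_table(30, time_labels(), n_features = 5,
                                 seed = 53L, separable = TRUE)
  va5 <- synthetic_feature_table(10, time_labels(), n_features = 5,
                                 seed = 54L, separable = TRUE)
  m <- tune_and_train(tr5, va5, label_scheme("five"), trials = 3, seed = 9L)
  expect_identical(m$validation_accuracy, 1)
  expect_identical(nrow(m$search_trace), 3L)
  expect_true(all(m$search_trace$n_trees >= 50 &
                    m$search_trace$n_trees <= 500))
  expect_true(all(m$search_trace$max_depth >= 2 &
                    m$search_trace$max_depth <= 8))
  expect_true(all(m$search_trace$learning_rate >= 0.01 &
                    m$search_trace$learning_rate <= 0.3))

  # reproducibility: same seed -> same winner and predictions
  m2 <- tune_and_train(tr5, va5, label_scheme("five"), trials = 3, seed = 9L)
  expect_identical(m$hyperparameters, m2$hyperparameters)
  expect_identical(predict(m, va5), predict(m2, va5))

  # more trials never lower the best objective (monotonicity of max)
  m1 <- tune_and_train(tr5, va5, label_scheme("binary_C"), trials = 1,
                       seed = 13L)
  m50 <- tune_and_train(tr5, va5, label_scheme("binary_C"), trials = 6,
                        seed = 13L)
  expect_gte(m50$validation_accuracy, m1$validation_accuracy)

  # permuted labels, balanced binary classes -> chance-level accuracy
  trp <- synthetic_feature_table(60, c("before drinking", "60 min"),
                                 n_features = 8, seed = 55L)
  vap <- synthetic_feature_table(50, c("before drinking", "60 min"),
                                 n_features = 8, seed = 56L)
  mp <- tune_and_train(trp, vap, label_scheme("binary_A"), trials = 2,
                       seed = 3L)
  # 95% binomial band around 0.5 at n = 100 validation rows
  expect_gt(mp$validation_accuracy, 0.5 - 1.96 * sqrt(0.25 / 100) - 0.05)
  expect_lt(mp$validation_accuracy, 0.5 + 1.96 * sqrt(0.25 / 100) + 0.05)

  # single-class training set after mapping is rejected
  tr_one <- synthetic_feature_table(20, c("60 min", "90 min"),
                                    n_features = 4, seed = 57L)
  expect_error(tune_and_train(tr_one, vap, label_scheme("binary_A"),
                              trials = 1, seed = 1L), "single class")
})
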