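test_that("feature extraction has the contracted shape and determinism", {
  tr <- as_displacement_trace(
    simulate_displacement(quiet_state(), 6, 500, seed = 21L))
  chunks <- chunk_trace(tr, "S1", 1, "0 min")
  tab <- extract_features(chunks)

  # 86 chunks x (18 features x 4 channels) + 4 metadata columns
  expect_identical(dim(tab), c(86L, 76L))
  expect_identical(names(tab)[1:4], feature_meta_cols())
  expect_length(feature_cols(tab), 72L)
  expect_true(all(c("x__mean", "dx__kurtosis", "dy__band_frac")
                  %in% names(tab)))
  expect_false(anyNA(tab))

  # bit-identical on repeat
  expect_identical(tab, extract_features(chunks))

  expect_error(extract_features(chunks, c("mean", "mode")), "mode")
  expect_error(extract_features(chunks, character(0)), "non-empty")
})

test_that("degenerate constant channels impute shape features to zero", {
  flat <- as_displacement_trace(matrix(4.2, 300, 2), fps = 100)
  chunks <- chunk_trace(flat, "S1", 1, "before drinking")
  expect_warning(tab <- extract_features(chunks), "imputed")
  # mean/median/min/max reflect the constant (re-zeroed chunks are 0),
  # spread and shape features are 0
  expect_true(all(tab$x__sd == 0))
  expect_true(all(tab$x__range == 0))
  expect_true(all(tab$x__skewness == 0))
  expect_true(all(tab$dy__kurtosis == 0))
  expect_false(anyNA(tab))
})

test_that("spectral features find a known sinusoid", {
  fps <- 500; n <- 2500  # 0.2 Hz bins put 1.2 and 5 Hz exactly on-bin
  t <- (seq_len(n) - 1) / fps
  ch <- structure(list(channels = rbind(x = sin(2 * pi * 1.2 * t),
                                        y = cos(2 * pi * 1.2 * t),
                                        dx = sin(2 * pi * 5 * t),
                                        dy = rep(0, n)),
                       fps = fps, subject_id = "S1", recording_id = 1,
                       chunk_index = 1, start_frame = 0,
                       time_label = "0 min"),
                  class = "element_chunk")
  suppressWarnings(tab <- extract_features(list(ch)))
  bin <- fps / n  # one periodogram bin
  expect_lt(abs(tab$x__dom_freq - 1.2), bin + 1e-9)
  expect_lt(abs(tab$dx__dom_freq - 5), bin + 1e-9)
  # 1.2 Hz lies inside the cardiac band, 5 Hz outside
  expect_gt(tab$x__band_frac, 0.99)
  expect_lt(tab$dx__band_frac, 0.01)
  # rms of a unit sinusoid
  expect_equal(tab$x__rms, sqrt(mean(sin(2 * pi * 1.2 * t)^2)))
})

test_that("selection keeps separable features and drops flat ones", {
  tab <- synthetic_feature_table(50, c("alcohol", "no alcohol"),
                                 n_features = 6, seed = 31L,
                                 separable = TRUE)
  tab$x__f2 <- 1  # zero-variance column
  sel <- select_features(tab, target = "time_label")

  expect_true("x__f1" %in% sel$kept)       # class indicator + tiny noise
  expect_false("x__f2" %in% sel$kept)
  expect_match(sel$ledger$reason[sel$ledger$feature == "x__f2"],
               "zero-variance")
  expect_identical(sel$ledger$test[1], "mann-whitney")
  expect_true(all(sel$ledger$p >= 0 & sel$ledger$p <= 1, na.rm = TRUE))

  # multiclass target switches to Kruskal-Wallis
  tab5 <- synthetic_feature_table(20, time_labels(), n_features = 4,
                                  seed = 32L, separable = TRUE)
  sel5 <- select_features(tab5)
  expect_identical(sel5$ledger$test[1], "kruskal-wallis")
  expect_true("x__f1" %in% sel5$kept)

  # FDR correction is at least as strict as the raw rule
  sel_fdr <- select_features(tab5, correction = "fdr")
  expect_true(all(sel_fdr$kept %in% sel5$kept))

  one <- tab[tab$time_label == "alcohol", ]
  expect_error(select_features(one), "single class")
})

test_that("applying a frozen selection never recomputes and never leaks", {
  tab <- synthetic_feature_table(30, c("alcohol", "no alcohol"),
                                 n_features = 8, seed = 41L,
                                 separable = TRUE)
  sel <- select_features(tab)
  other <- synthetic_feature_table(10, c("alcohol", "no alcohol"),
                                   n_features = 8, seed = 42L)
  out <- apply_selection(other, sel)
  expect_identical(setdiff(names(out), feature_meta_cols()), sel$kept)
  # the selection object is untouched by application (frozen p-values)
  expect_identical(sel, select_features(tab))

  crippled <- other[, setdiff(names(other), sel$kept[1])]
  expect_error(apply_selection(crippled, sel), sel$kept[1], fixed = TRUE)
})
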