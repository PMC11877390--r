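#' Label-merging schemes
#'
#' Maps the five measurement time points onto merged classes. `five` is the
#' identity. The three-label case 1 merges before drinking + 0 min into
#' "no alcohol" and 60 + 90 min into "alcohol", keeping "30 min"; case 2
#' keeps only "before drinking" as "no alcohol", merges 0 + 30 min, and
#' merges 60 + 90 min into "alcohol". The binary models: A calls
#' before/0/30 min "no alcohol" and 60/90 min "alcohol"; B calls before/0
#' min "no alcohol" and 30/60/90 min "alcohol"; C calls only "before
#' drinking" "no alcohol" and everything after consumption "alcohol".
#'
#' @param name One of `"five"`, `"three_case1"`, `"three_case2"`,
#'   `"binary_A"`, `"binary_B"`, `"binary_C"`.
#' @return A `label_scheme`: list with `name`, `mapping` (named character
#'   vector over the five labels), `classes` (ordered class labels) and
#'   `positive_class` (`"alcohol"` for binary schemes, else `NA`).
#' @export
label_scheme <- function(name = c("five", "three_case1", "three_case2",
                                  "binary_A", "binary_B", "binary_C")) {
  name <- match.arg(name)
  labs <- time_labels()
  mapping <- switch(name,
    five = setNames(labs, labs),
    three_case1 = setNames(c("no alcohol", "no alcohol", "30 min",
                             "alcohol", "alcohol"), labs),
    three_case2 = setNames(c("no alcohol", "0 and 30 min", "0 and 30 min",
                             "alcohol", "alcohol"), labs),
    binary_A = setNames(c("no alcohol", "no alcohol", "no alcohol",
                          "alcohol", "alcohol"), labs),
    binary_B = setNames(c("no alcohol", "no alcohol", "alcohol",
                          "alcohol", "alcohol"), labs),
    binary_C = setNames(c("no alcohol", "alcohol", "alcohol", "alcohol",
                          "alcohol"), labs))
  classes <- unique(unname(mapping))
  binary <- length(classes) == 2L
  structure(list(name = name, mapping = mapping, classes = classes,
                 positive_class = if (binary) "alcohol" else NA_character_),
            class = "label_scheme")
}

#' All six label schemes
#' @return Named list of `label_scheme`s.
#' @export
all_label_schemes <- function() {
  nms <- c("five", "three_case1", "three_case2", "binary_A", "binary_B",
           "binary_C")
  setNames(lapply(nms, label_scheme), nms)
}

#' Apply a label scheme to five-label annotations
#'
#' @param labels Character vector drawn from [time_labels()].
#' @param scheme A [label_scheme()].
#' @return Character vector of merged class labels, same length.
#' @export
apply_scheme <- function(labels, scheme) {
  if (!inherits(scheme, "label_scheme"))
    stop_invalid("`scheme` must be a label_scheme")
  bad <- setdiff(unique(labels), names(scheme$mapping))
  if (length(bad))
    stop_invalid("unknown label(s): %s", paste(bad, collapse = ", "))
  unname(scheme$mapping[labels])
}

# ---- gradient-boosted tree ensemble (softmax objective) ----

#' Fit a gradient-boosted tree ensemble
#'
#' Boosted regression trees with a softmax objective and Newton (xgboost
#' style) leaf weights: per boosting round one tree per class is fitted to
#' the softmax gradients, with exact greedy splits and second-order gain.
#' Fully deterministic for fixed inputs.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Factor or character vector of class labels.
#' @param n_trees Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage per round.
#' @param lambda L2 regularization on leaf weights.
#' @return A `gbt_model` (list with the fitted trees, class levels and
#'   feature names).
#' @export
gbt_fit <- function(x, y, n_trees = 100, max_depth = 4, learning_rate = 0.1,
                    lambda = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) < 2L)
    stop_invalid("training labels contain a single class ('%s')", levels(y))
  fit <- gbt_fit_cpp(x, as.integer(y) - 1L, nlevels(y), as.integer(n_trees),
                     as.integer(max_depth), learning_rate, lambda)
  structure(c(fit, list(levels = levels(y), feature_names = colnames(x))),
            class = "gbt_model")
}

#' Predict from a gradient-boosted tree ensemble
#'
#' @param object A `gbt_model`.
#' @param newdata Numeric matrix or data frame with the training features.
#' @param type `"prob"` for the class-probability matrix (rows sum to 1) or
#'   `"class"` for the argmax label.
#' @param ... Unused.
#' @return Matrix of probabilities or character vector of labels.
#' @export
predict.gbt_model <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  if (!is.null(object$feature_names)) {
    if (is.data.frame(newdata)) {
      miss <- setdiff(object$feature_names, names(newdata))
      if (length(miss))
        stop_invalid("newdata lacks feature columns: %s",
                     paste(miss, collapse = ", "))
      newdata <- newdata[, object$feature_names, drop = FALSE]
    }
  }
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  p <- gbt_predict_cpp(object, x)
  colnames(p) <- object$levels
  if (type == "prob") p else object$levels[max.col(p, ties.method = "first")]
}

# ---- hyperparameter search ----

#' Tune and train a boosted-tree classifier under a label scheme
#'
#' Maps the five time-point labels through `scheme`, then runs a seeded
#' random search over `n_trees` in \[50, 500\], `max_depth` in \[2, 8\] and
#' `learning_rate` log-uniform in \[0.01, 0.3\], maximizing accuracy on the
#' validation table (the held-out subject). Ties are broken toward fewer
#' trees, then shallower depth, then earlier trial, so the search is fully
#' reproducible. The winning model is the one refit on the training rows
#' with the best parameters (fits are deterministic, so the best trial's
#' model is that refit).
#'
#' The validation rows influence only the search objective — never feature
#' selection or tree fitting.
#'
#' @param train,validation Feature tables (see [extract_features()]); if a
#'   `selection` is given it is applied to both.
#' @param scheme A [label_scheme()].
#' @param trials Number of random-search trials.
#' @param seed Integer seed for the parameter draws.
#' @param selection Optional `selection_result` from [select_features()]
#'   (computed on training rows).
#' @param search_space Optional overrides: list with `n_trees`, `max_depth`
#'   (integer ranges, length 2) and `learning_rate` (range, length 2).
#' @return A `trained_model`: list with `ensemble` (`gbt_model`),
#'   `hyperparameters`, `selected_features`, `scheme`, `seed`,
#'   `search_trials`, `validation_accuracy` and the full `search_trace`
#'   tibble.
#' @export
tune_and_train <- function(train, validation, scheme, trials = 50,
                           seed = 1L, selection = NULL,
                           search_space = NULL) {
  if (!inherits(scheme, "label_scheme"))
    stop_invalid("`scheme` must be a label_scheme")
  check_scalar_num(trials, "trials", 1)
  if (!is.null(selection)) {
    train <- apply_selection(train, selection)
    validation <- apply_selection(validation, selection)
  }
  feats <- feature_cols(train)
  miss <- setdiff(feats, names(validation))
  if (length(miss))
    stop_invalid("validation table lacks feature columns: %s",
                 paste(miss, collapse = ", "))
  if (length(feats) == 0L) stop_invalid("no feature columns to train on")

  y_tr <- apply_scheme(train$time_label, scheme)
  y_va <- apply_scheme(validation$time_label, scheme)
  if (length(unique(y_tr)) < 2L)
    stop_invalid("training set has a single class after mapping ('%s')",
                 unique(y_tr))

  space <- list(n_trees = c(50L, 500L), max_depth = c(2L, 8L),
                learning_rate = c(0.01, 0.3))
  if (!is.null(search_space)) space[names(search_space)] <- search_space

  x_tr <- as.matrix(train[, feats, drop = FALSE])
  x_va <- as.matrix(validation[, feats, drop = FALSE])

  set.seed(derive_seed(seed, 101L))
  draws <- tibble::tibble(
    trial = seq_len(trials),
    n_trees = sample(space$n_trees[1L]:space$n_trees[2L], trials,
                     replace = TRUE),
    max_depth = sample(space$max_depth[1L]:space$max_depth[2L], trials,
                       replace = TRUE),
    learning_rate = exp(runif(trials, log(space$learning_rate[1L]),
                              log(space$learning_rate[2L]))))

  acc <- numeric(trials)
  models <- vector("list", trials)
  for (i in seq_len(trials)) {
    m <- gbt_fit(x_tr, y_tr, n_trees = draws$n_trees[i],
                 max_depth = draws$max_depth[i],
                 learning_rate = draws$learning_rate[i])
    pred <- predict(m, x_va, type = "class")
    acc[i] <- mean(pred == y_va)
    models[[i]] <- m
  }
  trace <- cbind(draws, tibble::tibble(validation_accuracy = acc))
  # smallest model wins among equal-accuracy trials
  ord <- order(-acc, draws$n_trees, draws$max_depth, draws$trial)
  best <- ord[1L]

  structure(list(
    ensemble = models[[best]],
    hyperparameters = list(n_trees = draws$n_trees[best],
                           max_depth = draws$max_depth[best],
                           learning_rate = draws$learning_rate[best]),
    selected_features = feats, scheme = scheme, seed = seed,
    search_trials = trials, validation_accuracy = acc[best],
    search_trace = trace), class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(paste0("trained_model (%s scheme): %d trees, depth %d, ",
                     "learning rate %.3f; %d features; validation accuracy ",
                     "%.3f over %d trials\n"),
              x$scheme$name, x$hyperparameters$n_trees,
              x$hyperparameters$max_depth, x$hyperparameters$learning_rate,
              length(x$selected_features), x$validation_accuracy,
              x$search_trials))
  invisible(x)
}

#' @export
predict.trained_model <- function(object, newdata, type = c("prob", "class"),
                                  ...) {
  predict(object$ensemble, newdata, type = match.arg(type))
}
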