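#' Names of the default time-series feature registry
#'
#' Eighteen per-channel descriptors: location (mean, median), spread (sd,
#' range, min, max, quantiles 0.1/0.25/0.75/0.9, rms), shape (skewness,
#' excess kurtosis), dynamics (mean absolute change, lag-1 autocorrelation,
#' signal energy) and spectrum (dominant frequency in Hz and the fraction of
#' non-DC power in the 0.5-3 Hz cardiac band). Quantiles use linear
#' interpolation between order statistics (type 7) so values are
#' bit-reproducible. Applied to the four chunk channels this yields
#' 18 x 4 = 72 feature columns.
#'
#' @return Character vector of 18 feature names.
#' @export
feature_registry <- function() {
  c("mean", "median", "sd", "skewness", "kurtosis", "min", "max", "range",
    "q10", "q25", "q75", "q90", "rms", "mean_abs_change", "acf1", "energy",
    "dom_freq", "band_frac")
}

# one channel -> named vector over `registry`; degenerate descriptors
# (zero-variance skew/kurtosis/acf, empty spectrum) are imputed to 0
channel_features <- function(v, fps, registry) {
  n <- length(v)
  m <- mean(v)
  s <- sd(v)
  cent <- v - m
  degen <- character(0)

  spec_needed <- any(c("dom_freq", "band_frac") %in% registry)
  if (spec_needed) {
    # one-sided periodogram, DC excluded
    p <- Mod(fft(cent))^2
    nf <- n %/% 2
    freq <- (1:nf) / n * fps
    pw <- p[2:(nf + 1)]
    tot <- sum(pw)
  }

  get <- function(name) {
    switch(name,
      mean = m,
      median = median(v),
      sd = s,
      skewness = if (s > 0) mean(cent^3) / (mean(cent^2)^1.5) else {
        degen <<- c(degen, "skewness"); 0
      },
      kurtosis = if (s > 0) mean(cent^4) / (mean(cent^2)^2) - 3 else {
        degen <<- c(degen, "kurtosis"); 0
      },
      min = min(v),
      max = max(v),
      range = max(v) - min(v),
      q10 = unname(quantile(v, 0.10, type = 7)),
      q25 = unname(quantile(v, 0.25, type = 7)),
      q75 = unname(quantile(v, 0.75, type = 7)),
      q90 = unname(quantile(v, 0.90, type = 7)),
      rms = sqrt(mean(v^2)),
      mean_abs_change = mean(abs(diff(v))),
      acf1 = if (s > 0) {
        sum(cent[-n] * cent[-1]) / sum(cent^2)
      } else { degen <<- c(degen, "acf1"); 0 },
      energy = sum(v^2),
      dom_freq = if (tot > 0) freq[which.max(pw)] else {
        degen <<- c(degen, "dom_freq"); 0
      },
      band_frac = if (tot > 0) {
        sum(pw[freq >= 0.5 & freq <= 3]) / tot
      } else { degen <<- c(degen, "band_frac"); 0 },
      stop_invalid("unknown feature '%s'; valid names: %s", name,
                   paste(feature_registry(), collapse = ", "))
    )
  }
  out <- vapply(registry, get, numeric(1))
  attr(out, "degenerate") <- degen
  out
}

#' Extract a feature table from element chunks
#'
#' Computes every registry feature on each of the four channels of every
#' chunk. Column names follow the `channel__feature` pattern (e.g.
#' `dx__kurtosis`). Degenerate descriptors on constant channels (skewness,
#' kurtosis, lag-1 autocorrelation, spectral features) are imputed to 0 with
#' one consolidated warning, so the table never contains missing values.
#'
#' @param chunks List of `element_chunk`s from [chunk_trace()].
#' @param registry Feature names, a subset of [feature_registry()].
#' @return A tibble with one row per chunk: metadata columns `subject_id`,
#'   `recording_id`, `chunk_index`, `time_label` followed by
#'   `4 * length(registry)` numeric feature columns.
#' @export
extract_features <- function(chunks, registry = feature_registry()) {
  if (length(registry) == 0L)
    stop_invalid("`registry` must be non-empty")
  bad <- setdiff(registry, feature_registry())
  if (length(bad))
    stop_invalid("unknown feature name(s) %s; valid names: %s",
                 paste(bad, collapse = ", "),
                 paste(feature_registry(), collapse = ", "))
  if (length(chunks) == 0L) stop_invalid("no chunks supplied")

  ch_names <- c("x", "y", "dx", "dy")
  col_names <- as.vector(t(outer(ch_names, registry, paste, sep = "__")))
  degen_any <- character(0)
  feat <- matrix(NA_real_, length(chunks), length(col_names),
                 dimnames = list(NULL, col_names))
  for (i in seq_along(chunks)) {
    ch <- chunks[[i]]
    row <- unlist(lapply(ch_names, function(cn) {
      f <- channel_features(ch$channels[cn, ], ch$fps, registry)
      degen_any <<- union(degen_any,
                          if (length(attr(f, "degenerate")))
                            paste0(cn, "__", attr(f, "degenerate")) else
                              character(0))
      f
    }), use.names = FALSE)
    feat[i, ] <- row
  }
  if (length(degen_any))
    warning(sprintf("degenerate features imputed to 0: %s",
                    paste(sort(degen_any), collapse = ", ")), call. = FALSE)

  meta <- tibble::tibble(
    subject_id = vapply(chunks, function(x) x$subject_id, character(1)),
    recording_id = vapply(chunks, function(x) as.numeric(x$recording_id),
                          numeric(1)),
    chunk_index = vapply(chunks, function(x) as.numeric(x$chunk_index),
                         numeric(1)),
    time_label = vapply(chunks, function(x) x$time_label, character(1)))
  cbind(meta, tibble::as_tibble(feat))
}

#' Metadata column names of a feature table
#' @return Character vector.
#' @export
feature_meta_cols <- function() {
  c("subject_id", "recording_id", "chunk_index", "time_label")
}

#' Names of the feature (non-metadata) columns of a feature table
#' @param table A feature table from [extract_features()].
#' @return Character vector.
#' @export
feature_cols <- function(table) {
  setdiff(names(table), feature_meta_cols())
}

#' Filter features by per-feature hypothesis tests against the target
#'
#' For each feature column, tests association with the target labels using
#' rank-based tests (robust on heavy-tailed displacement features): a
#' two-sided Mann-Whitney U test when the target is binary, Kruskal-Wallis
#' when multiclass. Features with p <= alpha are kept; `correction = "none"`
#' applies the raw-p discard rule, `correction = "fdr"` applies
#' Benjamini-Hochberg before thresholding. Zero-variance features have no
#' defined p-value and are dropped with a recorded reason.
#'
#' Selection must be computed on training rows only; apply the returned
#' object to validation data with [apply_selection()], which never
#' recomputes p-values.
#'
#' @param table Feature table (training rows).
#' @param target Name of the label column (default `"time_label"`).
#' @param alpha Significance threshold (default 0.05).
#' @param correction `"none"` or `"fdr"`.
#' @return A `selection_result`: list with `ledger` (tibble: feature, p,
#'   p_adjusted, test, kept, reason), `kept` (character vector), `alpha`,
#'   `correction`, `target`.
#' @export
select_features <- function(table, target = "time_label", alpha = 0.05,
                            correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  check_scalar_num(alpha, "alpha", 0, 1)
  if (!target %in% names(table))
    stop_invalid("target column '%s' not found", target)
  y <- factor(table[[target]])
  if (nlevels(y) < 2L)
    stop_invalid("target has a single class ('%s'); need at least 2",
                 levels(y))
  if (min(table(y)) < 2L)
    stop_invalid("every class needs at least 2 rows")

  feats <- feature_cols(table)
  test_name <- if (nlevels(y) == 2L) "mann-whitney" else "kruskal-wallis"
  p <- vapply(feats, function(f) {
    v <- table[[f]]
    if (length(unique(v)) == 1L) return(NA_real_)
    if (nlevels(y) == 2L) {
      suppressWarnings(
        wilcox.test(v[y == levels(y)[1L]], v[y == levels(y)[2L]],
                    exact = FALSE)$p.value)
    } else {
      suppressWarnings(kruskal.test(v, y)$p.value)
    }
  }, numeric(1))

  p_adj <- if (correction == "fdr") p.adjust(p, "BH") else p
  kept <- !is.na(p_adj) & p_adj <= alpha
  reason <- ifelse(is.na(p), "zero-variance (p undefined)",
                   ifelse(kept, "significant", "not significant"))
  ledger <- tibble::tibble(feature = feats, p = unname(p),
                           p_adjusted = unname(p_adj), test = test_name,
                           kept = unname(kept), reason = reason)
  structure(list(ledger = ledger, kept = feats[kept], alpha = alpha,
                 correction = correction, target = target),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("selection_result: kept %d / %d features ",
                     "(%s test, alpha = %g, correction = %s)\n"),
              length(x$kept), nrow(x$ledger), x$ledger$test[1L], x$alpha,
              x$correction))
  invisible(x)
}

#' Apply a frozen feature selection to a table
#'
#' Subsets the table to the kept features plus metadata; p-values are never
#' recomputed, so applying a training-derived selection to validation rows
#' cannot leak label information.
#'
#' @param table A feature table.
#' @param selection A `selection_result`.
#' @return The filtered table.
#' @export
apply_selection <- function(table, selection) {
  if (!inherits(selection, "selection_result"))
    stop_invalid("`selection` must be a selection_result")
  missing_cols <- setdiff(selection$kept, names(table))
  if (length(missing_cols))
    stop_invalid("table lacks selected feature columns: %s",
                 paste(missing_cols, collapse = ", "))
  table[, c(intersect(feature_meta_cols(), names(table)), selection$kept)]
}
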