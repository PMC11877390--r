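#' Slice a displacement trace into overlapping chunks
#'
#' Emits one chunk per start index `s` in `{0, stride, 2*stride, ...}` with
#' `s + length <= trace length`; trailing partial windows are dropped. Each
#' chunk carries four channels: `x`, `y` — the cumulative peak position
#' re-zeroed to the chunk's first sample — and `dx`, `dy` — their first
#' differences (per-pair shifts), padded to length L by repeating the first
#' difference value so the array stays rectangular.
#'
#' @param trace A `displacement_trace` (or anything [as_displacement_trace()]
#'   accepts).
#' @param subject_id,recording_id,time_label Chunk metadata; `time_label`
#'   must be one of [time_labels()].
#' @param length Window length in frames (default 256).
#' @param stride Step between window starts in frames (default 32).
#' @return List of `element_chunk` objects: each a list with `channels`
#'   (4 x L matrix, rows x/y/dx/dy), `fps`, `subject_id`, `recording_id`,
#'   `chunk_index`, `start_frame` (0-based) and `time_label`.
#' @export
chunk_trace <- function(trace, subject_id, recording_id, time_label,
                        length = 256, stride = 32) {
  trace <- as_displacement_trace(trace)
  if (!(time_label %in% time_labels()))
    stop_invalid("unknown time_label '%s'", time_label)
  check_scalar_num(length, "length", 2)
  check_scalar_num(stride, "stride", 1)
  n <- nrow(trace$cum_position)
  if (n < length)
    stop_invalid("trace too short: %d samples, need at least %d (= length)",
                 n, length)

  starts <- seq.int(0L, n - length, by = stride)
  lapply(seq_along(starts), function(k) {
    s <- starts[k]
    seg <- trace$cum_position[(s + 1L):(s + length), , drop = FALSE]
    seg <- seg - matrix(seg[1L, ], length, 2L, byrow = TRUE)
    d <- diff(seg)
    ch <- rbind(x = seg[, 1L], y = seg[, 2L],
                dx = c(d[1L, 1L], d[, 1L]), dy = c(d[1L, 2L], d[, 2L]))
    dimnames(ch) <- list(c("x", "y", "dx", "dy"), NULL)
    structure(list(channels = ch, fps = trace$fps, subject_id = subject_id,
                   recording_id = recording_id, chunk_index = k,
                   start_frame = s, time_label = time_label),
              class = "element_chunk")
  })
}

#' Chunk every recording of a simulated or loaded study
#'
#' @param study List with `recordings` and `manifest` as produced by
#'   [simulate_study()].
#' @param length,stride Passed to [chunk_trace()].
#' @return Flat list of `element_chunk`s across all recordings.
#' @export
chunk_study <- function(study, length = 256, stride = 32) {
  man <- study$manifest
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    rec <- study$recordings[[man$name[i]]]
    tr <- if (inherits(rec, "speckle_video"))
      extract_displacement(rec) else as_displacement_trace(rec)
    out[[i]] <- chunk_trace(tr, man$subject_id[i], man$recording_id[i],
                            man$time_label[i], length, stride)
  }
  do.call(c, out)
}

#' Split chunks into training and validation sets by subject
#'
#' Leave-subject(s)-out partition: every chunk of a validation subject goes
#' to validation, all others to training. Subject-wise splitting is the
#' canonical mode because overlapping chunks of one recording leak across a
#' random chunk-wise split.
#'
#' @param chunks List of `element_chunk`s.
#' @param validation_subjects Non-empty proper subset of the observed
#'   subject ids.
#' @return List with elements `train` and `validation` (chunk lists).
#' @export
split_by_subject <- function(chunks, validation_subjects) {
  ids <- vapply(chunks, function(ch) ch$subject_id, character(1))
  observed <- unique(ids)
  if (length(validation_subjects) == 0L)
    stop_invalid("`validation_subjects` must be non-empty")
  unknown <- setdiff(validation_subjects, observed)
  if (length(unknown))
    stop_invalid("unknown validation subjects: %s",
                 paste(unknown, collapse = ", "))
  if (setequal(validation_subjects, observed))
    stop_invalid("validation set must be a proper subset of subjects")
  val <- ids %in% validation_subjects
  list(train = chunks[!val], validation = chunks[val])
}

#' Random chunk-wise split (leakage-prone; for comparison only)
#'
#' An 80/20 split over chunks ignoring subject identity. Overlapping chunks
#' from the same recording end up on both sides, so validation scores are
#' optimistically biased; a warning says so.
#'
#' @param chunks List of `element_chunk`s.
#' @param train_fraction Fraction assigned to training.
#' @param seed RNG seed.
#' @return List with `train` and `validation`.
#' @export
split_random <- function(chunks, train_fraction = 0.8, seed = 1L) {
  check_scalar_num(train_fraction, "train_fraction", 0, 1)
  warning(paste("chunk-wise random splitting leaks overlapping chunks",
                "across the split; prefer split_by_subject()"), call. = FALSE)
  set.seed(seed)
  n <- length(chunks)
  idx <- sample.int(n, floor(n * train_fraction))
  list(train = chunks[idx], validation = chunks[-idx])
}
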