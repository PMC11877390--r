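#' Write a speckle video as a directory of PNG frames
#'
#' One grayscale PNG per frame (`frame_000001.png`, ...; lexicographic order
#' is frame order) plus a `video.json` sidecar holding fps, bit depth and,
#' when present, the ground-truth shift series.
#'
#' @param video A `speckle_video`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_speckle_video <- function(video, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(video$frames)
  full <- max(video$frames)
  scale <- if (full > 255) 65535 else 255
  for (i in seq_len(d[3L])) {
    png::writePNG(video$frames[, , i] / scale,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  side <- list(fps = video$fps, n_frames = d[3L], height = d[1L],
               width = d[2L], scale = scale)
  if (!is.null(video$ground_truth))
    side$ground_truth <- unname(apply(video$ground_truth, 1L, c,
                                      simplify = FALSE))
  jsonlite::write_json(side, file.path(dir, "video.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a speckle video from a directory of PNG frames
#'
#' Frames are read in lexicographic filename order; `video.json`, when
#' present, restores fps and ground truth.
#'
#' @param dir Directory written by [write_speckle_video()] (or any
#'   directory of equally sized grayscale PNGs).
#' @param fps Frame rate override when no sidecar exists.
#' @return A `speckle_video`.
#' @export
read_speckle_video <- function(dir, fps = NULL) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop_invalid("no PNG frames found in %s", dir)
  side_path <- file.path(dir, "video.json")
  side <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else NULL
  scale <- if (!is.null(side)) side$scale else 255
  frames <- NULL
  for (i in seq_along(files)) {
    im <- png::readPNG(files[i])
    if (length(dim(im)) == 3L) im <- im[, , 1L]  # grayscale from RGB
    if (is.null(frames))
      frames <- array(0L, dim = c(nrow(im), ncol(im), length(files)))
    frames[, , i] <- as.integer(round(im * scale))
  }
  gt <- NULL
  if (!is.null(side$ground_truth)) {
    gt <- side$ground_truth
    if (is.list(gt)) gt <- do.call(rbind, lapply(gt, unlist))
    if (ncol(gt) != 2L) gt <- t(gt)
    colnames(gt) <- c("x", "y")
  }
  if (is.null(fps)) fps <- if (!is.null(side)) as.numeric(side$fps) else 500
  structure(list(frames = frames, fps = fps, ground_truth = gt),
            class = "speckle_video")
}

#' Write a displacement trace to CSV
#'
#' Columns: `frame_index` (0-based), `dx`, `dy` (per-pair shift; first row
#' NA), `x_cum`, `y_cum`, `peak_height`; fps goes to a JSON sidecar next to
#' the CSV.
#'
#' @param trace A `displacement_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  n <- nrow(trace$cum_position)
  df <- data.frame(frame_index = 0:(n - 1L),
                   dx = c(NA, trace$pair_shift[, 1L]),
                   dy = c(NA, trace$pair_shift[, 2L]),
                   x_cum = trace$cum_position[, 1L],
                   y_cum = trace$cum_position[, 2L],
                   peak_height = c(NA, trace$peak_height))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fps = trace$fps),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write a chunk set to CSV
#'
#' Long format: one row per sample per chunk, columns `subject_id`,
#' `recording_id`, `chunk_index`, `time_label`, `start_frame`, `fps`,
#' `sample`, `x`, `y`, `dx`, `dy`.
#'
#' @param chunks List of `element_chunk`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chunks_csv <- function(chunks, path) {
  blocks <- lapply(chunks, function(ch) {
    L <- ncol(ch$channels)
    data.frame(subject_id = ch$subject_id, recording_id = ch$recording_id,
               chunk_index = ch$chunk_index, time_label = ch$time_label,
               start_frame = ch$start_frame, fps = ch$fps,
               sample = seq_len(L), x = ch$channels["x", ],
               y = ch$channels["y", ], dx = ch$channels["dx", ],
               dy = ch$channels["dy", ])
  })
  write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}

#' Read a chunk set from CSV
#'
#' @param path CSV written by [write_chunks_csv()].
#' @return List of `element_chunk`s.
#' @export
read_chunks_csv <- function(path) {
  df <- read.csv(path)
  key <- interaction(df$subject_id, df$time_label, df$recording_id,
                     df$chunk_index, drop = TRUE)
  lapply(split(df, key), function(b) {
    b <- b[order(b$sample), ]
    structure(list(
      channels = rbind(x = b$x, y = b$y, dx = b$dx, dy = b$dy),
      fps = b$fps[1L], subject_id = as.character(b$subject_id[1L]),
      recording_id = b$recording_id[1L], chunk_index = b$chunk_index[1L],
      start_frame = b$start_frame[1L],
      time_label = as.character(b$time_label[1L])),
      class = "element_chunk")
  })
}

#' Read a displacement trace from CSV
#'
#' @param path CSV written by [write_trace_csv()].
#' @param fps Frame rate override when no sidecar exists.
#' @return A `displacement_trace`.
#' @export
read_trace_csv <- function(path, fps = NULL) {
  df <- read.csv(path)
  need <- c("frame_index", "dx", "dy", "x_cum", "y_cum")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("trace CSV lacks columns: %s", paste(miss, collapse = ", "))
  side_path <- paste0(tools::file_path_sans_ext(path), ".json")
  if (is.null(fps)) {
    fps <- if (file.exists(side_path))
      as.numeric(jsonlite::read_json(side_path)$fps) else 500
  }
  cum <- as.matrix(df[, c("x_cum", "y_cum")])
  colnames(cum) <- c("x", "y")
  pair <- as.matrix(df[-1L, c("dx", "dy")])
  ph <- if ("peak_height" %in% names(df)) df$peak_height[-1L]
    else rep(NA_real_, nrow(pair))
  structure(list(fps = fps, pair_shift = pair, cum_position = cum,
                 peak_height = ph),
            class = "displacement_trace")
}
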