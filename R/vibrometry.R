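#' Shift between two speckle frames by correlation-peak location
#'
#' Computes the zero-mean normalized circular cross-correlation of the two
#' frames in the frequency domain and locates its maximum; the peak offset
#' is the lateral shift of the pattern between the frames. Shifts are signed
#' per axis in (-N/2, N/2\]. With `subpixel = TRUE` the integer peak is
#' refined by a per-axis three-point parabolic fit, clamped to +/- 0.5 px.
#'
#' Coordinate convention: x = column index increasing rightward, y = row
#' index increasing downward, origin top-left. A returned shift (dx, dy)
#' means the pattern in `frame_b` sits (dx, dy) pixels from where it sat in
#' `frame_a`.
#'
#' @param frame_a,frame_b Numeric matrices of identical shape, at least
#'   32 x 32.
#' @param subpixel Apply parabolic subpixel refinement?
#' @param window Apply a Hann window to both frames before correlating
#'   (useful for edge-dominated, non-speckle scenes). Off by default.
#' @return Named numeric vector `c(dx, dy, peak_height)`; `peak_height` is
#'   the normalized correlation at the integer argmax, in \[-1, 1\].
#' @export
correlate_pair <- function(frame_a, frame_b, subpixel = FALSE,
                           window = FALSE) {
  if (!is.matrix(frame_a) || !is.matrix(frame_b))
    stop_invalid("frames must be numeric matrices")
  if (!identical(dim(frame_a), dim(frame_b)))
    stop_invalid("frame shape mismatch: %s vs %s",
                 paste(dim(frame_a), collapse = "x"),
                 paste(dim(frame_b), collapse = "x"))
  if (any(dim(frame_a) < 32L))
    stop_invalid("frames must be at least 32 x 32 (got %s)",
                 paste(dim(frame_a), collapse = "x"))
  a <- frame_a - mean(frame_a)
  b <- frame_b - mean(frame_b)
  if (window) {
    nr <- nrow(a); nc <- ncol(a)
    hr <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
    hc <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
    w <- outer(hr, hc)
    a <- a * w; b <- b * w
    a <- a - mean(a); b <- b - mean(b)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop_invalid("constant (zero-variance) frame: %s",
                 paste(c("a", "b")[c(na == 0, nb == 0)], collapse = " and "))

  # circular cross-correlation surface: cc[dy+1, dx+1] = corr at shift (dx, dy)
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) /
    (length(a) * na * nb)
  pk <- which(cc == max(cc), arr.ind = TRUE)
  pk <- pk[order(pk[, 1L], pk[, 2L]), , drop = FALSE][1L, ]  # smallest row-major index
  peak_height <- cc[pk[1L], pk[2L]]

  nr <- nrow(cc); nc <- ncol(cc)
  to_signed <- function(idx0, n) if (idx0 > n / 2) idx0 - n else idx0
  dy <- to_signed(pk[1L] - 1L, nr)
  dx <- to_signed(pk[2L] - 1L, nc)

  if (subpixel) {
    wrap <- function(i, n) ((i - 1L) %% n) + 1L
    para <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (den == 0) return(0)
      max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
    }
    dy <- dy + para(cc[wrap(pk[1L] - 1L, nr), pk[2L]], peak_height,
                    cc[wrap(pk[1L] + 1L, nr), pk[2L]])
    dx <- dx + para(cc[pk[1L], wrap(pk[2L] - 1L, nc)], peak_height,
                    cc[pk[1L], wrap(pk[2L] + 1L, nc)])
  }
  c(dx = unname(dx), dy = unname(dy), peak_height = unname(peak_height))
}

#' Extract the displacement trace from a speckle video
#'
#' Applies [correlate_pair()] to every consecutive frame pair and integrates
#' the per-pair shifts into the cumulative peak position relative to frame 0.
#'
#' @param video A `speckle_video` (list with `frames` H x W x n array and
#'   `fps`), e.g. from [render_speckle_video()] or [read_speckle_video()].
#' @param subpixel Passed to [correlate_pair()].
#' @param window Passed to [correlate_pair()].
#' @return A `displacement_trace`: list with `fps`, `pair_shift`
#'   ((n-1) x 2), `cum_position` (n x 2, first row (0, 0)), `peak_height`
#'   (length n-1).
#' @export
extract_displacement <- function(video, subpixel = TRUE, window = FALSE) {
  fr <- video$frames
  if (is.null(fr) || length(dim(fr)) != 3L)
    stop_invalid("`video` must carry an H x W x n frame array")
  n <- dim(fr)[3L]
  if (n < 2L)
    stop_invalid("video must have at least 2 frames (got %d)", n)

  pair <- matrix(0, n - 1L, 2L, dimnames = list(NULL, c("dx", "dy")))
  height <- numeric(n - 1L)
  prev <- fr[, , 1L]
  for (i in seq_len(n - 1L)) {
    cur <- fr[, , i + 1L]
    r <- tryCatch(correlate_pair(prev, cur, subpixel = subpixel,
                                 window = window),
                  error = function(e)
                    stop_invalid("frame pair (%d, %d): %s", i, i + 1L,
                                 conditionMessage(e)))
    pair[i, ] <- r[c("dx", "dy")]
    height[i] <- r["peak_height"]
    prev <- cur
  }
  cum <- rbind(c(0, 0), apply(pair, 2L, cumsum))
  colnames(cum) <- c("x", "y")
  structure(list(fps = video$fps, pair_shift = pair, cum_position = cum,
                 peak_height = height),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf(paste0("displacement_trace: %d frames at %g fps; cumulative ",
                     "range x [%.2f, %.2f] px, y [%.2f, %.2f] px\n"),
              nrow(x$cum_position), x$fps,
              min(x$cum_position[, 1L]), max(x$cum_position[, 1L]),
              min(x$cum_position[, 2L]), max(x$cum_position[, 2L])))
  invisible(x)
}

#' Coerce a displacement series or trace to the common trace form
#'
#' Ground-truth `displacement_series` objects (simulator output) carry only
#' cumulative positions; this builds the full trace structure from either
#' representation so downstream chunking treats measured and ground-truth
#' traces alike.
#'
#' @param x A `displacement_trace` or `displacement_series` (or plain n x 2
#'   matrix plus `fps`).
#' @param fps Frame rate, required when `x` carries none.
#' @return A `displacement_trace`.
#' @export
as_displacement_trace <- function(x, fps = NULL) {
  if (inherits(x, "displacement_trace")) return(x)
  if (is.null(fps)) fps <- attr(x, "fps")
  if (is.null(fps)) stop_invalid("`fps` is required when `x` carries none")
  cum <- unclass(x)
  if (!is.matrix(cum) || ncol(cum) != 2L)
    stop_invalid("`x` must be an n x 2 matrix of cumulative positions")
  cum <- cum - matrix(cum[1L, ], nrow(cum), 2L, byrow = TRUE)
  colnames(cum) <- c("x", "y")
  pair <- diff(cum)
  colnames(pair) <- c("dx", "dy")
  structure(list(fps = fps, pair_shift = pair, cum_position = cum,
                 peak_height = rep(NA_real_, nrow(pair))),
            class = "displacement_trace")
}
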