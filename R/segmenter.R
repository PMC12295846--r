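# Frame-gap video segmentation: variable-length videos are converted into
# fixed-size segments of N frames taken every G frames (spanning S = N * G
# raw frames), zero-padded at the end of a video.

#' Video record
#'
#' A labeled, ordered stack of frames — the unit of splitting and
#' prediction.
#'
#' @param frames a `T x H x W x 3` numeric array with intensities in
#'   `[0, 1]`.
#' @param label class label, `"upper"` or `"lower"`.
#' @param video_id identifier string.
#' @return an object of class `video_record`.
#' @export
video_record <- function(frames, label, video_id) {
  d <- dim(frames)
  if (is.null(d) || length(d) != 4L || d[4] != 3L)
    stop("frames must be a T x H x W x 3 array")
  if (d[1] < 1L) stop("a video must contain at least one frame")
  label <- match.arg(label, c("upper", "lower"))
  structure(list(video_id = as.character(video_id), frames = frames,
                 label = label, n_frames = d[1]),
            class = "video_record")
}

#' @export
print.video_record <- function(x, ...) {
  d <- dim(x$frames)
  cat("video ", x$video_id, ": ", d[1], " frames of ", d[2], "x", d[3],
      ", label ", x$label, "\n", sep = "")
  invisible(x)
}

#' Segment sampling configuration
#'
#' @param frames_per_segment number of frames `N` in a segment.
#' @param frame_gap index stride `G` between consecutive selected frames.
#' @return an object of class `segment_config` with fields
#'   `frames_per_segment`, `frame_gap` and the derived span
#'   `segment_span = G * N`.
#' @export
segment_config <- function(frames_per_segment, frame_gap) {
  n <- frames_per_segment; g <- frame_gap
  if (length(n) != 1L || length(g) != 1L || is.na(n) || is.na(g) ||
      n < 1 || g < 1 || n != round(n) || g != round(g))
    stop("frames_per_segment and frame_gap must be positive integers")
  structure(list(frames_per_segment = as.integer(n),
                 frame_gap = as.integer(g),
                 segment_span = as.integer(g) * as.integer(n)),
            class = "segment_config")
}

#' Segment span
#'
#' Number of raw-video frames spanned by one segment:
#' `S = G x N` (frame gap times frames per segment).
#'
#' @param config a [segment_config()].
#' @return the positive integer span `S`.
#' @export
segment_span <- function(config) {
  stopifnot(inherits(config, "segment_config"))
  config$segment_span
}

#' Preprocess raw frames into a video record
#'
#' Every frame is resized (bilinear, no aspect-ratio preservation) to a
#' fixed spatial size — 224 x 224 by default — and intensities are scaled
#' to `[0, 1]` (inputs in 0..255 are divided by 255).
#'
#' @param raw_frames a `T x H x W x 3` array of frames at any resolution.
#' @param label,video_id passed to [video_record()].
#' @param size target `(height, width)`.
#' @return a [video_record()] whose frames are `T x size[1] x size[2] x 3`.
#' @export
preprocess_video <- function(raw_frames, label, video_id,
                             size = c(224L, 224L)) {
  d <- dim(raw_frames)
  if (is.null(d) || length(d) != 4L || d[1] < 1L || d[4] != 3L)
    stop("undecodable input for video '", video_id,
         "': need a nonempty T x H x W x 3 frame stack")
  if (max(raw_frames, na.rm = TRUE) > 1) raw_frames <- raw_frames / 255
  if (d[2] == size[1] && d[3] == size[2]) {
    return(video_record(raw_frames, label, video_id))
  }
  out <- array(0, c(d[1], size[1], size[2], 3L))
  for (i in seq_len(d[1])) {
    fr <- aperm(raw_frames[i, , , , drop = TRUE], c(2L, 1L, 3L))  # x, y, c
    rs <- EBImage::resize(fr, w = size[2], h = size[1])
    out[i, , , ] <- aperm(rs, c(2L, 1L, 3L))
  }
  video_record(out, label, video_id)
}

#' Extract one segment from a video
#'
#' Reads frames at `start_index, start_index + G, ...` while the index is
#' inside the video, then appends all-zero frames until the segment holds
#' exactly `N` frames.
#'
#' @param video a [video_record()].
#' @param start_index 0-based start frame index in `[0, T)`.
#' @param config a [segment_config()].
#' @return an object of class `video_segment` with fields `data`
#'   (`N x H x W x 3`), `source_id`, `start_index`, `source_indices`
#'   (0-based) and `pad_count`.
#' @export
extract_segment <- function(video, start_index, config) {
  stopifnot(inherits(video, "video_record"), inherits(config, "segment_config"))
  T <- video$n_frames
  if (length(start_index) != 1L || is.na(start_index) ||
      start_index < 0 || start_index >= T)
    stop("start_index must lie in [0, ", T, ")")
  start_index <- as.integer(start_index)
  n <- config$frames_per_segment
  g <- config$frame_gap
  idx <- start_index + (0:(n - 1L)) * g
  idx <- idx[idx < T]
  d <- dim(video$frames)
  data <- array(0, c(n, d[2], d[3], 3L))
  data[seq_along(idx), , , ] <- video$frames[idx + 1L, , , , drop = FALSE]
  structure(list(data = data, source_id = video$video_id,
                 start_index = start_index,
                 source_indices = idx,
                 pad_count = n - length(idx),
                 label = video$label),
            class = "video_segment")
}

#' @export
print.video_segment <- function(x, ...) {
  cat("segment of ", x$source_id, " @", x$start_index, ": ",
      length(x$source_indices), " real frame(s), pad_count ", x$pad_count,
      "\n", sep = "")
  invisible(x)
}

#' Number of segments a video provides
#'
#' A video of `T` frames is treated as `ceiling(T / S)` distinct
#' non-overlapping span-aligned windows (minimum 1), with window origins
#' `0, S, 2S, ...`.
#'
#' @param video a [video_record()].
#' @param config a [segment_config()].
#' @return a positive integer count.
#' @export
n_segments <- function(video, config) {
  stopifnot(inherits(video, "video_record"), inherits(config, "segment_config"))
  max(1L, as.integer(ceiling(video$n_frames / segment_span(config))))
}

#' Randomly sample a training segment
#'
#' The start index is drawn uniformly from every frame index in `[0, T)`
#' (a segment can come from any part of the video); starts near the end of
#' the video yield zero-padded segments.
#'
#' @param video a [video_record()].
#' @param config a [segment_config()].
#' @param seed optional integer seed; `NULL` uses (and advances) the
#'   ambient RNG stream.
#' @return a `video_segment`.
#' @export
sample_training_segment <- function(video, config, seed = NULL) {
  stopifnot(inherits(video, "video_record"))
  start <- .with_seed(seed, sample.int(video$n_frames, 1L) - 1L)
  extract_segment(video, start, config)
}

#' Select segments for inference
#'
#' Draws up to `max_segments` segments (10 by default, matching the
#' inference cap) with distinct start indices, sampled without replacement
#' from the non-overlapping window origins `0, S, 2S, ...`; a video with
#' fewer windows contributes all of them.
#'
#' @param video a [video_record()].
#' @param config a [segment_config()].
#' @param max_segments maximum number of segments used for one prediction.
#' @param seed optional integer seed.
#' @return a list of `video_segment`s with pairwise-distinct start indices.
#' @export
select_inference_segments <- function(video, config, max_segments = 10L,
                                      seed = NULL) {
  stopifnot(inherits(video, "video_record"))
  if (max_segments < 1L) stop("max_segments must be at least 1")
  avail <- n_segments(video, config)
  origins <- (seq_len(avail) - 1L) * segment_span(config)
  origins <- origins[origins < video$n_frames]
  k <- min(length(origins), as.integer(max_segments))
  starts <- .with_seed(seed, origins[sample.int(length(origins), k)])
  lapply(starts, extract_segment, video = video, config = config)
}

#' Write / read an uncompressed video fixture
#'
#' One file per video holding the frame stack, label and id, independent of
#' any codec.
#'
#' @param video a [video_record()].
#' @param path file path (`.rds`).
#' @return `write_video_record` returns `path` invisibly;
#'   `read_video_record` returns the [video_record()].
#' @export
write_video_record <- function(video, path) {
  stopifnot(inherits(video, "video_record"))
  saveRDS(video, path)
  invisible(path)
}

#' @rdname write_video_record
#' @export
read_video_record <- function(path) {
  v <- readRDS(path)
  if (!inherits(v, "video_record")) stop("file '", path, "' is not a video fixture")
  v
}
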