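# Frame-accurate audio-video alignment: audio frame grids, call marking,
# head/tail trimming to a common span, and the merged per-frame annotation
# table.

#' Number of rows of the audio frame grid
#'
#' An audio recording of `audio_duration_s` seconds sampled on the video
#' frame clock occupies `floor(audio_duration_s * fps)` rows (drop, never
#' invent, a partial trailing frame).
#'
#' @param audio_duration_s Audio duration, seconds.
#' @param fps Frames per second.
#' @return Integer row count.
#' @examples
#' audio_frame_grid(1200.005, 12)  # 14400
#' audio_frame_grid(1202.168, 12)  # 14426
#' @export
audio_frame_grid <- function(audio_duration_s, fps) {
  if (audio_duration_s <= 0 || fps <= 0)
    stop("duration and fps must be positive")
  as.integer(floor(audio_duration_s * fps))
}

#' Mark call-type frames on an audio grid
#'
#' Builds (or updates) the per-type 0/1 call columns of an audio frame grid:
#' a call spanning `[begin_s, end_s]` marks frames `floor(begin * fps)` ..
#' `floor(end * fps)` inclusive (1-based rows; a call shorter than one frame
#' still marks one frame).  Overlapping calls of different types may mark
#' the same frame.  Calls reaching outside the recording are clipped with a
#' warning.
#'
#' @param n_frames Grid length, e.g. from [audio_frame_grid()].
#' @param calls A typed call table (see [classify_calls()]).
#' @param fps Frames per second.
#' @return Data frame: `frame` plus one 0/1 column per type in
#'   [call_types()] and one `Probability_<type>` placeholder column
#'   (all zeros, kept for the machine-results layout).
#' @export
mark_call_frames <- function(n_frames, calls, fps) {
  grid <- data.frame(frame = seq_len(n_frames))
  for (tp in call_types()) {
    grid[[paste0("Probability_", tp)]] <- 0
    grid[[tp]] <- 0L
  }
  if (!nrow(calls)) return(grid)
  if (!"call_type" %in% names(calls)) calls <- classify_calls(calls)
  clipped <- calls$begin_s < 0 | calls$end_s > n_frames / fps
  if (any(clipped))
    warning(sum(clipped), " call(s) outside the recording span were clipped")
  for (i in seq_len(nrow(calls))) {
    tp <- calls$call_type[i]
    if (!tp %in% call_types()) next
    f0 <- max(1L, floor(max(0, calls$begin_s[i]) * fps) + 1L)
    f1 <- min(n_frames, floor(calls$end_s[i] * fps) + 1L)
    if (f1 < f0) next
    grid[f0:f1, tp] <- 1L
  }
  grid
}

#' Trim video frames and audio grid to a common span
#'
#' The later-starting stream defines time zero: the earlier stream loses
#' `round(lag * fps)` head frames, then both are cut to the shorter tail so
#' the spans are identical.  Trimming only drops rows; it never alters an
#' annotation value.
#'
#' @param video A per-frame data frame for the video stream.
#' @param audio A per-frame data frame for the audio grid.
#' @param start_lag_s Audio start minus video start, seconds (as recovered
#'   from the session index timestamps).
#' @param fps Frames per second.
#' @return List: `video` and `audio` (equal-length data frames) and
#'   `report` (head/tail frames cut per stream, the common length, and
#'   `residual_subframe` -- the sub-frame part of the lag that rounding to
#'   whole frames could not remove, in frames, always <= 0.5).
#' @export
trim_to_common <- function(video, audio, start_lag_s, fps) {
  nv <- nrow(video)
  na <- nrow(audio)
  shift <- round(start_lag_s * fps)
  cut_v <- max(0L, shift)        # audio starts later -> cut video head
  cut_a <- max(0L, -shift)       # audio starts earlier -> cut audio head
  if (cut_v >= nv || cut_a >= na)
    stop("no overlap between audio and video after lag correction")
  v <- video[(cut_v + 1L):nv, , drop = FALSE]
  a <- audio[(cut_a + 1L):na, , drop = FALSE]
  common <- min(nrow(v), nrow(a))
  report <- list(
    head_cut_video = cut_v, head_cut_audio = cut_a,
    tail_cut_video = nrow(v) - common, tail_cut_audio = nrow(a) - common,
    common_frames = common,
    residual_subframe = abs(shift - start_lag_s * fps))
  v <- v[seq_len(common), , drop = FALSE]
  a <- a[seq_len(common), , drop = FALSE]
  rownames(v) <- rownames(a) <- NULL
  list(video = v, audio = a, report = report)
}

#' Merge behavior predictions with the call grid
#'
#' Column union of the (already trimmed) per-frame behavior table and call
#' grid; the row count is preserved.  The result is the frame annotation
#' table consumed by the aggregation stage.
#'
#' @param behavior Data frame: `frame` plus per-behavior 0/1 (and optional
#'   probability) columns.
#' @param call_grid Data frame from [mark_call_frames()], same length.
#' @param tolerance_frames Maximal tolerated length mismatch (default 0).
#' @return Data frame with `frame` re-numbered 1..n and all annotation
#'   columns.
#' @export
merge_annotations <- function(behavior, call_grid, tolerance_frames = 0) {
  if (abs(nrow(behavior) - nrow(call_grid)) > tolerance_frames)
    stop("length mismatch between behavior table and call grid: ",
         nrow(behavior), " vs ", nrow(call_grid))
  n <- min(nrow(behavior), nrow(call_grid))
  b <- behavior[seq_len(n), setdiff(names(behavior), "frame"), drop = FALSE]
  g <- call_grid[seq_len(n), setdiff(names(call_grid), "frame"), drop = FALSE]
  out <- cbind(frame = seq_len(n), b, g)
  rownames(out) <- NULL
  out
}

#' Write a machine-readable alignment report
#'
#' Serializes the trim report of [trim_to_common()] (head/tail cuts, common
#' length, sub-frame residue) as JSON next to the plain-text session log.
#'
#' @param report The `report` element returned by [trim_to_common()] or
#'   [align_session()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Recover the audio-video start lag from index timestamps
#'
#' @param index_row One row of the session index.
#' @return Audio start minus video start, seconds (whole-second resolution,
#'   the precision the recorder logs carry).
#' @export
index_start_lag <- function(index_row) {
  v <- as.POSIXct(index_row$video_start_iso, format = "%Y-%m-%dT%H:%M:%S",
                  tz = "UTC")
  a <- as.POSIXct(index_row$audio_start_iso, format = "%Y-%m-%dT%H:%M:%S",
                  tz = "UTC")
  if (is.na(v) || is.na(a)) stop("unparseable index timestamps")
  as.numeric(difftime(a, v, units = "secs"))
}
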