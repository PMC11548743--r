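# Audio frame grids, call marking, trimming and annotation merging.

test_that("grid row counts are floor(duration x fps)", {
  expect_equal(audio_frame_grid(1200.005, 12), 14400L)
  expect_equal(audio_frame_grid(1202.168, 12), 14426L)
  expect_equal(audio_frame_grid(1, 12), 12L)
  expect_error(audio_frame_grid(0, 12), "positive")
  expect_error(audio_frame_grid(10, -1), "positive")
})

test_that("calls mark inclusive frame spans; sub-frame calls still mark a frame", {
  calls <- classify_calls(data.frame(
    begin_s = 0, end_s = 1 / 12, duration_s = 1 / 12,
    principal_freq_khz = 60, bandwidth_khz = 2, detector = "hf"))
  grid <- mark_call_frames(24, calls, 12)
  expect_equal(which(grid$FLAT == 1), c(1, 2))
  short <- classify_calls(data.frame(
    begin_s = 0.5, end_s = 0.512, duration_s = 0.012,
    principal_freq_khz = 60, bandwidth_khz = 2, detector = "hf"))
  g2 <- mark_call_frames(24, short, 12)
  expect_equal(sum(g2$SHORT), 1)      # 12 ms is a seventh of a frame
  empty <- mark_call_frames(24, short[0, ], 12)
  expect_true(all(empty[call_types()] == 0))
})

test_that("overlapping calls of different types can share a frame", {
  calls <- data.frame(
    begin_s = c(0.1, 0.15), end_s = c(0.3, 0.2),
    duration_s = c(0.2, 0.05),
    principal_freq_khz = c(24, 60), bandwidth_khz = c(2, 3),
    detector = c("lf", "hf"))
  grid <- mark_call_frames(12, calls, 12)
  both <- grid$ALARM == 1 & grid$FLAT == 1
  expect_true(any(both))
})

test_that("every in-range call marks at least one frame (event conservation)", {
  set.seed(5)
  for (rep in 1:20) {
    n <- 30
    begin <- runif(n, 0, 9.5)
    dur <- runif(n, 0.003, 0.4)
    calls <- classify_calls(data.frame(
      begin_s = begin, end_s = begin + dur, duration_s = dur,
      principal_freq_khz = runif(n, 36, 94), bandwidth_khz = runif(n, 0, 20),
      detector = "hf"))
    grid <- mark_call_frames(120, calls, 12)
    # marked frames can be shared by overlapping calls, so check each call
    # individually: its span must contain a marked frame of its type
    for (i in seq_len(n)) {
      f0 <- floor(calls$begin_s[i] * 12) + 1
      f1 <- min(120, floor(calls$end_s[i] * 12) + 1)
      expect_true(any(grid[f0:f1, calls$call_type[i]] == 1))
    }
  }
})

test_that("out-of-span calls are clipped with a warning", {
  calls <- classify_calls(data.frame(
    begin_s = 1.9, end_s = 2.5, duration_s = 0.6,
    principal_freq_khz = 24, bandwidth_khz = 2, detector = "lf"))
  expect_warning(grid <- mark_call_frames(24, calls, 12), "clipped")
  expect_equal(which(grid$ALARM == 1), 23:24)
})

test_that("trimming cuts the earlier stream's head and the longer tail", {
  video <- data.frame(frame = 1:14400, v = seq_len(14400))
  audio <- data.frame(frame = 1:14426, a = seq_len(14426))
  # equal starts: only the audio tail is cut
  tr <- trim_to_common(video, audio, start_lag_s = 0, fps = 12)
  expect_equal(nrow(tr$video), 14400)
  expect_equal(nrow(tr$audio), 14400)
  expect_equal(tr$report$tail_cut_audio, 26)
  expect_equal(tr$report$head_cut_audio, 0)
  # audio starts 1 s before the video: 12 audio head rows go
  tr2 <- trim_to_common(video, audio, start_lag_s = -1, fps = 12)
  expect_equal(tr2$report$head_cut_audio, 12)
  expect_equal(tr2$report$head_cut_video, 0)
  expect_equal(tr2$audio$a[1], 13)     # values survive, rows drop
  expect_equal(tr2$video$v[1], 1)
  # equal streams: nothing cut
  tr3 <- trim_to_common(video, video, 0, 12)
  expect_equal(unlist(tr3$report[1:4]), c(head_cut_video = 0, head_cut_audio = 0,
                                          tail_cut_video = 0, tail_cut_audio = 0))
  expect_error(trim_to_common(video[1:10, ], audio, start_lag_s = 100, fps = 12),
               "overlap")
})

test_that("trimming preserves annotation values (only rows drop)", {
  set.seed(9)
  video <- data.frame(frame = 1:120, fighting = rbinom(120, 1, 0.2))
  audio <- data.frame(frame = 1:130, ALARM = rbinom(130, 1, 0.2))
  tr <- trim_to_common(video, audio, start_lag_s = -0.5, fps = 12)
  expect_equal(tr$audio$ALARM, audio$ALARM[7:(6 + nrow(tr$audio))])
  expect_equal(tr$video$fighting, video$fighting[seq_len(nrow(tr$video))])
})

test_that("the merged annotation table reproduces the explanatory toy example", {
  # three frames: fighting only on frame 3; an alarm call over frames 1-2,
  # flat calls on frame 1 and frame 3 -> fighting and flat co-occur at 3
  behavior <- data.frame(frame = 1:3, fighting = c(0L, 0L, 1L))
  calls <- classify_calls(data.frame(
    begin_s = c(0.005, 0.02, 0.18),
    end_s = c(0.100, 0.05, 0.23),
    duration_s = c(0.095, 0.03, 0.05),
    principal_freq_khz = c(24, 60, 60),
    bandwidth_khz = c(2, 3, 3),
    detector = c("lf", "hf", "hf")))
  grid <- mark_call_frames(3, calls, 12)
  ann <- merge_annotations(behavior, grid)
  expect_equal(ann$ALARM, c(1L, 1L, 0L))
  expect_equal(ann$FLAT, c(1L, 0L, 1L))
  expect_equal(ann$fighting, c(0L, 0L, 1L))
  expect_equal(which(ann$fighting == 1 & ann$FLAT == 1), 3L)
  # empty call grid: behaviors survive, call columns all zero
  ann2 <- merge_annotations(behavior, mark_call_frames(3, calls[0, ], 12))
  expect_equal(ann2$fighting, behavior$fighting)
  expect_true(all(ann2[call_types()] == 0))
  expect_error(merge_annotations(behavior, grid[1:2, ]), "mismatch")
  # file round-trip preserves the table
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(ann, path, row.names = FALSE)
  expect_equal(read.csv(path), ann)
})

test_that("whole-second index timestamps bound the residual alignment error by 12 frames", {
  set.seed(123)
  fps <- 12
  worst <- 0
  for (rep in 1:50) {
    true_off <- runif(1, -2, 2)
    vstart <- as.POSIXct("2023-05-05 17:50:00", tz = "UTC") + runif(1)
    astart <- vstart + true_off
    est_lag <- as.numeric(difftime(trunc(astart, "secs"),
                                   trunc(vstart, "secs"), units = "secs"))
    residual <- abs(round(est_lag * fps) - round(true_off * fps))
    worst <- max(worst, residual)
    expect_lte(residual, 12)
    # and the trim itself reports only a sub-frame rounding residue
    video <- data.frame(frame = 1:360)
    audio <- data.frame(frame = 1:370)
    tr <- trim_to_common(video, audio, est_lag, fps)
    expect_lte(tr$report$residual_subframe, 0.5)
  }
  expect_gt(worst, 0)   # the bound is actually exercised
})

test_that("exact lags align to within one frame", {
  video <- data.frame(frame = 1:240)
  audio <- data.frame(frame = 1:250)
  for (lag in c(-1.71, -0.3, 0, 0.49, 1.96)) {
    tr <- trim_to_common(video, audio, lag, 12)
    expect_lte(abs(round(lag * 12) - lag * 12), 0.5)
    expect_equal(nrow(tr$video), nrow(tr$audio))
  }
})

test_that("the alignment report serializes to JSON faithfully", {
  video <- data.frame(frame = 1:120)
  audio <- data.frame(frame = 1:130)
  tr <- trim_to_common(video, audio, start_lag_s = -0.5, fps = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_alignment_report(tr$report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$head_cut_audio, tr$report$head_cut_audio)
  expect_equal(back$common_frames, tr$report$common_frames)
  expect_equal(back$residual_subframe, tr$report$residual_subframe)
})

test_that("index round-trip and lag recovery work together", {
  idx <- data.frame(
    box = "A", date = "2023-05-05", session_type = "light_to_dark",
    video_file = "v.csv", audio_file = "a.csv",
    video_start_iso = "2023-05-05T17:50:00",
    audio_start_iso = "2023-05-05T17:49:58",
    video_duration_s = 1200.1, audio_duration_s = 1201.5, fps = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_index_csv(idx, path)
  back <- read_index_csv(path)
  expect_equal(index_start_lag(back[1, ]), -2)
  idx2 <- rbind(idx, idx)
  write_index_csv(idx2, path)
  expect_error(read_index_csv(path), "duplicated")
})
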