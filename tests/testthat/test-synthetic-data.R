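# Synthetic generator: determinism, scripted geometry, call emission, study
# layout.

test_that("empty episode script yields an all-null ground truth of the right size", {
  spec <- synth_session_spec(video_duration = 10, audio_duration = 10, seed = 3)
  g <- generate_pose_track(spec)
  expect_equal(nrow(g$track), 120)
  expect_equal(ncol(g$track), 73)   # frame + 24 keypoints x 3
  expect_equal(sum(g$truth), 0)
  expect_equal(colnames(g$truth), behavior_categories())
})

test_that("generation is deterministic under a fixed seed and leaves the RNG alone", {
  spec <- synth_session_spec(video_duration = 8, audio_duration = 8, seed = 7,
    episode_script = data.frame(behavior = "fighting", start_s = 2, end_s = 5))
  set.seed(999)
  g1 <- generate_pose_track(spec)
  after1 <- runif(1)
  set.seed(999)
  g2 <- generate_pose_track(spec)
  after2 <- runif(1)
  expect_identical(g1, g2)
  expect_identical(after1, after2)   # caller's stream undisturbed
  c1 <- generate_call_table(spec)
  c2 <- generate_call_table(spec)
  expect_identical(c1, c2)
})

test_that("scripted adjacent lying puts body centroids close on exactly those frames", {
  spec <- synth_session_spec(video_duration = 15, audio_duration = 15, seed = 21,
    episode_script = data.frame(behavior = "adjacent_lying",
                                start_s = 0, end_s = 5))
  g <- generate_pose_track(spec, noise_px = 0, missing_rate = 0)
  tr <- g$track
  # recompute whole-body centroid distance from the emitted coordinates
  cxa <- rowMeans(as.data.frame(tr)[paste0("A_", body_parts(), "_x")])
  cya <- rowMeans(as.data.frame(tr)[paste0("A_", body_parts(), "_y")])
  cxb <- rowMeans(as.data.frame(tr)[paste0("B_", body_parts(), "_x")])
  cyb <- rowMeans(as.data.frame(tr)[paste0("B_", body_parts(), "_y")])
  d <- sqrt((cxa - cxb)^2 + (cya - cyb)^2)
  lying <- g$truth[, "adjacent_lying"] == 1
  expect_equal(which(lying), 1:60)
  expect_true(all(d[lying] < 80))          # well under one body length
  expect_true(all(d[!lying] > 80))         # wandering rats stay apart here
})

test_that("scripted postures shape the geometry their classifiers rely on", {
  script <- data.frame(
    behavior = c("mounting", "rearing", "nosing"),
    start_s = c(1, 6, 11), end_s = c(4, 9, 14))
  spec <- synth_session_spec(video_duration = 16, audio_duration = 16,
                             seed = 5, episode_script = script)
  g <- generate_pose_track(spec, noise_px = 0, missing_rate = 0)
  tr <- interpolate_track(g$track)
  ft <- extract_features(tr)
  mount <- g$truth[, "mounting"] == 1
  rear <- g$truth[, "rearing"] == 1
  nose <- g$truth[, "nosing"] == 1
  none <- rowSums(g$truth) == 0
  expect_gt(mean(ft$polygon_pct_overlap[mount]), 90)
  expect_lt(mean(ft$polygon_pct_overlap[none]), 30)
  # rearing shrinks the rearing animal's body hull well below baseline
  expect_lt(mean(ft$hull_body_A[rear]), 0.5 * mean(ft$hull_body_A[none]))
  expect_lt(mean(ft$d_nose_nose[nose]), 15)
})

test_that("mutually exclusive postures on the same frames are rejected", {
  bad <- data.frame(behavior = c("adjacent_lying", "following"),
                    start_s = c(0, 3), end_s = c(5, 8))
  expect_error(
    synth_session_spec(video_duration = 10, audio_duration = 10,
                       episode_script = bad),
    "mutually exclusive")
  ok <- data.frame(behavior = c("adjacent_lying", "following"),
                   start_s = c(0, 6), end_s = c(5, 8))
  expect_s3_class(
    synth_session_spec(video_duration = 10, audio_duration = 10,
                       episode_script = ok),
    "synth_session_spec")
})

test_that("spec validation enforces clocks and scripts", {
  expect_error(synth_session_spec(fps = 0), "fps")
  expect_error(synth_session_spec(video_duration = 100, audio_duration = 110),
               "5 s")
  expect_error(synth_session_spec(
    video_duration = 10, audio_duration = 10,
    episode_script = data.frame(behavior = "nosing", start_s = 5, end_s = 12)),
    "interval")
  expect_error(synth_session_spec(
    video_duration = 10, audio_duration = 10,
    call_script = data.frame(type = "FLAT", window_start_s = 0,
                             window_end_s = 10, rate_per_min = -1)),
    "negative")
})

test_that("call generation honours fixed counts and the type parameter regions", {
  sc <- data.frame(type = c("SHORT", "FM"), window_start_s = 0,
                   window_end_s = 60, n = c(1, 4))
  spec <- synth_session_spec(video_duration = 60, audio_duration = 60,
                             seed = 9, call_script = sc)
  ct <- generate_call_table(spec)
  expect_equal(nrow(ct$calls), 5)
  expect_equal(sum(ct$truth == "FM"), 4)
  expect_equal(sum(ct$truth == "SHORT"), 1)
  expect_true(all(ct$calls$begin_s >= 0 & ct$calls$end_s <= 60))
  # emitted records satisfy the scripted type's defining inequalities
  short <- ct$calls[ct$truth == "SHORT", ]
  fm <- ct$calls[ct$truth == "FM", ]
  expect_true(all(short$duration_s <= 0.012))
  expect_true(all(fm$duration_s > 0.012 & fm$bandwidth_khz > 6))
  # closed loop: rule-based typing recovers the script exactly
  expect_equal(classify_call(ct$calls), ct$truth)
})

test_that("zero rates yield an empty call table", {
  sc <- data.frame(type = call_types(), window_start_s = 0,
                   window_end_s = 60, rate_per_min = 0)
  spec <- synth_session_spec(video_duration = 60, audio_duration = 60,
                             seed = 2, call_script = sc)
  expect_equal(nrow(generate_call_table(spec)$calls), 0)
})

test_that("a generated study has the full session grid, emulates dropout, and flags short designs", {
  dir <- withr::local_tempdir()
  idx <- generate_study(dir, n_boxes = 2, n_days = 4, seed = 4,
                        session_duration = 30)
  expect_equal(nrow(idx), 2 * 4 * 2)
  expect_true(all(file.exists(file.path(dir, idx$video_file))))
  expect_true(all(file.exists(file.path(dir, idx$audio_file))))
  expect_true(file.exists(file.path(dir, "index.csv")))
  expect_true(file.exists(file.path(dir, "study_truth.csv")))
  expect_true(attr(idx, "early_late_available"))

  dir2 <- withr::local_tempdir()
  drop <- data.frame(box = "A", day = 2, session_type = "dark_to_light")
  idx2 <- generate_study(dir2, n_boxes = 2, n_days = 4, seed = 4,
                         session_duration = 30, drop_sessions = drop)
  expect_equal(nrow(idx2), 15)

  dir3 <- withr::local_tempdir()
  expect_warning(
    idx3 <- generate_study(dir3, n_boxes = 1, n_days = 1, seed = 4,
                           session_duration = 30),
    "early/late")
  expect_false(attr(idx3, "early_late_available"))
})

test_that("study ground truth matches what the geometry recovers (noise off)", {
  dir <- withr::local_tempdir()
  suppressWarnings(   # 1-day design: the early/late warning is expected
    generate_study(dir, n_boxes = 1, n_days = 1, seed = 8,
                   session_duration = 120, noise_px = 0, missing_rate = 0))
  idx <- read_index_csv(file.path(dir, "index.csv"))
  row <- idx[idx$session_type == "light_to_dark", ]
  tr <- read_pose_csv(file.path(dir, row$video_file), fps = row$fps)
  truth <- read.csv(file.path(dir, sub("_pose", "_truth", row$video_file)))
  ft <- extract_features(interpolate_track(tr))
  mount <- truth$mounting == 1
  if (any(mount)) expect_gt(mean(ft$polygon_pct_overlap[mount]), 80)
  fight <- truth$fighting == 1
  if (any(fight)) expect_gt(mean(ft$mov_total[fight]), 10)
})
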