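# Classifier training, PR curves, threshold selection, frame prediction.

test_that("a perfectly separable feature gives held-out F1 = 1 and exact prediction", {
  set.seed(10)
  n <- 400
  ft <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(ft) <- paste0("f", 1:5)
  y <- as.integer(ft$f1 > 0.3)
  labels <- data.frame(nosing = y)
  b <- train_classifiers(ft, labels, list(num_trees = 60, seed = 3))
  expect_equal(b$models$nosing$max_f1, 1)
  pred <- predict_frames(b, ft)
  expect_equal(unname(pred$present[, "nosing"]), y)
})

test_that("shuffled labels give chance-level max F1 (permutation baseline)", {
  set.seed(20)
  n <- 400
  prev <- 0.3
  ft <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(ft) <- paste0("f", 1:5)
  f1s <- replicate(20, {
    y <- sample(c(rep(1L, n * prev), rep(0L, n * (1 - prev))))
    b <- train_classifiers(ft, data.frame(sniffing = y),
                           list(num_trees = 30, seed = sample.int(1e6, 1)))
    b$models$sniffing$max_f1
  })
  # a random scorer's best F1 concentrates near the all-positive point
  # 2 * prev / (1 + prev); far below 1, above prev itself
  expect_lt(mean(f1s), 0.62)
  expect_gt(mean(f1s), prev)
  expect_lt(abs(mean(f1s) - 2 * prev / (1 + prev)), 0.1)
})

test_that("eleven labeled behaviors give eleven fitted models; single-class ones are untrainable", {
  set.seed(30)
  n <- 200
  ft <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  names(ft) <- paste0("f", 1:4)
  labels <- as.data.frame(setNames(
    lapply(behavior_categories(), function(b) rbinom(n, 1, 0.3)),
    behavior_categories()))
  labels$mounting <- 0L    # never observed
  b <- train_classifiers(ft, labels, list(num_trees = 20, seed = 1))
  expect_length(b$models, 11)
  expect_true(b$models$mounting$untrainable)
  expect_false(b$models$fighting$untrainable)
  pred <- predict_frames(b, ft)
  expect_equal(dim(pred$present), c(n, 11))
  expect_true(all(pred$present[, "mounting"] == 0))
  expect_true(all(is.na(pred$probability[, "mounting"])))
})

test_that("pr_curve matches exhaustive counting at every distinct score", {
  set.seed(40)
  for (rep in 1:5) {
    n <- 50
    scores <- round(runif(n), 2)       # force ties
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) next
    curve <- pr_curve(scores, truth)
    expect_setequal(curve$threshold, unique(scores))
    for (i in seq_len(nrow(curve))) {
      oracle <- bf_pr_at(scores, truth, curve$threshold[i])
      expect_equal(curve$precision[i], unname(oracle["precision"]))
      expect_equal(curve$recall[i], unname(oracle["recall"]))
      expect_equal(curve$f1[i], unname(oracle["f1"]))
    }
  }
  expect_error(pr_curve(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("pr_curve worked examples match brute force", {
  # scores equal to the truth: perfect separation
  curve <- pr_curve(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(max(curve$f1), 1)
  expect_equal(curve$f1[curve$threshold == 1], 1)
  # mixed case: exhaustive enumeration gives max F1 = 0.8 at score 0.3
  # (all-positive point has F1 = 2/3; top-3 point P = 2/3, R = 1)
  curve2 <- pr_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
  expect_equal(max(curve2$f1), 0.8)
  expect_equal(curve2$threshold[which.max(curve2$f1)], 0.3)
  # anti-correlated scores: best move is to call everything positive
  curve3 <- pr_curve(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  prev <- 0.5
  expect_equal(max(curve3$f1), 2 * prev / (1 + prev))
  expect_equal(curve3$threshold[which.max(curve3$f1)], 0.1)
})

test_that("threshold selection breaks ties upward and reproduces its operating point under strict >", {
  # plateau of equal F1 -> the stricter (higher) curve point wins
  curve <- data.frame(threshold = c(0.2, 0.4, 0.6),
                      precision = 1, recall = 1, f1 = c(0.5, 0.7, 0.7))
  sel <- select_threshold(curve)
  expect_equal(sel$score, 0.6)
  expect_equal(sel$max_f1, 0.7)
  expect_equal(sel$threshold, 0.5)        # midpoint below the chosen score
  # monotone-decreasing F1 -> the lowest evaluated threshold
  curve2 <- data.frame(threshold = c(0.1, 0.5, 0.9),
                       precision = 1, recall = 1, f1 = c(0.9, 0.6, 0.2))
  sel2 <- select_threshold(curve2)
  expect_equal(sel2$score, 0.1)
  expect_equal(sel2$threshold, 0.05)
  # strict > at the returned threshold reproduces >= at the chosen score
  scores <- c(0.9, 0.8, 0.3, 0.2)
  truth <- c(1, 0, 1, 0)
  s3 <- select_threshold(pr_curve(scores, truth))
  expect_equal(bf_pr_at(scores, truth, s3$score)[["f1"]], s3$max_f1)
  expect_equal(as.integer(scores > s3$threshold),
               as.integer(scores >= s3$score))
  expect_error(select_threshold(data.frame()), "empty")
})

test_that("prediction uses strict >, monotone in the threshold, and errors on missing features", {
  set.seed(50)
  n <- 300
  ft <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(ft) <- paste0("f", 1:5)
  y <- as.integer(ft$f1 + 0.3 * rnorm(n) > 0)
  b <- train_classifiers(ft, data.frame(rearing = y),
                         list(num_trees = 40, seed = 6))
  pred <- predict_frames(b, ft)
  p1 <- pred$probability[1, "rearing"]
  # probability exactly equal to the threshold -> absent
  hit <- predict_frames(b, ft, config = list(rearing = list(
    detection_threshold = p1)))$present[1, "rearing"]
  expect_equal(unname(hit), 0L)
  # threshold 0: every frame with positive probability is positive
  all_pos <- predict_frames(b, ft, config = list(rearing = list(
    detection_threshold = 0)))$present[, "rearing"]
  expect_equal(unname(all_pos), as.integer(pred$probability[, "rearing"] > 0))
  # raising the threshold never increases the positive count
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(t) {
    sum(predict_frames(b, ft, config = list(rearing = list(
      detection_threshold = t)))$present[, "rearing"])
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(predict_frames(b, ft[, 1:3]), "f4")
})

test_that("training is reproducible under a fixed seed", {
  set.seed(60)
  n <- 200
  ft <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  names(ft) <- paste0("f", 1:4)
  labels <- data.frame(crawling = rbinom(n, 1, 0.4))
  b1 <- train_classifiers(ft, labels, list(num_trees = 30, seed = 11))
  b2 <- train_classifiers(ft, labels, list(num_trees = 30, seed = 11))
  expect_equal(b1$models$crawling$detection_threshold,
               b2$models$crawling$detection_threshold)
  expect_equal(predict_frames(b1, ft)$present, predict_frames(b2, ft)$present)
})

test_that("minimum bout filtering drops only sub-threshold runs", {
  hit <- c(1, 0, 1, 1, 0, 1, 1, 1, 0, 1)
  expect_equal(ratduet:::drop_short_bouts(hit, 2), c(0, 0, 1, 1, 0, 1, 1, 1, 0, 0))
  expect_equal(ratduet:::drop_short_bouts(hit, 0), hit)
})

test_that("classifiers trained on a few synthetic sessions recover behaviors in a new one (noise off)", {
  script_for <- function(seed) {
    set.seed(seed)
    behs <- behavior_categories()
    starts <- seq(2, 215, length.out = length(behs))
    data.frame(behavior = sample(behs), start_s = starts, end_s = starts + 14)
  }
  mk <- function(seed) {
    spec <- synth_session_spec(video_duration = 240, audio_duration = 240,
                               seed = seed, episode_script = script_for(seed))
    g <- generate_pose_track(spec, noise_px = 0, missing_rate = 0)
    list(ft = extract_features(interpolate_track(g$track)), truth = g$truth)
  }
  # several training sessions with different episode placements, so the
  # forests must learn the geometry rather than where episodes happened
  train <- lapply(c(101, 303, 404), mk)
  test <- mk(202)
  keep <- seq(1, 240 * 12, by = 2)
  ft <- do.call(rbind, lapply(train, function(s) as.data.frame(s$ft)[keep, ]))
  lab <- do.call(rbind, lapply(train, function(s) as.data.frame(s$truth)[keep, ]))
  b <- train_classifiers(ft, lab, list(num_trees = 40, seed = 1))
  pred <- predict_frames(b, test$ft)
  f1 <- vapply(behavior_categories(), function(beh) {
    p <- pred$present[, beh]
    y <- test$truth[, beh]
    tp <- sum(p == 1 & y == 1)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + sum(p == 1 & y == 0) + sum(p == 0 & y == 1))
  }, numeric(1))
  expect_true(all(f1 >= 0.8), info = paste(names(f1), round(f1, 2), collapse = "; "))
})

test_that("the threshold config round-trips through YAML", {
  set.seed(70)
  n <- 150
  ft <- as.data.frame(matrix(rnorm(n * 3), n, 3))
  names(ft) <- paste0("f", 1:3)
  b <- train_classifiers(ft, data.frame(grooming = rbinom(n, 1, 0.5)),
                         list(num_trees = 20, seed = 2))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_classifier_config(b, path)
  cfg <- read_classifier_config(path)
  expect_equal(cfg$grooming$detection_threshold,
               b$models$grooming$detection_threshold, tolerance = 1e-9)
  expect_equal(cfg$grooming$min_bout_frames, 0)
})
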