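# Session- and study-level orchestration: from raw CSVs to the aligned
# annotation table, epoch summaries and the ANOVA battery.

#' Align one session's behavior frames with its call events
#'
#' Builds the audio frame grid, marks call-type frames, recovers the
#' audio-video start lag from the index timestamps, trims both streams to
#' their common span and merges them into one frame annotation table.
#' Call event times are shifted onto the trimmed clock.
#'
#' @param behavior Data frame: `frame` plus per-behavior 0/1 (and optional
#'   probability) columns, one row per video frame.
#' @param calls Raw call table for the session (audio clock).
#' @param index_row The session's row of the index.
#' @return List: `annotations` (merged frame table), `calls` (typed,
#'   band-filtered, time-shifted and clipped to the common span) and
#'   `report` from [trim_to_common()].
#' @export
align_session <- function(behavior, calls, index_row) {
  fps <- index_row$fps %||% 12
  calls <- filter_calls(classify_calls(read_calls_if_path(calls)))
  n_audio <- audio_frame_grid(index_row$audio_duration_s, fps)
  grid <- mark_call_frames(n_audio, calls, fps)
  lag <- index_start_lag(index_row)
  tr <- trim_to_common(behavior, grid, lag, fps)
  ann <- merge_annotations(tr$video, tr$audio)
  # calls on the trimmed clock
  shift <- tr$report$head_cut_audio / fps
  calls$begin_s <- calls$begin_s - shift
  calls$end_s <- calls$end_s - shift
  span <- tr$report$common_frames / fps
  calls <- calls[calls$end_s > 0 & calls$begin_s < span, , drop = FALSE]
  calls$begin_s <- pmax(calls$begin_s, 0)
  calls$end_s <- pmin(calls$end_s, span)
  rownames(calls) <- NULL
  list(annotations = ann, calls = calls, report = tr$report)
}

read_calls_if_path <- function(calls) {
  if (is.character(calls)) read_call_csv(calls) else calls
}

#' Train classifiers on selected sessions of a study directory
#'
#' Pools the feature tables and synthetic ground-truth labels of the given
#' sessions and fits the per-behavior forests.
#'
#' @param dir Study directory written by [generate_study()].
#' @param sessions Data frame with `box`, `day`, `session_type` rows to
#'   train on; defaults to box A's day-1 sessions.
#' @param config Passed to [train_classifiers()].
#' @param thin Keep every `thin`-th frame of the pooled training data
#'   (1 = all frames).
#' @return A `behavior_classifiers` bundle.
#' @export
train_from_study <- function(dir, sessions = NULL, config = list(), thin = 1L) {
  index <- read_index_csv(file.path(dir, "index.csv"))
  if (is.null(sessions))
    sessions <- data.frame(box = "A", day = 1,
                           session_type = c("dark_to_light", "light_to_dark"))
  feats <- list()
  labs <- list()
  for (i in seq_len(nrow(sessions))) {
    row <- index[index$box == sessions$box[i] & index$day == sessions$day[i] &
                   index$session_type == sessions$session_type[i], ]
    if (!nrow(row)) stop("training session not in index: ",
                         paste(sessions[i, ], collapse = " "))
    ft <- session_features(dir, row)
    truth <- read.csv(file.path(dir, session_truth_file(row)))
    n <- min(nrow(ft), nrow(truth))
    keep <- seq(1L, n, by = thin)
    feats[[i]] <- as.data.frame(ft)[keep, , drop = FALSE]
    labs[[i]] <- truth[keep, behavior_categories(), drop = FALSE]
  }
  train_classifiers(do.call(rbind, feats), do.call(rbind, labs), config)
}

session_truth_file <- function(row) {
  sub("_pose\\.csv$", "_truth.csv", row$video_file)
}

session_features <- function(dir, row) {
  track <- read_pose_csv(file.path(dir, row$video_file), fps = row$fps %||% 12)
  extract_features(interpolate_track(track))
}

#' Analyze a whole study directory
#'
#' For every session in the index: preprocess the pose track, extract the
#' 111 features, predict per-frame behaviors (or take the stored synthetic
#' ground truth when `predictor = "truth"`), type and align the calls, and
#' aggregate 1-minute epoch durations.  Then collapse the design to 2x2
#' cell means and run the rank-ANOVA battery.
#'
#' @param dir Study directory written by [generate_study()].
#' @param bundle A `behavior_classifiers` bundle (required for
#'   `predictor = "classifier"`).
#' @param predictor `"classifier"` or `"truth"`.
#' @param keep_cooccurrence Also compute per-session co-occurrence sums.
#' @param change_epoch Last epoch before the light change (default 10).
#' @return List: `epochs` (long per-epoch durations), `cells` (2x2 cell
#'   means), `anova` (battery results), `alignment` (per-session trim
#'   reports), and optionally `cooccurrence`.
#' @export
analyze_study <- function(dir, bundle = NULL,
                          predictor = c("classifier", "truth"),
                          keep_cooccurrence = FALSE, change_epoch = 10) {
  predictor <- match.arg(predictor)
  if (predictor == "classifier" && is.null(bundle))
    stop("a classifier bundle is required unless predictor = 'truth'")
  index <- read_index_csv(file.path(dir, "index.csv"))
  epochs <- list()
  cooc <- list()
  reports <- list()
  for (i in seq_len(nrow(index))) {
    row <- index[i, ]
    fps <- row$fps %||% 12
    if (predictor == "classifier") {
      ft <- session_features(dir, row)
      pred <- predict_frames(bundle, ft)
      behavior <- data.frame(frame = seq_len(nrow(ft)))
      behavior <- cbind(behavior, as.data.frame(pred$present))
    } else {
      truth <- read.csv(file.path(dir, session_truth_file(row)))
      behavior <- truth[c("frame", behavior_categories())]
    }
    al <- align_session(behavior,
                        file.path(dir, row$audio_file), row)
    ep <- epoch_durations(al$annotations, fps, change_epoch = change_epoch)
    ep$box <- row$box
    ep$day <- row$day
    ep$session_type <- row$session_type
    epochs[[i]] <- ep
    reports[[i]] <- c(list(box = row$box, day = row$day,
                           session_type = row$session_type), al$report)
    if (keep_cooccurrence) {
      cs <- cooccurrence_sums(al$annotations, al$calls, fps)
      cs$box <- row$box
      cs$day <- row$day
      cs$session_type <- row$session_type
      cooc[[i]] <- cs
    }
  }
  epochs <- do.call(rbind, epochs)
  cells <- collapse_design(epochs, change_epoch = change_epoch)
  anova <- run_battery(cells)
  out <- list(epochs = epochs, cells = cells, anova = anova,
              alignment = do.call(rbind, lapply(reports, as.data.frame)))
  if (keep_cooccurrence) out$cooccurrence <- do.call(rbind, cooc)
  out
}
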