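# Whole synthetic study: boxes x days x two transition sessions, written to
# disk as pose CSVs, call CSVs, ground-truth CSVs and a session index.

.default_behavior_rates <- function() {
  # episodes per 10-minute half and episode duration range (s); chosen to
  # give every category non-trivial, zero-inflated per-epoch durations like
  # a real dyadic ethogram, while keeping total scheduling demand near 25%
  # of the half so episode placement never saturates
  data.frame(
    behavior = behavior_categories(),
    n_per_half = c(1, 4, 2, 2, 3, 2, 2, 4, 5, 2, 5),
    dur_min = c(20, 2, 3, 3, 4, 4, 3, 1, 2, 4, 2),
    dur_max = c(30, 4, 5, 6, 6, 8, 5, 2, 4, 8, 3),
    stringsAsFactors = FALSE
  )
}

.default_call_rates <- function() {
  # calls per minute by type
  c(ALARM = 0.2, FLAT = 3, FM = 5, SHORT = 1.5)
}

#' Generate a whole synthetic transition study
#'
#' Writes, for every box x day x session type, a pose CSV, a call CSV and a
#' ground-truth CSV (synthetic labels), plus a session index CSV and a
#' session-level ground-truth CSV (`study_truth.csv`, holding the true
#' audio-video offsets that the whole-second index timestamps cannot carry).
#'
#' The generator's defaults are the study conditions: 6 boxes, 6 days,
#' 20-minute sessions at 12 fps with the light change at 600 s, audio start
#' offsets uniform within +/- 2 s and audio durations differing from video by
#' up to ~2 s.  A lights-off effect is programmed into the light-to-dark
#' sessions: after minute 10 the fighting episode rate is multiplied by
#' `effect$fighting` and the ALARM/FLAT/SHORT call rates by their
#' multipliers, while all other categories keep symmetric rates.  This gives
#' downstream stages a known positive and known-null set of effects.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_boxes,n_days Study size; boxes are labelled A, B, C, ...
#' @param seed Integer seed for the whole study.
#' @param session_duration Video length (s); audio length varies around it.
#' @param fps Frames per second.
#' @param effect Named list of lights-off multipliers applied after minute 10
#'   of light-to-dark sessions: `fighting`, `ALARM`, `FLAT`, `SHORT`.
#' @param drop_sessions Optional data frame (`box`, `day`, `session_type`)
#'   of sessions to omit, emulating the availability calendars of a real
#'   study.
#' @param noise_px,missing_rate Passed to [generate_pose_track()].
#' @param start_date Date of day 1 (sessions at 05:50 and 17:50).
#' @return The session index data frame, invisibly; files under `out_dir`.
#' @export
generate_study <- function(out_dir,
                           n_boxes = 6, n_days = 6, seed = 1L,
                           session_duration = 1200, fps = 12,
                           effect = list(fighting = 5, ALARM = 8,
                                         FLAT = 3, SHORT = 3),
                           drop_sessions = NULL,
                           noise_px = 1.5, missing_rate = 0.05,
                           start_date = as.Date("2023-05-05")) {
  if (n_boxes < 1) stop("n_boxes must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  boxes <- LETTERS[seq_len(n_boxes)]
  half <- session_duration / 2

  index <- list()
  truth_rows <- list()
  k <- 0L
  for (b in seq_along(boxes)) {
    # per-box propensity: lognormal scatter shared by all of a box's sessions
    box_scale <- with_seed(seed + 7919L * b,
                           exp(rnorm(length(behavior_categories()), 0, 0.15)))
    names(box_scale) <- behavior_categories()
    for (day in seq_len(n_days)) {
      for (stype in c("dark_to_light", "light_to_dark")) {
        if (!is.null(drop_sessions) &&
            any(drop_sessions$box == boxes[b] & drop_sessions$day == day &
                drop_sessions$session_type == stype)) next
        k <- k + 1L
        sseed <- (seed + 7919L * b + 131L * day +
                    13L * (stype == "light_to_dark")) %% .Machine$integer.max
        sess <- with_seed(sseed, make_session(
          boxes[b], stype, day, session_duration, half, fps, sseed,
          box_scale, effect))
        files <- write_session(out_dir, sess, noise_px, missing_rate)
        nominal <- if (stype == "dark_to_light") "05:50:00" else "17:50:00"
        date <- start_date + (day - 1)
        vstart <- as.POSIXct(paste(date, nominal), tz = "UTC") + sess$video_frac
        astart <- vstart + sess$spec$start_offset
        index[[k]] <- data.frame(
          box = boxes[b], date = as.character(date), day = day,
          session_type = stype,
          video_file = files$pose, audio_file = files$calls,
          video_start_iso = format(trunc(vstart, "secs"), "%Y-%m-%dT%H:%M:%S"),
          audio_start_iso = format(trunc(astart, "secs"), "%Y-%m-%dT%H:%M:%S"),
          video_duration_s = sess$spec$video_duration,
          audio_duration_s = sess$spec$audio_duration,
          fps = fps, stringsAsFactors = FALSE)
        truth_rows[[k]] <- data.frame(
          box = boxes[b], day = day, session_type = stype,
          true_offset_s = sess$spec$start_offset,
          truth_file = files$truth, stringsAsFactors = FALSE)
      }
    }
  }
  index <- do.call(rbind, index)
  write_index_csv(index, file.path(out_dir, "index.csv"))
  write.csv(do.call(rbind, truth_rows),
            file.path(out_dir, "study_truth.csv"), row.names = FALSE)
  attr(index, "early_late_available") <- n_days >= 4
  if (n_days < 4)
    warning("fewer than 4 days: early/late phase contrast unavailable")
  invisible(index)
}

# draw one session's scripts and spec (RNG already seeded by caller)
make_session <- function(box, stype, day, session_duration, half, fps, sseed,
                         box_scale, effect) {
  rates <- .default_behavior_rates()
  # draw all episode demands first, then place them in random order:
  # episodes in a generated study never overlap, so each frame's geometry
  # belongs to exactly one behavior, and any residual crowding pressure is
  # spread evenly over categories instead of loading onto the last ones
  wanted <- list()
  for (i in seq_len(nrow(rates))) {
    beh <- rates$behavior[i]
    for (h in 1:2) {
      lambda <- rates$n_per_half[i] * box_scale[[beh]]
      if (beh == "fighting" && stype == "light_to_dark" && h == 2)
        lambda <- lambda * (effect$fighting %||% 1)
      n_ep <- rpois(1, lambda)
      for (e in seq_len(n_ep)) {
        dur <- min(runif(1, rates$dur_min[i], rates$dur_max[i]), 0.8 * half)
        wanted[[length(wanted) + 1]] <- list(behavior = beh, half = h,
                                             dur = dur)
      }
    }
  }
  placed <- empty_episode_script()
  for (w in sample(wanted)) {
    for (try in 1:50) {
      start <- runif(1, (w$half - 1) * half,
                     max((w$half - 1) * half, w$half * half - w$dur))
      cand <- data.frame(behavior = w$behavior, start_s = start,
                         end_s = start + w$dur, stringsAsFactors = FALSE)
      if (!overlaps_any(cand, placed)) {
        placed <- rbind(placed, cand)
        break
      }
    }
  }
  script <- placed[order(placed$start_s), , drop = FALSE]
  rownames(script) <- NULL

  crates <- .default_call_rates()
  calls <- list()
  for (tp in names(crates)) {
    for (h in 1:2) {
      r <- crates[[tp]]
      if (stype == "light_to_dark" && h == 2 && tp %in% c("ALARM", "FLAT", "SHORT"))
        r <- r * (effect[[tp]] %||% 1)
      calls[[length(calls) + 1]] <- data.frame(
        type = tp, window_start_s = (h - 1) * half, window_end_s = h * half,
        rate_per_min = r, n = NA_real_, stringsAsFactors = FALSE)
    }
  }
  call_script <- do.call(rbind, calls)

  video_duration <- session_duration + runif(1, 0, 0.3)
  audio_duration <- video_duration + runif(1, -2, 2)
  offset <- runif(1, -2, 2)
  spec <- synth_session_spec(
    box_id = box, session_type = stype, day = day,
    video_duration = video_duration, audio_duration = audio_duration,
    start_offset = offset, fps = fps, seed = sseed,
    episode_script = script, call_script = call_script)
  list(spec = spec, video_frac = runif(1))
}

# does a candidate episode overlap any placed episode (with a 1-frame berth)?
overlaps_any <- function(cand, placed, berth = 0.1) {
  if (!nrow(placed)) return(FALSE)
  any(placed$start_s - berth < cand$end_s &
        cand$start_s < placed$end_s + berth)
}

write_session <- function(out_dir, sess, noise_px, missing_rate) {
  spec <- sess$spec
  stub <- sprintf("%s_day%02d_%s", spec$box_id, spec$day, spec$session_type)
  pose_file <- paste0(stub, "_pose.csv")
  call_file <- paste0(stub, "_calls.csv")
  truth_file <- paste0(stub, "_truth.csv")

  g <- generate_pose_track(spec, noise_px = noise_px,
                           missing_rate = missing_rate)
  write_pose_csv(g$track, file.path(out_dir, pose_file))
  truth <- as.data.frame(g$truth)
  truth <- cbind(frame = seq_len(nrow(truth)), truth)
  write.csv(truth, file.path(out_dir, truth_file), row.names = FALSE)

  ct <- generate_call_table(spec)
  calls <- ct$calls
  calls$scripted_type <- ct$truth
  write_call_csv(calls, file.path(out_dir, call_file))

  list(pose = pose_file, calls = call_file, truth = truth_file)
}
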