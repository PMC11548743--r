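#' Define a synthetic transition session
#'
#' A session spec describes one 20-minute light/dark transition recording of
#' a rat pair: the video/audio clocks, the scripted behavior episodes and the
#' scripted ultrasonic call bouts.  Everything downstream (pose track, call
#' table, ground truth) is derived deterministically from the spec and its
#' seed.
#'
#' @param box_id Box label, e.g. `"A"`.
#' @param session_type `"dark_to_light"` or `"light_to_dark"`.
#' @param day Experimental day, integer 1-6.
#' @param video_duration Video length in seconds (default 1200 s = 20 min).
#' @param audio_duration Audio length in seconds; must be within 5 s of the
#'   video length (recorders drift by seconds, not minutes).
#' @param start_offset Audio start minus video start, seconds.
#' @param fps Video frame rate (frames/second); the study standard is 12.
#' @param seed Integer seed; identical specs with identical seeds regenerate
#'   byte-identical data.
#' @param episode_script Data frame with columns `behavior`, `start_s`,
#'   `end_s`: scripted ground-truth behavior episodes (video clock).
#'   Episodes of different behaviors may overlap unless their postures
#'   contradict (e.g. adjacent lying and following).
#' @param call_script Data frame with columns `type`, `window_start_s`,
#'   `window_end_s` and either `rate_per_min` (Poisson counts) or `n`
#'   (exact counts): scripted call bouts (audio clock).
#'
#' @return An object of class `synth_session_spec`.
#' @export
synth_session_spec <- function(box_id = "A",
                               session_type = c("light_to_dark", "dark_to_light"),
                               day = 1L,
                               video_duration = 1200,
                               audio_duration = video_duration,
                               start_offset = 0,
                               fps = 12,
                               seed = 1L,
                               episode_script = empty_episode_script(),
                               call_script = empty_call_script()) {
  session_type <- match.arg(session_type)
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  if (video_duration <= 0 || audio_duration <= 0) stop("durations must be > 0")
  if (abs(audio_duration - video_duration) > 5)
    stop("audio and video durations differ by more than 5 s")
  if (!is.numeric(day) || day < 1) stop("day must be a positive integer")

  episode_script <- validate_episode_script(episode_script, video_duration)
  call_script <- validate_call_script(call_script, audio_duration)

  structure(list(
    box_id = as.character(box_id),
    session_type = session_type,
    day = as.integer(day),
    video_duration = video_duration,
    audio_duration = audio_duration,
    start_offset = start_offset,
    fps = fps,
    seed = as.integer(seed),
    episode_script = episode_script,
    call_script = call_script
  ), class = "synth_session_spec")
}

#' @rdname synth_session_spec
#' @export
empty_episode_script <- function() {
  data.frame(behavior = character(), start_s = numeric(), end_s = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname synth_session_spec
#' @export
empty_call_script <- function() {
  data.frame(type = character(), window_start_s = numeric(),
             window_end_s = numeric(), rate_per_min = numeric(),
             n = numeric(), stringsAsFactors = FALSE)
}

validate_episode_script <- function(script, video_duration) {
  script <- as.data.frame(script, stringsAsFactors = FALSE)
  needed <- c("behavior", "start_s", "end_s")
  if (!all(needed %in% names(script)))
    stop("episode_script needs columns: ", paste(needed, collapse = ", "))
  if (nrow(script) == 0) return(script[needed])
  bad <- setdiff(script$behavior, behavior_categories())
  if (length(bad)) stop("unknown behaviors in script: ", paste(bad, collapse = ", "))
  if (any(script$start_s < 0) || any(script$end_s > video_duration) ||
      any(script$end_s <= script$start_s))
    stop("episode intervals must satisfy 0 <= start < end <= video_duration")
  for (pair in .conflicting_behaviors) {
    a <- script[script$behavior == pair[1], , drop = FALSE]
    b <- script[script$behavior == pair[2], , drop = FALSE]
    if (nrow(a) && nrow(b)) {
      for (i in seq_len(nrow(a))) {
        overlap <- pmin(a$end_s[i], b$end_s) - pmax(a$start_s[i], b$start_s)
        if (any(overlap > 0))
          stop("mutually exclusive postures overlap in episode_script: ",
               pair[1], " and ", pair[2])
      }
    }
  }
  script[needed]
}

validate_call_script <- function(script, audio_duration) {
  script <- as.data.frame(script, stringsAsFactors = FALSE)
  if (!"rate_per_min" %in% names(script)) script$rate_per_min <- NA_real_
  if (!"n" %in% names(script)) script$n <- NA_real_
  needed <- c("type", "window_start_s", "window_end_s", "rate_per_min", "n")
  if (!all(needed %in% names(script)))
    stop("call_script needs columns: type, window_start_s, window_end_s and rate_per_min or n")
  if (nrow(script) == 0) return(script[needed])
  bad <- setdiff(script$type, call_types())
  if (length(bad)) stop("unknown call types in script: ", paste(bad, collapse = ", "))
  if (any(!is.na(script$rate_per_min) & script$rate_per_min < 0))
    stop("negative call rate")
  if (any(!is.na(script$n) & script$n < 0)) stop("negative call count")
  if (any(is.na(script$rate_per_min) & is.na(script$n)))
    stop("each call_script row needs rate_per_min or n")
  if (any(script$window_start_s < 0) ||
      any(script$window_end_s <= script$window_start_s))
    stop("call windows must satisfy 0 <= start < end")
  script$window_end_s <- pmin(script$window_end_s, audio_duration)
  script[needed]
}

#' @export
print.synth_session_spec <- function(x, ...) {
  cat("<synth_session_spec> box", x$box_id, "day", x$day, x$session_type, "\n")
  cat("  video", x$video_duration, "s / audio", x$audio_duration,
      "s @", x$fps, "fps; audio offset", x$start_offset, "s; seed", x$seed, "\n")
  cat("  ", nrow(x$episode_script), "scripted episodes,",
      nrow(x$call_script), "scripted call bouts\n")
  invisible(x)
}
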