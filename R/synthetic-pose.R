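# Synthetic two-rat pose tracks with scripted ground truth.
#
# Rats are modeled as a rigid 2-segment body axis (nose -> tail) carrying the
# 12 tracked parts at fixed offsets (see .skeleton_plan).  Each rat follows a
# smooth random walk; scripted behavior episodes override position, heading,
# posture (hull contraction, head bend) and per-frame agitation so that every
# behavior produces the geometric signature its classifier relies on.

ARENA_PX <- 500      # 50 x 50 cm box at a nominal 10 px/cm
BODY_LEN_PX <- 160   # nose-to-tail-end body length

#' Generate a synthetic pose track with ground truth
#'
#' Emits a two-animal, 12-keypoint track of `floor(video_duration * fps)`
#' frames together with the per-frame ground-truth matrix for the 11 behavior
#' categories.  Coordinates are pixels in a 500 x 500 px arena (origin
#' top-left, y downward).  Keypoints are jittered by Gaussian pixel noise and
#' a fraction of keypoints is marked untrustworthy (likelihood below the
#' usual 0.6 cutoff) with their coordinates retained.
#'
#' @param spec A [synth_session_spec()].
#' @param noise_px Gaussian jitter SD applied to every keypoint (px).
#'   `0` gives noise-free geometry (agitation programmed by behaviors such as
#'   fighting is part of the signal and remains).
#' @param missing_rate Fraction of keypoint observations flagged as
#'   low-likelihood.
#' @return A list with `track` (a `pose_track` data frame: `frame` plus 72
#'   keypoint columns `<animal>_<part>_<x|y|p>`) and `truth` (frames x 11
#'   binary matrix, one column per behavior).
#' @examples
#' spec <- synth_session_spec(video_duration = 10, audio_duration = 10, seed = 7)
#' g <- generate_pose_track(spec)
#' dim(g$track); colSums(g$truth)
#' @export
generate_pose_track <- function(spec, noise_px = 1.5, missing_rate = 0.05) {
  stopifnot(inherits(spec, "synth_session_spec"))
  n <- floor(spec$video_duration * spec$fps)
  if (n < 1) stop("spec yields an empty track")

  with_seed(spec$seed, {
    st <- base_motion(n, spec$fps)          # per-rat state arrays
    truth <- matrix(0L, n, length(behavior_categories()),
                    dimnames = list(NULL, behavior_categories()))

    script <- spec$episode_script
    if (nrow(script)) {
      for (i in seq_len(nrow(script))) {
        f0 <- max(1L, floor(script$start_s[i] * spec$fps) + 1L)
        f1 <- min(n, ceiling(script$end_s[i] * spec$fps))
        if (f1 < f0) next
        frames <- f0:f1
        truth[frames, script$behavior[i]] <- 1L
        st <- apply_episode(st, script$behavior[i], frames, spec$fps)
      }
    }

    track <- realize_skeleton(st, n, noise_px, missing_rate)
    track <- as_pose_track(track, fps = spec$fps)
    list(track = track, truth = truth)
  })
}

# smooth correlated random walk for both rats
base_motion <- function(n, fps) {
  st <- list()
  for (a in animal_ids()) {
    theta <- cumsum(rnorm(n, 0, 0.08)) + runif(1, 0, 2 * pi)
    # amble speed waxes and wanes on a ~minute scale
    speed <- 1.5 * (0.5 + 0.5 * sin(seq_len(n) / (8 * fps) + runif(1, 0, 6))^2)
    x <- numeric(n); y <- numeric(n)
    x[1] <- runif(1, 120, ARENA_PX - 120)
    y[1] <- runif(1, 120, ARENA_PX - 120)
    for (i in seq_len(n - 1)) {
      x[i + 1] <- x[i] + speed[i] * cos(theta[i])
      y[i + 1] <- y[i] + speed[i] * sin(theta[i])
      # reflect off walls (keep a body-half margin)
      if (x[i + 1] < 90 || x[i + 1] > ARENA_PX - 90) {
        theta[(i + 1):n] <- pi - theta[(i + 1):n]
        x[i + 1] <- min(max(x[i + 1], 90), ARENA_PX - 90)
      }
      if (y[i + 1] < 90 || y[i + 1] > ARENA_PX - 90) {
        theta[(i + 1):n] <- -theta[(i + 1):n]
        y[i + 1] <- min(max(y[i + 1], 90), ARENA_PX - 90)
      }
    }
    st[[a]] <- list(cx = x, cy = y, theta = theta,
                    contract = rep(1, n), headbend = rep(FALSE, n),
                    agitation = rep(0, n))
  }
  st
}

# place both rats in the configuration characteristic of `behavior`
apply_episode <- function(st, behavior, frames, fps) {
  m <- length(frames)
  L <- BODY_LEN_PX
  anchor <- c(runif(1, 140, ARENA_PX - 140), runif(1, 140, ARENA_PX - 140))
  phi <- runif(1, 0, 2 * pi)
  dir <- c(cos(phi), sin(phi))
  perp <- c(-sin(phi), cos(phi))

  set_rat <- function(st, a, cx, cy, theta, contract = 1, headbend = FALSE,
                      agitation = 0.3) {
    st[[a]]$cx[frames] <- cx
    st[[a]]$cy[frames] <- cy
    st[[a]]$theta[frames] <- theta
    st[[a]]$contract[frames] <- contract
    st[[a]]$headbend[frames] <- headbend
    st[[a]]$agitation[frames] <- agitation
    st
  }

  switch(behavior,
    adjacent_lying = {
      st <- set_rat(st, "A", anchor[1] + 25 * perp[1], anchor[2] + 25 * perp[2], phi)
      st <- set_rat(st, "B", anchor[1] - 25 * perp[1], anchor[2] - 25 * perp[2], phi)
    },
    anogenital_sniffing = {
      # B stands still; A's nose is placed at B's anogenital keypoint
      st <- set_rat(st, "B", anchor[1], anchor[2], phi)
      ag <- anchor - 0.28 * L * dir          # B's anogenital point
      st <- set_rat(st, "A", ag[1] - 0.5 * L * dir[1], ag[2] - 0.5 * L * dir[2],
                    phi, agitation = 0.6)
    },
    crawling = {
      st <- set_rat(st, "B", anchor[1], anchor[2], phi, agitation = 1)
      st <- set_rat(st, "A", anchor[1] + 8 * perp[1], anchor[2] + 8 * perp[2],
                    phi + pi / 2, contract = 0.9, agitation = 1.5)
    },
    fighting = {
      # tight tumbling pair: both centers jiggle hard around the anchor
      clamp <- function(v) pmin(pmax(v, 90), ARENA_PX - 90)
      st <- set_rat(st, "A",
                    clamp(anchor[1] + 18 * dir[1] + cumsum(rnorm(m, 0, 6))),
                    clamp(anchor[2] + 18 * dir[2] + cumsum(rnorm(m, 0, 6))),
                    phi, agitation = 12)
      st <- set_rat(st, "B",
                    clamp(anchor[1] - 18 * dir[1] + cumsum(rnorm(m, 0, 6))),
                    clamp(anchor[2] - 18 * dir[2] + cumsum(rnorm(m, 0, 6))),
                    phi + pi, agitation = 12)
    },
    following = {
      # leader B walks a curving path, A trails one body length behind
      speed <- 7
      lag <- max(1L, round(0.9 * L / speed))
      hd <- phi + cumsum(rnorm(m + lag, 0, 0.03))
      px <- anchor[1] + cumsum(speed * cos(hd))
      py <- anchor[2] + cumsum(speed * sin(hd))
      px <- reflect_path(px); py <- reflect_path(py)
      idx <- (lag + 1):(lag + m)
      st <- set_rat(st, "B", px[idx], py[idx], hd[idx], agitation = 1)
      st <- set_rat(st, "A", px[idx - lag], py[idx - lag], hd[idx - lag],
                    agitation = 1)
    },
    grooming = {
      st <- set_rat(st, "B", anchor[1], anchor[2], phi, agitation = 0.2)
      bk <- anchor + 0.10 * L * dir          # B's back keypoint
      ahead <- phi + pi / 2
      st <- set_rat(st, "A",
                    bk[1] - 0.5 * L * cos(ahead), bk[2] - 0.5 * L * sin(ahead),
                    ahead, agitation = 0.8)
    },
    mounting = {
      st <- set_rat(st, "B", anchor[1], anchor[2], phi, agitation = 0.4)
      st <- set_rat(st, "A", anchor[1] + 5 * dir[1], anchor[2] + 5 * dir[2],
                    phi, contract = 0.8, agitation = 0.4)
    },
    nosing = {
      gap <- 3
      st <- set_rat(st, "A", anchor[1] - (0.5 * L + gap) * dir[1],
                    anchor[2] - (0.5 * L + gap) * dir[2], phi, agitation = 0.4)
      st <- set_rat(st, "B", anchor[1] + (0.5 * L + gap) * dir[1],
                    anchor[2] + (0.5 * L + gap) * dir[2], phi + pi, agitation = 0.4)
    },
    rearing = {
      # only one animal rears: body hull shrinks sharply
      st <- set_rat(st, "A", anchor[1], anchor[2], phi, contract = 0.4,
                    agitation = 0.5)
    },
    self_grooming = {
      st <- set_rat(st, "A", anchor[1], anchor[2], phi, headbend = TRUE,
                    agitation = 1)
    },
    sniffing = {
      # A's nose at B's flank (the `middle` keypoint), approaching sideways
      st <- set_rat(st, "B", anchor[1], anchor[2], phi, agitation = 0.3)
      ahead <- phi - pi / 2
      st <- set_rat(st, "A",
                    anchor[1] - 0.5 * L * cos(ahead) - 4 * cos(ahead),
                    anchor[2] - 0.5 * L * sin(ahead) - 4 * sin(ahead),
                    ahead, agitation = 0.5)
    },
    stop("unknown behavior: ", behavior)
  )
  st
}

reflect_path <- function(p, lo = 90, hi = ARENA_PX - 90) {
  # fold a free path back into [lo, hi] (triangle-wave reflection)
  w <- hi - lo
  q <- (p - lo) %% (2 * w)
  lo + ifelse(q > w, 2 * w - q, q)
}

# turn per-rat state into the 72 keypoint columns
realize_skeleton <- function(st, n, noise_px, missing_rate) {
  out <- vector("list", 1 + 72)
  out[[1]] <- seq_len(n)
  names(out)[1] <- "frame"
  k <- 2
  plan <- .skeleton_plan
  for (a in animal_ids()) {
    s <- st[[a]]
    cosT <- cos(s$theta); sinT <- sin(s$theta)
    agit_x <- s$agitation * rnorm(n)
    agit_y <- s$agitation * rnorm(n)
    for (j in seq_len(nrow(plan))) {
      along <- rep(plan$along[j], n)
      lateral <- rep(plan$lateral[j], n)
      if (plan$part[j] %in% c("nose", "eye_left", "eye_right", "head")) {
        bent <- s$headbend
        along[bent] <- -0.5 * along[bent]
        lateral[bent] <- lateral[bent] + 0.10
      }
      along <- along * s$contract
      lateral <- lateral * s$contract
      dx <- along * BODY_LEN_PX
      dy <- lateral * BODY_LEN_PX
      x <- s$cx + dx * cosT - dy * sinT + agit_x + noise_px * rnorm(n)
      y <- s$cy + dx * sinT + dy * cosT + agit_y + noise_px * rnorm(n)
      miss <- runif(n) < missing_rate
      p <- ifelse(miss, runif(n, 0, 0.5), runif(n, 0.85, 1))
      cols <- .kp_cols(a, plan$part[j])
      out[[k]] <- x; names(out)[k] <- cols[1]; k <- k + 1
      out[[k]] <- y; names(out)[k] <- cols[2]; k <- k + 1
      out[[k]] <- p; names(out)[k] <- cols[3]; k <- k + 1
    }
  }
  as.data.frame(out, check.names = FALSE)
}

#' Construct a pose_track object
#'
#' @param df Data frame with a `frame` column and the 72 keypoint columns
#'   `<animal>_<part>_<x|y|p>` in canonical order.
#' @param fps Frames per second.
#' @return `df` with class `pose_track` and an `fps` attribute.
#' @export
as_pose_track <- function(df, fps) {
  missing_cols <- setdiff(c("frame", .track_cols()), names(df))
  if (length(missing_cols))
    stop("not a pose track; missing columns: ",
         paste(head(missing_cols, 5), collapse = ", "))
  df <- df[c("frame", .track_cols())]
  attr(df, "fps") <- fps
  class(df) <- c("pose_track", "data.frame")
  df
}

#' @rdname as_pose_track
#' @param x A `pose_track`.
#' @export
track_fps <- function(x) {
  fps <- attr(x, "fps")
  if (is.null(fps)) stop("track has no fps attribute")
  fps
}
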