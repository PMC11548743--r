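#' Clean a raw pose track
#'
#' Coordinates whose detection likelihood falls below `p_cutoff` are treated
#' as missing and replaced by the temporally nearest observed value of the
#' same series (ties break toward the earlier frame, which also governs the
#' leading/trailing fill).  A keypoint that is never observed above the
#' cutoff in the whole session is set to 0 for all frames.  Outlier
#' correction is deliberately not performed.
#'
#' Interpolation is idempotent and never invents values outside the observed
#' range of a series.
#'
#' @param raw A `pose_track` (see [as_pose_track()]).
#' @param p_cutoff Likelihood below which a detection is untrusted
#'   (default 0.6, the usual pose-estimation cutoff).
#' @return A `pose_track` with no untrusted coordinates left; likelihood
#'   columns are retained unchanged for the downstream probability features.
#' @examples
#' spec <- synth_session_spec(video_duration = 5, audio_duration = 5, seed = 2)
#' tr <- generate_pose_track(spec, missing_rate = 0.2)$track
#' clean <- interpolate_track(tr)
#' @export
interpolate_track <- function(raw, p_cutoff = 0.6) {
  stopifnot(inherits(raw, "pose_track"))
  if (nrow(raw) < 1) stop("empty track")
  out <- raw
  zero_filled <- character()
  for (a in animal_ids()) {
    for (bp in body_parts()) {
      cols <- .kp_cols(a, bp)
      ok <- raw[[cols[3]]] >= p_cutoff
      if (!any(ok)) zero_filled <- c(zero_filled, paste0(a, "_", bp))
      for (cc in cols[1:2]) {
        out[[cc]] <- fill_nearest(raw[[cc]], ok)
      }
    }
  }
  attr(out, "zero_filled") <- zero_filled
  out
}

# replace entries where !ok by the nearest ok entry (ties -> earlier frame);
# all-missing series -> 0
fill_nearest <- function(x, ok) {
  if (all(ok)) return(x)
  if (!any(ok)) return(rep(0, length(x)))
  obs <- which(ok)
  n <- length(x)
  pos <- seq_len(n)
  ip <- findInterval(pos, obs)                  # last observed index <= pos
  prev <- ifelse(ip >= 1L, obs[pmax(ip, 1L)], NA_integer_)
  nxt <- ifelse(ip + 1L <= length(obs),
                obs[pmin(ip + 1L, length(obs))], NA_integer_)
  d_prev <- pos - prev
  d_next <- nxt - pos
  pick_prev <- !is.na(prev) & (is.na(nxt) | d_prev <= d_next)
  src <- ifelse(pick_prev, prev, nxt)
  out <- x[src]
  out[ok] <- x[ok]
  out
}

#' Expose a preprocessed track as plain per-frame arrays
#'
#' Returns the coordinate and likelihood columns in the fixed canonical
#' order (animal A then B, each part in skeleton order, x/y/likelihood),
#' with the frame index preserved -- the contract consumed by the feature
#' stage.
#'
#' @param track A preprocessed `pose_track`.
#' @return A list with `frame`, `xy` (frames x 48 matrix of coordinates),
#'   `p` (frames x 24 matrix of likelihoods) and `fps`.
#' @export
to_feature_input <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  cols <- .track_cols()
  xy_cols <- cols[!grepl("_p$", cols)]
  p_cols <- cols[grepl("_p$", cols)]
  list(frame = track$frame,
       xy = as.matrix(track[xy_cols]),
       p = as.matrix(track[p_cols]),
       fps = track_fps(track))
}
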