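# Per-frame feature extraction: 2 polygon features + 109 custom features.

.centroid_members <- list(
  body = body_parts(),
  head = c("nose", "eye_left", "eye_right", "head"),
  ag   = c("pelvis", "anogenital", "tail_middle")
)

#' Polygon features: body-hull overlap and area difference
#'
#' For every frame, each animal's body polygon is the convex hull of its 12
#' keypoints.  `polygon_pct_overlap` is `100 * intersection_area /
#' min(area_A, area_B)` (the smaller-hull denominator captures one animal on
#' top of the other during mounting/crawling; set `denominator = "union"`
#' for a Jaccard-style overlap).  `difference_area` is `|area_A - area_B|`
#' in px^2.  A degenerate hull (fewer than 3 distinct points) has area 0 and
#' produces overlap 0.
#'
#' @param track A preprocessed `pose_track`.
#' @param denominator `"min"` (default) or `"union"`.
#' @param hulls Precomputed per-frame hull matrix (internal reuse).
#' @return Data frame with columns `polygon_pct_overlap` (0-100) and
#'   `difference_area` (px^2), one row per frame.
#' @export
polygon_features <- function(track, denominator = c("min", "union"),
                             hulls = NULL) {
  stopifnot(inherits(track, "pose_track"))
  denominator <- match.arg(denominator)
  if (is.null(hulls)) hulls <- frame_hulls(track)
  area_a <- hulls[, "body_area_A"]
  area_b <- hulls[, "body_area_B"]
  inter <- hulls[, "intersection_area"]
  denom <- if (denominator == "min") pmin(area_a, area_b) else
    area_a + area_b - inter
  overlap <- ifelse(denom > 0, 100 * inter / denom, 0)
  data.frame(polygon_pct_overlap = overlap,
             difference_area = abs(area_a - area_b))
}

#' Body-part centroids
#'
#' Three centroids per animal and frame: whole body (all 12 parts), head
#' (nose, both eyes, head) and anogenital region (pelvis, anogenital, tail
#' middle).  Parts zero-filled as wholly missing for the session are
#' excluded from the mean; if every member of a centroid is zero-filled the
#' centroid is (0, 0).
#'
#' @param track A preprocessed `pose_track`.
#' @return Data frame with columns `ctr_<kind>_<animal>_<x|y>` for kind in
#'   body/head/ag and animal in A/B, one row per frame.
#' @export
centroids <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  zf_attr <- attr(track, "zero_filled")
  out <- list()
  for (a in animal_ids()) {
    zero_filled <- if (!is.null(zf_attr)) {
      # the preprocessing step recorded which parts it zero-filled
      setNames(paste0(a, "_", body_parts()) %in% zf_attr, body_parts())
    } else {
      # tracks from disk: a keypoint frozen at the origin for the whole
      # session can only be a fill
      vapply(body_parts(), function(bp) {
        cols <- .kp_cols(a, bp)
        all(track[[cols[1]]] == 0) && all(track[[cols[2]]] == 0)
      }, logical(1))
    }
    for (kind in names(.centroid_members)) {
      members <- .centroid_members[[kind]]
      use <- members[!zero_filled[members]]
      nm <- paste0("ctr_", kind, "_", a)
      if (!length(use)) {
        out[[paste0(nm, "_x")]] <- rep(0, nrow(track))
        out[[paste0(nm, "_y")]] <- rep(0, nrow(track))
      } else {
        xs <- as.matrix(track[paste0(a, "_", use, "_x")])
        ys <- as.matrix(track[paste0(a, "_", use, "_y")])
        out[[paste0(nm, "_x")]] <- rowMeans(xs)
        out[[paste0(nm, "_y")]] <- rowMeans(ys)
      }
    }
  }
  as.data.frame(out)
}

#' The 109 custom per-frame features
#'
#' Fixed inventory spanning every feature family the classifier stage
#' relies on: the 24 raw keypoint likelihoods; 12 centroid coordinates and
#' their 1-s rolling means; body and head convex-hull areas, rolling means
#' and change ratios; per-frame and 1-s rolling centroid movements plus a
#' both-animals total; all 9 between-animal centroid distances, their
#' rolling means and minimum; nose-to-nose and nose-to-anogenital keypoint
#' distances; within-animal posture distances and elongation; axial angles;
#' and per-animal likelihood summaries.  Rolling windows are trailing,
#' `fps` frames (1 s), truncated at the session start.  See
#' [feature_manifest()] for the machine-readable inventory.
#'
#' @param track A preprocessed `pose_track` carrying its `fps`.
#' @param hulls Precomputed per-frame hull matrix (internal reuse).
#' @return Data frame with exactly 109 numeric columns, one row per frame.
#' @export
custom_features <- function(track, hulls = NULL) {
  stopifnot(inherits(track, "pose_track"))
  fps <- track_fps(track)
  w <- max(1L, as.integer(round(fps)))
  n <- nrow(track)
  f <- list()

  # -- 24 keypoint likelihoods
  for (a in animal_ids()) for (bp in body_parts())
    f[[paste0("prob_", a, "_", bp)]] <- track[[.kp_cols(a, bp)[3]]]

  # -- centroids: 12 coordinates + 12 rolling means
  ctr <- centroids(track)
  for (nm in names(ctr)) f[[nm]] <- ctr[[nm]]
  for (nm in names(ctr)) f[[paste0(nm, "_roll")]] <- roll_mean_trail(ctr[[nm]], w)

  # -- hull areas: 4 + 4 rolling + 2 body change ratios
  if (is.null(hulls)) hulls <- frame_hulls(track)
  for (a in animal_ids()) {
    f[[paste0("hull_body_", a)]] <- hulls[, paste0("body_area_", a)]
    f[[paste0("hull_head_", a)]] <- hulls[, paste0("head_area_", a)]
  }
  for (a in animal_ids()) {
    f[[paste0("hull_body_", a, "_roll")]] <-
      roll_mean_trail(f[[paste0("hull_body_", a)]], w)
    f[[paste0("hull_head_", a, "_roll")]] <-
      roll_mean_trail(f[[paste0("hull_head_", a)]], w)
  }
  for (a in animal_ids()) {
    rm_ <- f[[paste0("hull_body_", a, "_roll")]]
    f[[paste0("hull_body_", a, "_ratio")]] <-
      ifelse(rm_ > 0, f[[paste0("hull_body_", a)]] / rm_, 1)
  }

  # -- movements: 6 per-frame + 6 rolling sums + 1 total
  mov_names <- character()
  for (a in animal_ids()) for (kind in names(.centroid_members)) {
    cx <- ctr[[paste0("ctr_", kind, "_", a, "_x")]]
    cy <- ctr[[paste0("ctr_", kind, "_", a, "_y")]]
    mv <- c(0, euclid(cx[-1], cy[-1], cx[-n], cy[-n]))
    nm <- paste0("mov_", kind, "_", a)
    f[[nm]] <- mv
    mov_names <- c(mov_names, nm)
  }
  for (nm in mov_names) f[[paste0(nm, "_roll")]] <- roll_sum_trail(f[[nm]], w)
  f[["mov_total"]] <- f[["mov_body_A"]] + f[["mov_body_B"]]

  # -- between-animal centroid distances: 9 + 9 rolling + min
  dist_names <- character()
  for (ka in names(.centroid_members)) for (kb in names(.centroid_members)) {
    nm <- paste0("d_", ka, "A_", kb, "B")
    f[[nm]] <- euclid(ctr[[paste0("ctr_", ka, "_A_x")]],
                      ctr[[paste0("ctr_", ka, "_A_y")]],
                      ctr[[paste0("ctr_", kb, "_B_x")]],
                      ctr[[paste0("ctr_", kb, "_B_y")]])
    dist_names <- c(dist_names, nm)
  }
  for (nm in dist_names) f[[paste0(nm, "_roll")]] <- roll_mean_trail(f[[nm]], w)
  f[["d_min_centroids"]] <- do.call(pmin, f[dist_names])

  # -- raw cross-part distances: 3
  f[["d_nose_nose"]] <- euclid(track$A_nose_x, track$A_nose_y,
                               track$B_nose_x, track$B_nose_y)
  f[["d_noseA_agB"]] <- euclid(track$A_nose_x, track$A_nose_y,
                               track$B_anogenital_x, track$B_anogenital_y)
  f[["d_noseB_agA"]] <- euclid(track$B_nose_x, track$B_nose_y,
                               track$A_anogenital_x, track$A_anogenital_y)

  # -- within-animal distances: 6 + 2 elongation
  for (a in animal_ids()) {
    f[[paste0("within_nose_back_", a)]] <-
      euclid(track[[paste0(a, "_nose_x")]], track[[paste0(a, "_nose_y")]],
             track[[paste0(a, "_back_x")]], track[[paste0(a, "_back_y")]])
    f[[paste0("within_headctr_agctr_", a)]] <-
      euclid(ctr[[paste0("ctr_head_", a, "_x")]],
             ctr[[paste0("ctr_head_", a, "_y")]],
             ctr[[paste0("ctr_ag_", a, "_x")]],
             ctr[[paste0("ctr_ag_", a, "_y")]])
    f[[paste0("within_nose_tailend_", a)]] <-
      euclid(track[[paste0(a, "_nose_x")]], track[[paste0(a, "_nose_y")]],
             track[[paste0(a, "_tail_end_x")]], track[[paste0(a, "_tail_end_y")]])
  }
  for (a in animal_ids()) {
    f[[paste0("elong_", a)]] <-
      euclid(track[[paste0(a, "_nose_x")]], track[[paste0(a, "_nose_y")]],
             track[[paste0(a, "_pelvis_x")]], track[[paste0(a, "_pelvis_y")]])
  }

  # -- axial angles: 4 (degrees at the middle vertex)
  for (a in animal_ids()) {
    f[[paste0("ang_nose_head_back_", a)]] <- angle_deg(
      track[[paste0(a, "_nose_x")]], track[[paste0(a, "_nose_y")]],
      track[[paste0(a, "_head_x")]], track[[paste0(a, "_head_y")]],
      track[[paste0(a, "_back_x")]], track[[paste0(a, "_back_y")]])
    f[[paste0("ang_head_back_pelvis_", a)]] <- angle_deg(
      track[[paste0(a, "_head_x")]], track[[paste0(a, "_head_y")]],
      track[[paste0(a, "_back_x")]], track[[paste0(a, "_back_y")]],
      track[[paste0(a, "_pelvis_x")]], track[[paste0(a, "_pelvis_y")]])
  }

  # -- likelihood summaries: mean and min per animal
  for (a in animal_ids()) {
    p <- as.matrix(track[vapply(body_parts(),
                                function(bp) .kp_cols(a, bp)[3], "")])
    f[[paste0("prob_mean_", a)]] <- rowMeans(p)
    f[[paste0("prob_min_", a)]] <- do.call(pmin, as.data.frame(p))
  }

  out <- as.data.frame(f, check.names = FALSE)
  stopifnot(ncol(out) == 109)
  out
}

#' Merge polygon and custom features into the final feature table
#'
#' Row counts are truncated to the shorter of the two inputs (sessions can
#' disagree by a few trailing frames); the result has exactly 111 columns.
#'
#' @param polygon_table Output of [polygon_features()].
#' @param custom_table Output of [custom_features()].
#' @param fps Frames per second, stored on the result.
#' @return A `feature_table` data frame (111 columns, `fps` attribute).
#' @export
merge_features <- function(polygon_table, custom_table, fps = NULL) {
  n <- min(nrow(polygon_table), nrow(custom_table))
  if (n < 1) stop("no overlapping rows between feature tables")
  out <- cbind(polygon_table[seq_len(n), , drop = FALSE],
               custom_table[seq_len(n), , drop = FALSE])
  rownames(out) <- NULL
  stopifnot(ncol(out) == 111)
  attr(out, "fps") <- fps
  class(out) <- c("feature_table", "data.frame")
  out
}

#' One-call feature extraction for a preprocessed track
#'
#' @param track A preprocessed `pose_track`.
#' @return A `feature_table` (see [merge_features()]).
#' @export
extract_features <- function(track) {
  hulls <- frame_hulls(track)
  merge_features(polygon_features(track, hulls = hulls),
                 custom_features(track, hulls = hulls),
                 fps = track_fps(track))
}

#' Machine-readable feature manifest
#'
#' @return Data frame with `name` and `family` for the 111 features, in
#'   column order of [extract_features()].
#' @export
feature_manifest <- function() {
  spec <- synth_session_spec(video_duration = 2, audio_duration = 2, seed = 1)
  tr <- generate_pose_track(spec, noise_px = 0, missing_rate = 0)$track
  nm <- names(extract_features(tr))
  family <- rep("other", length(nm))
  family[nm %in% c("polygon_pct_overlap", "difference_area")] <- "polygon"
  family[grepl("^prob_", nm)] <- "probability"
  family[grepl("^ctr_", nm)] <- "centroid"
  family[grepl("^hull_", nm)] <- "hull"
  family[grepl("^mov_", nm)] <- "movement"
  family[grepl("^(d_|within_|elong_)", nm)] <- "distance"
  family[grepl("^ang_", nm)] <- "angle"
  data.frame(name = nm, family = family, stringsAsFactors = FALSE)
}
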