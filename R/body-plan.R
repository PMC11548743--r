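#' Tracked body parts, behaviors and call types
#'
#' The pipeline assumes the 12-keypoint rat skeleton used by the
#' pose-estimation stage, tracked on each of two animals (A and B), the
#' 11-category dyadic ethogram, and the four ultrasonic call types.
#'
#' @return Character vectors of canonical names, in fixed order.
#' @examples
#' body_parts()
#' behavior_categories()
#' call_types()
#' @export
body_parts <- function() {
  c("nose", "eye_left", "eye_right", "head", "back", "pelvis",
    "anogenital", "shoulder_left", "shoulder_right", "middle",
    "tail_middle", "tail_end")
}

#' @rdname body_parts
#' @export
animal_ids <- function() c("A", "B")

#' @rdname body_parts
#' @export
behavior_categories <- function() {
  c("adjacent_lying", "anogenital_sniffing", "crawling", "fighting",
    "following", "grooming", "mounting", "nosing", "rearing",
    "self_grooming", "sniffing")
}

#' @rdname body_parts
#' @export
call_types <- function() c("ALARM", "FLAT", "FM", "SHORT")

# Behaviors whose postures contradict each other: an episode script must not
# place both members of a pair on the same frame (a resting posture cannot
# co-occur with locomotion of the same animals).
.conflicting_behaviors <- list(
  c("adjacent_lying", "following"),
  c("adjacent_lying", "fighting"),
  c("mounting", "following"),
  c("self_grooming", "following")
)

# Body-axis layout of the skeleton: offsets along the nose-to-tail axis
# (unit = body length fraction, nose at +0.5, tail end at -0.5) and lateral
# offsets (left positive).  Used by the synthetic generator only.
.skeleton_plan <- data.frame(
  part = c("nose", "eye_left", "eye_right", "head", "back", "pelvis",
           "anogenital", "shoulder_left", "shoulder_right", "middle",
           "tail_middle", "tail_end"),
  along = c(0.50, 0.44, 0.44, 0.38, 0.10, -0.18,
            -0.28, 0.28, 0.28, 0.00, -0.40, -0.50),
  lateral = c(0, 0.06, -0.06, 0, 0, 0,
              0, 0.12, -0.12, 0, 0, 0),
  stringsAsFactors = FALSE
)

# column names of one keypoint triplet
.kp_cols <- function(animal, part) {
  paste(animal, part, c("x", "y", "p"), sep = "_")
}

# all 72 track columns in canonical order (animal-major, part-minor)
.track_cols <- function() {
  unlist(lapply(animal_ids(), function(a) {
    unlist(lapply(body_parts(), function(bp) .kp_cols(a, bp)))
  }))
}
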