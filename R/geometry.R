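# Planar geometry for the feature stage.  The per-frame convex hulls and
# their intersection run in compiled code (src/hulls.cpp); this file keeps
# the R-level plumbing.

# body and head hull areas plus body-hull intersection area for every frame
# of a preprocessed track; 5-column matrix (body_area_A, body_area_B,
# head_area_A, head_area_B, intersection_area)
frame_hulls <- function(track) {
  bxa <- as.matrix(track[paste0("A_", body_parts(), "_x")])
  bya <- as.matrix(track[paste0("A_", body_parts(), "_y")])
  bxb <- as.matrix(track[paste0("B_", body_parts(), "_x")])
  byb <- as.matrix(track[paste0("B_", body_parts(), "_y")])
  head_parts <- .centroid_members$head
  hxa <- as.matrix(track[paste0("A_", head_parts, "_x")])
  hya <- as.matrix(track[paste0("A_", head_parts, "_y")])
  hxb <- as.matrix(track[paste0("B_", head_parts, "_x")])
  hyb <- as.matrix(track[paste0("B_", head_parts, "_y")])
  .frame_hull_geometry(bxa, bya, bxb, byb, hxa, hya, hxb, hyb)
}

# interior angle at vertex (x2,y2), degrees in [0, 180]
angle_deg <- function(x1, y1, x2, y2, x3, y3) {
  ux <- x1 - x2; uy <- y1 - y2
  vx <- x3 - x2; vy <- y3 - y2
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  cosang <- ifelse(nu * nv > 0, (ux * vx + uy * vy) / (nu * nv), 1)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
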