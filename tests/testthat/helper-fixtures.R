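# Shared fixtures and independent oracles.

# pose_track with every keypoint at a fixed position per (animal, part);
# `pos` is a named list like list(A_nose = c(1, 2)); unnamed parts default
# to spread-out positions so hulls are non-degenerate unless degenerate=TRUE
make_track <- function(n, pos = list(), fps = 12, p = 1, degenerate = FALSE) {
  cols <- list(frame = seq_len(n))
  k <- 0
  for (a in animal_ids()) {
    for (bp in body_parts()) {
      k <- k + 1
      key <- paste0(a, "_", bp)
      xy <- pos[[key]]
      if (is.null(xy)) {
        xy <- if (degenerate) c(0, 0) else
          c(100 + 17 * k + 50 * (a == "B"), 100 + 13 * ((k * 7) %% 11))
      }
      cols[[paste0(key, "_x")]] <- rep(xy[1], n)
      cols[[paste0(key, "_y")]] <- rep(xy[2], n)
      cols[[paste0(key, "_p")]] <- rep(p, n)
    }
  }
  tr <- as_pose_track(as.data.frame(cols, check.names = FALSE), fps = fps)
  attr(tr, "zero_filled") <- character()   # fixture coordinates are real
  tr
}

# place each animal's 12 parts on the perimeter of an axis-aligned square
square_track <- function(n, originA = c(0, 0), originB = c(0, 0), size = 10,
                         fps = 12) {
  corners <- rbind(c(0, 0), c(size, 0), c(size, size), c(0, size),
                   c(size / 2, 0), c(size, size / 2), c(size / 2, size),
                   c(0, size / 2), c(0, 0), c(size, 0), c(size, size),
                   c(0, size))
  pos <- list()
  for (i in seq_along(body_parts())) {
    pos[[paste0("A_", body_parts()[i])]] <- corners[i, ] + originA
    pos[[paste0("B_", body_parts()[i])]] <- corners[i, ] + originB
  }
  make_track(n, pos, fps = fps)
}

# fully random track (not a plausible rat; exercises generic geometry)
random_track <- function(n, seed, fps = 12) {
  set.seed(seed)
  cols <- list(frame = seq_len(n))
  for (a in animal_ids()) for (bp in body_parts()) {
    key <- paste0(a, "_", bp)
    cols[[paste0(key, "_x")]] <- runif(n, 0, 500)
    cols[[paste0(key, "_y")]] <- runif(n, 0, 500)
    cols[[paste0(key, "_p")]] <- runif(n, 0.85, 1)
  }
  as_pose_track(as.data.frame(cols, check.names = FALSE), fps = fps)
}

# ---- independent oracles -------------------------------------------------

# hull area via base chull + shoelace (independent of the compiled path)
bf_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# hull intersection area by dense grid counting (grid step h)
bf_inter_area <- function(xa, ya, xb, yb, h = 0.25) {
  in_hull <- function(px, py, x, y) {
    pts <- unique(cbind(x, y))
    if (nrow(pts) < 3) return(rep(FALSE, length(px)))
    ch <- grDevices::chull(pts)
    hx <- pts[ch, 1]; hy <- pts[ch, 2]
    nh <- length(hx)
    ok <- rep(TRUE, length(px))
    for (i in seq_len(nh)) {
      j <- if (i == nh) 1 else i + 1
      cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
      ok <- ok & (cr <= 1e-9)   # chull is clockwise; inside = right side
    }
    ok
  }
  gx <- seq(min(c(xa, xb)) - h, max(c(xa, xb)) + h, by = h)
  gy <- seq(min(c(ya, yb)) - h, max(c(ya, yb)) + h, by = h)
  g <- expand.grid(x = gx, y = gy)
  inside <- in_hull(g$x, g$y, xa, ya) & in_hull(g$x, g$y, xb, yb)
  sum(inside) * h * h
}

# precision/recall/F1 by exhaustive counting at one threshold (>= rule)
bf_pr_at <- function(scores, truth, t) {
  pred <- scores >= t
  tp <- sum(pred & truth == 1)
  fp <- sum(pred & truth == 0)
  fn <- sum(!pred & truth == 1)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- tp / (tp + fn)
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

# repeated-measures ANOVA oracle via aov + Error strata
bf_rm_anova <- function(d) {
  d$box <- factor(d$box); d$lighting <- factor(d$lighting)
  d$phase <- factor(d$phase)
  fit <- summary(stats::aov(value ~ lighting * phase +
                              Error(box / (lighting * phase)), data = d))
  get_row <- function(stratum, term) {
    tab <- fit[[stratum]][[1]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)[1]
    e <- grep("Residuals", trimws(rownames(tab)), fixed = TRUE)[1]
    c(F = tab[i, "F value"],
      peta = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + tab[e, "Sum Sq"]))
  }
  list(lighting = get_row("Error: box:lighting", "lighting"),
       phase = get_row("Error: box:phase", "phase"),
       interaction = get_row("Error: box:lighting:phase", "lighting:phase"))
}

# ---- shared full-scale study for the end-to-end criteria -----------------

.study_cache <- new.env(parent = emptyenv())

e2e_study_dir <- function() {
  if (is.null(.study_cache$dir)) {
    dir <- file.path(tempdir(), "ratduet-e2e-study")
    generate_study(dir, n_boxes = 6, n_days = 6, seed = 42)
    .study_cache$dir <- dir
  }
  .study_cache$dir
}

e2e_analysis <- function() {
  if (is.null(.study_cache$analysis)) {
    dir <- e2e_study_dir()
    bundle <- train_from_study(
      dir,
      sessions = data.frame(box = "A", day = c(1, 1, 2),
                            session_type = c("dark_to_light",
                                             "light_to_dark",
                                             "light_to_dark")),
      config = list(num_trees = 50, seed = 42), thin = 3L)
    .study_cache$analysis <- analyze_study(dir, bundle)
    .study_cache$bundle <- bundle
  }
  .study_cache$analysis
}
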