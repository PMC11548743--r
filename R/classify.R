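# Per-frame random-forest ethogram classifiers: one independent binary
# forest per behavior, PR-curve threshold selection, strict-greater
# prediction rule, minimum bout length 0 by default.

#' Train per-behavior random-forest classifiers
#'
#' Fits one independent binary probability forest per behavior on the
#' 111-column feature table, holding out a stratified test fraction
#' (default 20%) on which the precision-recall curve is evaluated and the
#' max-F1 detection threshold selected.  No under/over-sampling is applied.
#' A behavior with a single class in the data is marked untrainable; the
#' others proceed.
#'
#' @param features A `feature_table` (or data frame with the same columns).
#' @param labels Data frame or matrix of per-frame 0/1 columns, one per
#'   behavior (names from [behavior_categories()]); several behaviors may be
#'   1 on the same frame.
#' @param config List: `num_trees` (default 100), `test_fraction` (default
#'   0.2), `seed` (default 1), `min_bout_frames` (default 0).
#' @return A `behavior_classifiers` bundle: per behavior the fitted forest,
#'   `detection_threshold`, `max_f1`, `min_bout_frames`, plus the feature
#'   manifest and seed.
#' @export
train_classifiers <- function(features, labels, config = list()) {
  cfg <- utils::modifyList(list(num_trees = 100, test_fraction = 0.2,
                                seed = 1L, min_bout_frames = 0L), config)
  labels <- as.data.frame(labels)
  behaviors <- intersect(behavior_categories(), names(labels))
  if (!length(behaviors)) stop("labels contain no known behavior columns")
  features <- as.data.frame(features)
  stopifnot(nrow(features) == nrow(labels))

  models <- list()
  with_seed(cfg$seed, {
    for (beh in behaviors) {
      y <- as.integer(labels[[beh]])
      if (length(unique(y)) < 2) {
        models[[beh]] <- list(untrainable = TRUE, detection_threshold = NA_real_,
                              max_f1 = NA_real_, min_bout_frames = cfg$min_bout_frames)
        next
      }
      test_idx <- stratified_test_idx(y, cfg$test_fraction)
      train_idx <- setdiff(seq_along(y), test_idx)
      fit <- ranger::ranger(
        x = features[train_idx, , drop = FALSE],
        y = factor(y[train_idx], levels = c(0, 1)),
        num.trees = cfg$num_trees, probability = TRUE,
        num.threads = 1, seed = cfg$seed)
      scores <- ranger_prob(fit, features[test_idx, , drop = FALSE])
      truth <- y[test_idx]
      if (length(unique(truth)) < 2) {
        # degenerate split; fall back to a 0.5 threshold
        thr <- list(threshold = 0.5, max_f1 = NA_real_)
      } else {
        thr <- select_threshold(pr_curve(scores, truth))
      }
      models[[beh]] <- list(
        untrainable = FALSE, forest = fit,
        detection_threshold = thr$threshold, max_f1 = thr$max_f1,
        min_bout_frames = cfg$min_bout_frames)
    }
  })
  structure(list(models = models, feature_names = names(features),
                 seed = cfg$seed, config = cfg),
            class = "behavior_classifiers")
}

stratified_test_idx <- function(y, fraction) {
  idx <- unlist(lapply(split(seq_along(y), y), function(g) {
    k <- max(1L, round(length(g) * fraction))
    sample(g, min(k, length(g)))
  }))
  sort(unname(idx))
}

ranger_prob <- function(fit, newdata) {
  pr <- stats::predict(fit, data = newdata, num.threads = 1)$predictions
  pr[, "1"]
}

#' Precision-recall curve over all distinct score values
#'
#' At each candidate threshold `t` (every distinct score), frames with
#' `score >= t` are predicted positive.  `F1 = 2PR/(P+R)`, defined as 0
#' when `P + R = 0`; precision is 0 when nothing is predicted positive.
#'
#' @param scores Per-frame classifier probabilities.
#' @param truth Per-frame 0/1 ground truth (both classes present).
#' @return Data frame with `threshold`, `precision`, `recall`, `f1`,
#'   thresholds in increasing order.
#' @export
pr_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2) stop("truth must contain both classes")
  stopifnot(length(scores) == length(truth))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  pos <- sum(y)
  last <- which(c(diff(s) != 0, TRUE))   # last index of each tie group
  precision <- tp[last] / (tp[last] + fp[last])
  recall <- tp[last] / pos
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  out <- data.frame(threshold = s[last], precision = precision,
                    recall = recall, f1 = f1)
  out[order(out$threshold), , drop = FALSE]
}

#' Select the max-F1 detection threshold from a PR curve
#'
#' Picks the curve point with maximal F1, breaking ties toward the higher
#' threshold (the stricter detector).  The returned `threshold` is the
#' midpoint between that score and the next lower distinct score (half the
#' score when it is the lowest), so that the strict-greater prediction rule
#' of [predict_frames()] reproduces exactly the selected operating point.
#'
#' @param curve Output of [pr_curve()].
#' @return List with `threshold` (detection threshold), `score` (the curve
#'   point chosen) and `max_f1`.
#' @export
select_threshold <- function(curve) {
  if (!nrow(curve)) stop("empty PR curve")
  curve <- curve[order(curve$threshold), , drop = FALSE]
  best <- max(curve$f1)
  i <- max(which(curve$f1 == best))       # tie -> higher threshold
  score <- curve$threshold[i]
  lower <- if (i > 1) curve$threshold[i - 1] else 0
  list(threshold = (score + lower) / 2, score = score, max_f1 = best)
}

#' Apply trained classifiers to a feature table
#'
#' A behavior is present on a frame iff its forest probability is strictly
#' greater than its detection threshold (a probability exactly equal to the
#' threshold is absent).  With `min_bout_frames = 0` (the default) bouts of
#' any length are kept, down to a single 1/12-s frame.
#'
#' @param bundle A `behavior_classifiers` bundle.
#' @param features Feature table whose columns must match the training
#'   manifest.
#' @param config Optional list of per-behavior overrides, as read by
#'   [read_classifier_config()]: `list(<behavior> = list(detection_threshold
#'   =, min_bout_frames =))`.
#' @return List with `probability` and `present` (frames x behaviors
#'   matrices; untrainable behaviors give NA probability and 0 presence).
#' @export
predict_frames <- function(bundle, features, config = NULL) {
  stopifnot(inherits(bundle, "behavior_classifiers"))
  features <- as.data.frame(features)
  missing_cols <- setdiff(bundle$feature_names, names(features))
  if (length(missing_cols))
    stop("feature columns missing from input: ",
         paste(missing_cols, collapse = ", "))
  features <- features[bundle$feature_names]
  behaviors <- names(bundle$models)
  n <- nrow(features)
  prob <- matrix(NA_real_, n, length(behaviors),
                 dimnames = list(NULL, behaviors))
  present <- matrix(0L, n, length(behaviors),
                    dimnames = list(NULL, behaviors))
  for (beh in behaviors) {
    m <- bundle$models[[beh]]
    thr <- m$detection_threshold
    min_bout <- m$min_bout_frames
    if (!is.null(config[[beh]])) {
      thr <- config[[beh]]$detection_threshold %||% thr
      min_bout <- config[[beh]]$min_bout_frames %||% min_bout
    }
    if (isTRUE(m$untrainable)) next
    p <- ranger_prob(m$forest, features)
    prob[, beh] <- p
    hit <- as.integer(p > thr)
    if (min_bout > 0) hit <- drop_short_bouts(hit, min_bout)
    present[, beh] <- hit
  }
  list(probability = prob, present = present)
}

drop_short_bouts <- function(hit, min_bout) {
  r <- rle(hit)
  r$values[r$values == 1L & r$lengths < min_bout] <- 0L
  inverse.rle(r)
}

#' Write / read a per-behavior threshold configuration
#'
#' YAML file holding, per behavior, `detection_threshold` and
#' `min_bout_frames` -- the role the classifier INI file plays in the usual
#' ethogram toolchain, including manual threshold overrides after video
#' inspection.
#'
#' @param bundle A `behavior_classifiers` bundle.
#' @param path File path.
#' @return `read_classifier_config` returns the named list of overrides;
#'   `write_classifier_config` returns `path` invisibly.
#' @export
write_classifier_config <- function(bundle, path) {
  cfg <- lapply(bundle$models, function(m) list(
    detection_threshold = m$detection_threshold,
    max_f1 = m$max_f1,
    min_bout_frames = m$min_bout_frames))
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' @rdname write_classifier_config
#' @export
read_classifier_config <- function(path) {
  yaml::read_yaml(path)
}

#' @export
print.behavior_classifiers <- function(x, ...) {
  cat("<behavior_classifiers>", length(x$models), "behaviors\n")
  for (beh in names(x$models)) {
    m <- x$models[[beh]]
    if (isTRUE(m$untrainable)) cat(sprintf("  %-20s untrainable\n", beh))
    else cat(sprintf("  %-20s threshold %.4f  max F1 %.3f\n",
                     beh, m$detection_threshold, m$max_f1))
  }
  invisible(x)
}
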