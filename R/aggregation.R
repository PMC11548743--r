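# Epoch aggregation: per-minute durations, design collapse to 2x2 cell
# means, behavior-call co-occurrence sums, and event binning.

#' Per-epoch durations of behaviors and call types
#'
#' Splits an aligned frame annotation table into consecutive 1-minute epochs
#' (`fps * 60` frames each, up to 720 frames at 12 fps) and converts
#' positive frames into seconds (`frames / fps`).  A trailing partial epoch
#' is kept, with its true length recorded, but callers collapsing the
#' design should drop it (only whole-minute epochs are comparable).
#'
#' @param annotations Frame annotation table (see [merge_annotations()]):
#'   per-frame 0/1 columns for behaviors and call types.
#' @param fps Frames per second.
#' @param epoch_s Epoch length in seconds (default 60).
#' @param categories Columns to aggregate; defaults to every behavior and
#'   call-type column present.
#' @param change_epoch Last epoch before the light change (default 10: the
#'   20-minute session layout).
#' @return Long data frame: `epoch` (1-based), `category`, `duration_s`,
#'   `n_frames`, `epoch_len_s`, `lighting` (`before_change` for epochs
#'   1-10, `after_change` for 11-20 under the 20-minute session layout).
#' @export
epoch_durations <- function(annotations, fps, epoch_s = 60,
                            categories = NULL, change_epoch = 10) {
  if (is.null(categories))
    categories <- intersect(c(behavior_categories(), call_types()),
                            names(annotations))
  n <- nrow(annotations)
  per_epoch <- as.integer(round(epoch_s * fps))
  epoch <- (seq_len(n) - 1L) %/% per_epoch + 1L
  epoch_len <- tabulate(epoch)
  rows <- lapply(categories, function(cat) {
    pos <- tapply(annotations[[cat]], epoch, sum)
    data.frame(epoch = as.integer(names(pos)), category = cat,
               duration_s = as.numeric(pos) / fps,
               n_frames = as.integer(pos),
               epoch_len_s = epoch_len[as.integer(names(pos))] / fps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$category, out$epoch), , drop = FALSE]
  out$lighting <- ifelse(out$epoch <= change_epoch, "before_change",
                         "after_change")
  rownames(out) <- NULL
  out
}

#' Collapse per-epoch data to the 2x2 within-subject design
#'
#' Averages epoch durations before vs after the light change (epochs 1-10
#' vs 11-20) within each session, then averages sessions over the early
#' (days 1-3) and late (days 4-6) phase, per box, session type and
#' category.  Days missing from a cell are simply absent from its mean; a
#' box missing an entire cell is flagged (and should be excluded from the
#' affected ANOVA).
#'
#' @param epochs Data frame of epoch rows carrying `box`, `day`,
#'   `session_type`, `epoch`, `category`, `duration_s` (and optionally
#'   `epoch_len_s`; partial epochs are excluded here).
#' @param epoch_s Nominal epoch length (s), used to drop partial epochs.
#' @param change_epoch Last epoch before the light change (default 10).
#' @return A `cell_means` data frame: `box`, `session_type`, `category`,
#'   `lighting`, `phase`, `value`; attribute `incomplete` lists flagged
#'   (box, session_type, category) combinations.
#' @export
collapse_design <- function(epochs, epoch_s = 60, change_epoch = 10) {
  stopifnot(all(c("box", "day", "session_type", "epoch", "category",
                  "duration_s") %in% names(epochs)))
  if ("epoch_len_s" %in% names(epochs))
    epochs <- epochs[epochs$epoch_len_s >= epoch_s - 1e-9, , drop = FALSE]
  epochs$lighting <- ifelse(epochs$epoch <= change_epoch, "before_change",
                            "after_change")
  epochs$phase <- ifelse(epochs$day <= 3, "early", "late")
  # mean over epochs within session, then over days within phase
  per_session <- aggregate(duration_s ~ box + session_type + category +
                             day + phase + lighting, data = epochs, FUN = mean)
  cells <- aggregate(duration_s ~ box + session_type + category +
                       phase + lighting, data = per_session, FUN = mean)
  names(cells)[names(cells) == "duration_s"] <- "value"
  cells <- cells[c("box", "session_type", "category", "lighting", "phase",
                   "value")]
  # flag boxes missing a whole cell
  full <- expand.grid(lighting = c("before_change", "after_change"),
                      phase = c("early", "late"), stringsAsFactors = FALSE)
  combos <- unique(cells[c("box", "session_type", "category")])
  incomplete <- combos[vapply(seq_len(nrow(combos)), function(i) {
    sub <- merge(combos[i, ], cells)
    nrow(sub) < nrow(full)
  }, logical(1)), , drop = FALSE]
  rownames(cells) <- rownames(incomplete) <- NULL
  attr(cells, "incomplete") <- incomplete
  class(cells) <- c("cell_means", "data.frame")
  cells
}

#' Per-epoch co-occurrence sums
#'
#' For two call types, the co-occurrence sum in an epoch is the total count
#' of calls of either type in that epoch (1 SHORT + 4 FM gives 5).  For a
#' behavior and a call type it is the number of calls of that type whose
#' marked frames intersect frames where the behavior is 1 (set
#' `behavior_units = "seconds"` for the frame-intersection variant in
#' seconds instead).
#'
#' @param annotations Aligned frame annotation table (behaviors + call-type
#'   0/1 columns).
#' @param calls Typed call table on the same (trimmed) clock; used to count
#'   call events.
#' @param fps Frames per second.
#' @param epoch_s Epoch length, seconds.
#' @param behavior_units `"calls"` (default) or `"seconds"`.
#' @return Long data frame: `epoch`, `cat_a`, `cat_b`, `sum`.  Symmetric in
#'   the two categories; call-call pairs listed once (cat_a < cat_b).
#' @export
cooccurrence_sums <- function(annotations, calls, fps, epoch_s = 60,
                              behavior_units = c("calls", "seconds")) {
  behavior_units <- match.arg(behavior_units)
  n <- nrow(annotations)
  per_epoch <- as.integer(round(epoch_s * fps))
  n_epochs <- max(1L, ceiling(n / per_epoch))
  behaviors <- intersect(behavior_categories(), names(annotations))
  if (nrow(calls) && !"call_type" %in% names(calls))
    calls <- classify_calls(calls)
  if (nrow(calls)) {
    call_epoch <- pmin(floor(calls$begin_s / epoch_s) + 1L, n_epochs)
    call_f0 <- pmax(1L, floor(calls$begin_s * fps) + 1L)
    call_f1 <- pmin(n, floor(calls$end_s * fps) + 1L)
  }
  out <- list()
  # call-type x call-type: total calls of the two types in the epoch
  counts <- matrix(0L, n_epochs, length(call_types()),
                   dimnames = list(NULL, call_types()))
  if (nrow(calls)) {
    tab <- table(factor(calls$call_type, levels = call_types()), call_epoch)
    counts[as.integer(colnames(tab)), ] <- t(tab)
  }
  tp <- call_types()
  for (i in seq_along(tp)) for (j in seq_along(tp)) {
    if (i >= j) next
    out[[length(out) + 1]] <- data.frame(
      epoch = seq_len(n_epochs), cat_a = tp[i], cat_b = tp[j],
      sum = counts[, tp[i]] + counts[, tp[j]], stringsAsFactors = FALSE)
  }
  # behavior x call-type
  for (beh in behaviors) {
    beh_pos <- annotations[[beh]] == 1
    for (ct in tp) {
      s <- numeric(n_epochs)
      if (nrow(calls)) {
        sel <- which(calls$call_type == ct)
        for (k in sel) {
          if (call_f1[k] < call_f0[k]) next
          frames <- call_f0[k]:call_f1[k]
          ov <- beh_pos[frames]
          if (behavior_units == "calls") {
            if (any(ov)) s[call_epoch[k]] <- s[call_epoch[k]] + 1
          } else {
            s[call_epoch[k]] <- s[call_epoch[k]] + sum(ov) / fps
          }
        }
      }
      out[[length(out) + 1]] <- data.frame(
        epoch = seq_len(n_epochs), cat_a = beh, cat_b = ct, sum = s,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bin event timestamps into fixed windows
#'
#' Half-open bins `[k * bin_s, (k+1) * bin_s)`: an event exactly on a
#' boundary falls into the later bin.  Counts conserve the number of
#' events.
#'
#' @param timestamps Sorted event times, seconds from recording start.
#' @param bin_s Bin width, seconds.
#' @param span_s Total span covered; defaults to the last bin containing an
#'   event.
#' @return Integer vector of counts, one per bin.
#' @export
bin_events <- function(timestamps, bin_s, span_s = NULL) {
  if (length(timestamps) && is.unsorted(timestamps))
    stop("timestamps must be sorted")
  if (any(timestamps < 0)) stop("timestamps must be non-negative")
  n_bins <- if (!is.null(span_s)) ceiling(span_s / bin_s)
            else if (length(timestamps)) floor(max(timestamps) / bin_s) + 1
            else 0L
  if (n_bins == 0L) return(integer())
  idx <- pmin(floor(timestamps / bin_s) + 1L, n_bins)
  tabulate(idx, nbins = n_bins)
}
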