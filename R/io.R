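#' Read and write pose track CSVs
#'
#' The on-disk dialect mirrors multi-animal pose-estimation exports: three
#' header rows (animal, body part, coordinate/likelihood) over a leading
#' frame-index column, then one row per frame.
#'
#' @param track A `pose_track`.
#' @param path File path.
#' @param fps Frames per second of the recording (not stored in the CSV; it
#'   comes from the session index).
#' @return `read_pose_csv` returns a `pose_track`; `write_pose_csv` returns
#'   `path` invisibly.
#' @export
write_pose_csv <- function(track, path) {
  cols <- .track_cols()
  animal <- sub("_.*$", "", cols)
  coord <- sub("^p$", "likelihood", sub("^.*_", "", cols))
  part <- sub("^[AB]_", "", sub("_[xyp]$", "", cols))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("animal", animal), collapse = ","), con)
  writeLines(paste(c("bodypart", part), collapse = ","), con)
  writeLines(paste(c("coords", coord), collapse = ","), con)
  m <- as.matrix(track[cols])
  body <- cbind(track$frame, round(m, 6))
  utils::write.table(body, con, sep = ",", col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path, fps) {
  hdr <- readLines(path, n = 3)
  h <- lapply(hdr, function(l) strsplit(l, ",", fixed = TRUE)[[1]][-1])
  cols <- paste(h[[1]], h[[2]], sub("likelihood", "p", h[[3]]), sep = "_")
  df <- read.csv(path, skip = 3, header = FALSE, check.names = FALSE)
  names(df) <- c("frame", cols)
  as_pose_track(df, fps = fps)
}

#' Read and write call detection CSVs
#'
#' Plain CSV with columns `id`, `begin_s`, `end_s`, `duration_s`,
#' `principal_freq_khz`, `bandwidth_khz`, `detector` (plus `call_type` once
#' assigned).  `read_call_csv` also accepts the common detection-export
#' spellings (`Begin Time (s)`, `End Time (s)`, `Call Length (s)`,
#' `Principal Frequency (kHz)`, `Delta Freq (kHz)`) and maps them onto the
#' canonical names.
#'
#' @param calls A call table data frame.
#' @param path File path.
#' @return `read_call_csv` returns a data frame; `write_call_csv` returns
#'   `path` invisibly.
#' @export
write_call_csv <- function(calls, path) {
  write.csv(calls, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_call_csv
#' @export
read_call_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  alias <- c("Begin Time (s)" = "begin_s", "End Time (s)" = "end_s",
             "Call Length (s)" = "duration_s",
             "Principal Frequency (kHz)" = "principal_freq_khz",
             "Delta Freq (kHz)" = "bandwidth_khz")
  hit <- names(alias) %in% names(df)
  names(df)[match(names(alias)[hit], names(df))] <- alias[hit]
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  need <- c("begin_s", "end_s", "duration_s", "principal_freq_khz",
            "bandwidth_khz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("call table missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"detector" %in% names(df)) df$detector <- NA_character_
  df
}

#' Read and write the session index
#'
#' One row per recorded session: box, date, session type, media file names,
#' start timestamps (ISO 8601, whole-second resolution as written by the
#' recorders) and durations in seconds.
#'
#' @param index Index data frame.
#' @param path File path.
#' @return `read_index_csv` returns the index data frame; `write_index_csv`
#'   returns `path` invisibly.
#' @export
write_index_csv <- function(index, path) {
  write.csv(index, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_index_csv
#' @export
read_index_csv <- function(path) {
  idx <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("box", "date", "session_type", "video_file", "audio_file",
            "video_start_iso", "audio_start_iso", "video_duration_s",
            "audio_duration_s")
  missing_cols <- setdiff(need, names(idx))
  if (length(missing_cols))
    stop("index missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(idx$video_duration_s <= 0) || any(idx$audio_duration_s <= 0))
    stop("index durations must be positive")
  key <- paste(idx$box, idx$date, idx$session_type)
  if (anyDuplicated(key))
    stop("index has duplicated (box, date, session_type) rows")
  idx
}
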