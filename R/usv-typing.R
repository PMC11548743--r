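# Rule-based ultrasonic call typing.
#
# 50-kHz calls:  SHORT  duration <= 12 ms
#                FLAT   duration  > 12 ms and bandwidth <= 6 kHz
#                FM     duration  > 12 ms and bandwidth  > 6 kHz
# 22-kHz path:   ALARM  (every call from the low-frequency detector)
# Unknown detector: principal frequency < 32 kHz is ALARM before the 50-kHz
# rules apply.

#' Assign call types by acoustic rules
#'
#' @param calls A call table (see [read_call_csv()]): `begin_s`, `end_s`,
#'   `duration_s` (s), `principal_freq_khz`, `bandwidth_khz` (kHz), and
#'   `detector` (`"hf"` for the 50-kHz path, `"lf"` for the 22-kHz path, NA
#'   when unknown).  Durations and bandwidths must be non-negative;
#'   `duration_s` must agree with `end_s - begin_s`.
#' @return `classify_calls`: the table with a `call_type` column appended;
#'   `classify_call`: a character vector of types.
#' @examples
#' classify_call(data.frame(begin_s = 0, end_s = 0.012, duration_s = 0.012,
#'                          principal_freq_khz = 60, bandwidth_khz = 8,
#'                          detector = "hf"))   # "SHORT" (boundary inclusive)
#' @export
classify_calls <- function(calls) {
  calls$call_type <- classify_call(calls)
  calls
}

#' @rdname classify_calls
#' @export
classify_call <- function(calls) {
  if (!nrow(calls)) return(character())
  if (any(calls$duration_s <= 0)) stop("non-positive call duration")
  if (any(abs(calls$duration_s - (calls$end_s - calls$begin_s)) > 1e-6))
    stop("duration_s inconsistent with begin/end times")
  if (any(calls$bandwidth_khz < 0)) stop("negative bandwidth")
  det <- as.character(calls$detector)
  type <- rep(NA_character_, nrow(calls))
  is_lf <- !is.na(det) & det == "lf"
  unknown <- is.na(det)
  type[is_lf] <- "ALARM"
  type[unknown & calls$principal_freq_khz < 32] <- "ALARM"
  rest <- is.na(type)
  type[rest & calls$duration_s <= 0.012] <- "SHORT"
  rest <- is.na(type)
  type[rest & calls$bandwidth_khz <= 6] <- "FLAT"
  type[is.na(type)] <- "FM"
  type
}

#' Band-filter a call table
#'
#' Calls from the 50-kHz detector outside `band_hf` and calls from the
#' 22-kHz detector outside `band_lf` are dropped (bounds inclusive).  The
#' published 22-kHz band is printed with its cutoffs transposed ("high: 10,
#' low: 35"); it is read here as [10, 35] kHz.
#'
#' @param calls A call table with a `detector` column.
#' @param band_hf,band_lf Principal-frequency bands, kHz, `c(low, high)`.
#' @return The filtered table, with attributes `n_dropped_hf` /
#'   `n_dropped_lf` recording what was removed.
#' @export
filter_calls <- function(calls, band_hf = c(35, 95), band_lf = c(10, 35)) {
  if (band_hf[1] >= band_hf[2] || band_lf[1] >= band_lf[2])
    stop("frequency bands must satisfy low < high")
  if (!nrow(calls)) {
    attr(calls, "n_dropped_hf") <- 0L
    attr(calls, "n_dropped_lf") <- 0L
    return(calls)
  }
  det <- as.character(calls$detector)
  fq <- calls$principal_freq_khz
  drop_hf <- !is.na(det) & det == "hf" & (fq < band_hf[1] | fq > band_hf[2])
  drop_lf <- !is.na(det) & det == "lf" & (fq < band_lf[1] | fq > band_lf[2])
  out <- calls[!(drop_hf | drop_lf), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_hf") <- sum(drop_hf)
  attr(out, "n_dropped_lf") <- sum(drop_lf)
  out
}
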