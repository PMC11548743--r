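# Synthetic ultrasonic call detection tables.
#
# Acoustic parameters are sampled strictly inside each type's defining
# region, so rule-based typing recovers the scripted type exactly on clean
# data:
#   SHORT  hf, duration <= 12 ms
#   FLAT   hf, duration  > 12 ms, bandwidth <= 6 kHz
#   FM     hf, duration  > 12 ms, bandwidth  > 6 kHz
#   ALARM  lf (22-kHz detector path), long calls at 18-32 kHz

.call_param_regions <- list(
  SHORT = list(duration = c(0.003, 0.012), bandwidth = c(0.5, 15),
               freq = c(40, 90), detector = "hf"),
  FLAT  = list(duration = c(0.015, 0.120), bandwidth = c(0.2, 6),
               freq = c(40, 90), detector = "hf"),
  FM    = list(duration = c(0.015, 0.120), bandwidth = c(7, 35),
               freq = c(40, 90), detector = "hf"),
  ALARM = list(duration = c(0.300, 1.500), bandwidth = c(0.5, 5),
               freq = c(18, 32), detector = "lf")
)

#' Generate a synthetic call detection table
#'
#' Draws call events from the spec's `call_script`: for each script row the
#' number of calls in the window is either the fixed `n` or
#' `Poisson(rate_per_min x window minutes)`; onset times are uniform in the
#' window and acoustic parameters are sampled inside the scripted type's
#' defining region.  Times are on the audio clock.
#'
#' @param spec A [synth_session_spec()].
#' @return A list with `calls` (a call table: `id`, `begin_s`, `end_s`,
#'   `duration_s`, `principal_freq_khz`, `bandwidth_khz`, `detector`) and
#'   `truth` (character vector of scripted types, one per call).
#' @examples
#' sc <- data.frame(type = c("SHORT", "FM"), window_start_s = 0,
#'                  window_end_s = 60, n = c(1, 4))
#' spec <- synth_session_spec(video_duration = 60, audio_duration = 60,
#'                            seed = 3, call_script = sc)
#' generate_call_table(spec)$calls
#' @export
generate_call_table <- function(spec) {
  stopifnot(inherits(spec, "synth_session_spec"))
  script <- spec$call_script
  with_seed(spec$seed + 1L, {
    rows <- list()
    types <- character()
    for (i in seq_len(nrow(script))) {
      win <- c(script$window_start_s[i], script$window_end_s[i])
      n_calls <- if (!is.na(script$n[i])) as.integer(script$n[i]) else
        rpois(1, script$rate_per_min[i] * diff(win) / 60)
      if (n_calls < 1) next
      reg <- .call_param_regions[[script$type[i]]]
      dur <- runif(n_calls, reg$duration[1], reg$duration[2])
      begin <- runif(n_calls, win[1], pmax(win[1], win[2] - max(reg$duration)))
      rows[[length(rows) + 1]] <- data.frame(
        begin_s = begin,
        end_s = begin + dur,
        duration_s = dur,
        principal_freq_khz = runif(n_calls, reg$freq[1], reg$freq[2]),
        bandwidth_khz = runif(n_calls, reg$bandwidth[1], reg$bandwidth[2]),
        detector = reg$detector,
        stringsAsFactors = FALSE
      )
      types <- c(types, rep(script$type[i], n_calls))
    }
    if (!length(rows)) {
      calls <- data.frame(id = integer(), begin_s = numeric(), end_s = numeric(),
                          duration_s = numeric(), principal_freq_khz = numeric(),
                          bandwidth_khz = numeric(), detector = character(),
                          stringsAsFactors = FALSE)
      return(list(calls = calls, truth = character()))
    }
    calls <- do.call(rbind, rows)
    ord <- order(calls$begin_s)
    calls <- calls[ord, , drop = FALSE]
    types <- types[ord]
    calls <- cbind(id = seq_len(nrow(calls)), calls)
    rownames(calls) <- NULL
    list(calls = calls, truth = types)
  })
}
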