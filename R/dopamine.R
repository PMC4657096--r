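#' Dopamine schedule
#'
#' Tonic dopamine level with an optional rectangular phasic event: a peak
#' to twice the basal level signalling reward, or a dip to zero signalling
#' punishment. The default event window (100-150 ms after stimulus onset)
#' matches the latency and duration of phasic dopaminergic responses, timed
#' after the network has reached its decision steady state.
#'
#' @param tonic Tonic (background) dopamine level. Default 0.45, the
#'   healthy basal value.
#' @param event_kind `"none"`, `"reward"` or `"punishment"`.
#' @param event_onset Event start, ms. Default 100.
#' @param event_duration Event length, ms. Default 50.
#' @param event_level Dopamine level during the event. Defaults to 0.9
#'   (double basal) for reward and 0 for punishment.
#' @return An object of class `dopamine_schedule`.
#' @export
#' @examples
#' sch <- dopamine_schedule(event_kind = "punishment")
#' dopamine_at(sch, c(50, 120, 200))  # 0.45, 0, 0.45
dopamine_schedule <- function(tonic = 0.45,
                              event_kind = c("none", "reward", "punishment"),
                              event_onset = 100, event_duration = 50,
                              event_level = NULL) {
  event_kind <- match.arg(event_kind)
  if (tonic < 0) stop("`tonic` must be >= 0", call. = FALSE)
  if (event_duration < 0) stop("`event_duration` must be >= 0", call. = FALSE)
  if (is.null(event_level))
    event_level <- switch(event_kind, none = tonic, reward = 2 * tonic,
                          punishment = 0)
  if (event_level < 0) stop("`event_level` must be >= 0", call. = FALSE)
  structure(list(tonic = tonic, event_kind = event_kind,
                 event_onset = event_onset, event_duration = event_duration,
                 event_level = event_level),
            class = "dopamine_schedule")
}

#' Dopamine level at a given time
#'
#' Rectangular pulse: returns the event level for `t` in
#' `[onset, onset + duration)` and the tonic level elsewhere.
#'
#' @param schedule A [dopamine_schedule()].
#' @param t Time(s) in ms, `>= 0`. Vectorized.
#' @return Dopamine level(s), same length as `t`.
#' @export
dopamine_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "dopamine_schedule"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (schedule$event_kind == "none") return(rep(schedule$tonic, length(t)))
  on <- t >= schedule$event_onset &
        t < schedule$event_onset + schedule$event_duration
  ifelse(on, schedule$event_level, schedule$tonic)
}

#' @export
print.dopamine_schedule <- function(x, ...) {
  cat("<dopamine_schedule> tonic =", x$tonic)
  if (x$event_kind != "none")
    cat("; ", x$event_kind, " to ", x$event_level, " over [",
        x$event_onset, ", ", x$event_onset + x$event_duration, ") ms",
        sep = "")
  cat("\n")
  invisible(x)
}
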