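#' Canonical experiment stimuli
#'
#' The stimulus vectors driving the package's paradigmatic scenarios:
#' `default` (single clear candidate), `conflict` (three strong competing
#' candidates), `feedback` (graded candidates used for reward/punishment
#' probes), `training` (context favouring channel 3, trained toward
#' channel 4) and `da_sweep` (prepotent channel 3, used for tonic-dopamine
#' comparisons).
#'
#' @return Named list of length-4 numeric vectors.
#' @export
bg_stimuli <- function() {
  list(default  = c(0.3, 0.8, 0.3, 0.2),
       conflict = c(0.85, 0.9, 0.85, 0.1),
       feedback = c(0.4, 0.8, 0.6, 0.5),
       training = c(0.15, 0.15, 0.9, 0.7),
       da_sweep = c(0.3, 0.3, 0.85, 0.3))
}

#' Experiment specification
#'
#' Bundles everything one scenario run needs. Non-training scenarios are
#' fully deterministic.
#'
#' @param name Scenario identifier (used in output file names).
#' @param stimulus Stimulus vector.
#' @param schedule A [dopamine_schedule()].
#' @param lesions A [lesion_spec()].
#' @param training Optional [training_config()] for learning scenarios.
#' @param duration Trial length in ms.
#' @param output_dir Directory where [run_scenario()] writes its files.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, stimulus, schedule = dopamine_schedule(),
                            lesions = lesion_spec(), training = NULL,
                            duration = 500, output_dir = ".") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            inherits(schedule, "dopamine_schedule"),
            inherits(lesions, "lesion_spec"))
  if (!is.null(training)) stopifnot(inherits(training, "training_config"))
  structure(list(name = name, stimulus = unclass(stimulus(unclass(stimulus))),
                 schedule = schedule, lesions = lesions, training = training,
                 duration = duration, output_dir = output_dir),
            class = "experiment_spec")
}

#' Run one scenario and write its outputs
#'
#' Simulates the trial described by `spec`, writes
#' `<output_dir>/<name>_trace.csv` (long-format activities plus conflict
#' energy and dopamine) and `<output_dir>/<name>_gating.json`, and returns
#' the trace and gating result. Deterministic: re-running a non-training
#' scenario reproduces its files byte for byte.
#'
#' @param spec An [experiment_spec()].
#' @param w A [bg_weights()] set.
#' @param p A [bg_params()] object.
#' @return Invisibly, `list(trace, gating, files)`.
#' @export
run_scenario <- function(spec, w = bg_weights(), p = bg_params()) {
  stopifnot(inherits(spec, "experiment_spec"))
  tr <- simulate_trial(w, spec$stimulus, spec$schedule, p,
                       duration = spec$duration, lesions = spec$lesions)
  g <- detect_gating(tr)
  if (!dir.exists(spec$output_dir))
    dir.create(spec$output_dir, recursive = TRUE)
  f_trace <- file.path(spec$output_dir, paste0(spec$name, "_trace.csv"))
  f_gate <- file.path(spec$output_dir, paste0(spec$name, "_gating.json"))
  write_trace_csv(tr, f_trace)
  write_gating_json(g, f_gate)
  invisible(list(trace = tr, gating = g,
                 files = c(trace = f_trace, gating = f_gate)))
}

#' End-state table across tonic dopamine levels
#'
#' Simulates the same stimulus under several tonic dopamine levels and
#' tabulates the end-of-trial activities of the winner channel in every
#' structure. Higher tonic dopamine promotes the direct over the indirect
#' pathway (winner Go up, NoGo down) and lowers cholinergic tone.
#'
#' @param stimulus Stimulus vector.
#' @param tonic_levels Numeric vector of tonic dopamine levels, all
#'   positive.
#' @param w,p Weights and parameters.
#' @param duration Trial length in ms.
#' @return Data frame with one row per level: `tonic_DA`, `winner`,
#'   `gated`, end-of-trial `C`, `Go`, `NoGo`, `GPe`, `GPi`, `T` (winner
#'   channel) and `ChI`. When nothing is gated the most active cortical
#'   unit is reported as winner.
#' @export
run_da_sweep <- function(stimulus, tonic_levels = c(0.35, 0.45, 0.55),
                         w = bg_weights(), p = bg_params(), duration = 500) {
  if (!length(tonic_levels) || any(tonic_levels <= 0))
    stop("`tonic_levels` must be a non-empty vector of positive levels",
         call. = FALSE)
  rows <- lapply(tonic_levels, function(da) {
    tr <- simulate_trial(w, stimulus, dopamine_schedule(tonic = da), p,
                         duration = duration)
    g <- detect_gating(tr)
    fin <- final_activities(tr)
    win <- if (!is.na(g$winner)) g$winner else which.max(fin$C)
    data.frame(tonic_DA = da, winner = win, gated = length(g$gated) > 0,
               C = fin$C[win], Go = fin$Go[win], NoGo = fin$NoGo[win],
               GPe = fin$GPe[win], GPi = fin$GPi[win], T = fin$T[win],
               ChI = fin$ChI)
  })
  do.call(rbind, rows)
}

#' Latency versus stimulus strength across dopamine levels
#'
#' For each tonic dopamine level and each amplitude `a` on the grid,
#' simulates a trial with the stimulus `[0.3, 0.3, a, 0.3]` (the varying
#' element on `channel`) and records whether any response was gated and
#' the winner's latency. Low dopamine networks neglect weak stimuli and
#' respond more slowly to medium ones.
#'
#' @param tonic_levels Tonic dopamine levels.
#' @param a_grid Amplitudes in (0, 1]; default `seq(0.31, 1, by = 0.01)`.
#' @param channel Which element of the stimulus carries `a`. Default 3.
#' @param base Baseline value of the other elements. Default 0.3.
#' @param w,p Weights and parameters.
#' @param duration Trial length in ms.
#' @return Data frame with columns `tonic_DA`, `a`, `gated`, `latency_ms`
#'   (`NA` when no acceptable response was gated), one row per grid point.
#' @export
run_latency_curve <- function(tonic_levels = c(0.35, 0.4, 0.45, 0.55),
                              a_grid = seq(0.31, 1, by = 0.01),
                              channel = 3, base = 0.3,
                              w = bg_weights(), p = bg_params(),
                              duration = 500) {
  if (any(a_grid <= 0 | a_grid > 1))
    stop("`a_grid` must lie in (0, 1]", call. = FALSE)
  grid <- expand.grid(a = a_grid, tonic_DA = tonic_levels,
                      KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(a, da) {
    s <- rep(base, p$N); s[channel] <- a
    tr <- simulate_trial(w, s, dopamine_schedule(tonic = da), p,
                         duration = duration)
    g <- detect_gating(tr)
    c(gated = length(g$gated) > 0,
      latency = if (!is.na(g$winner))
        unname(g$latency_ms[as.character(g$winner)]) else NA_real_)
  }, grid$a, grid$tonic_DA)
  data.frame(tonic_DA = grid$tonic_DA, a = grid$a,
             gated = as.logical(res["gated", ]),
             latency_ms = res["latency", ])
}
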