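#' Conflict energy of the cortical layer
#'
#' The scalar `E = sum_{i != j} y_i y_j` over all ordered pairs of cortical
#' activities: zero when at most one unit is active, large when two or more
#' units are simultaneously highly active. This is the conflict signal the
#' subthalamic nucleus reads from the cortex (hyperdirect pathway).
#'
#' @param y_C Cortical activity vector, elements in `[0, 1]`.
#' @return Non-negative scalar.
#' @export
#' @examples
#' conflict_energy(c(1, 1, 0, 0))          # 2
#' conflict_energy(rep(0.5, 4))            # 3
conflict_energy <- function(y_C) {
  if (any(y_C < 0 | y_C > 1)) stop("activities must lie in [0, 1]",
                                   call. = FALSE)
  sum(y_C)^2 - sum(y_C^2)
}

#' Lesion specification
#'
#' Two independent manipulations applied after every integration step:
#' clamping the subthalamic activity to zero (removes the hyperdirect
#' pathway) and clamping the cholinergic unit's activity to its tonic fixed
#' point under the tonic dopamine level (suppresses phasic cholinergic
#' signalling while preserving the tonic drive to the striatum).
#'
#' @param stn_off Clamp `y_STN` to 0 throughout the trial.
#' @param chi_clamped Clamp `y_H` to `sigmoid(I_H + gamma * tonic_DA)`.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(stn_off = FALSE, chi_clamped = FALSE) {
  stopifnot(is.logical(stn_off), is.logical(chi_clamped))
  structure(list(stn_off = isTRUE(stn_off), chi_clamped = isTRUE(chi_clamped)),
            class = "lesion_spec")
}

#' Fresh network state
#'
#' All membrane states start at zero (the silent baseline: activities
#' `sigmoid(0)`, about 0.018 with the default sigmoid), with activities
#' computed consistently.
#'
#' @param p A [bg_params()] object.
#' @return An object of class `bg_state`: membrane vectors `u_C, u_L, u_G,
#'   u_N, u_E, u_I, u_T` (length `N`), scalars `u_STN, u_H`, and matching
#'   activities `y_*` (no `y_L`: the lateral state feeds the cortex
#'   unfiltered).
#' @export
network_state <- function(p = bg_params()) {
  stopifnot(inherits(p, "bg_params"))
  N <- p$N
  st <- list(u_C = rep(0, N), u_L = rep(0, N), u_G = rep(0, N),
             u_N = rep(0, N), u_E = rep(0, N), u_I = rep(0, N),
             u_T = rep(0, N), u_STN = 0, u_H = 0)
  y0 <- sigmoid(0, p$sigmoid)
  st <- c(st, list(y_C = rep(y0, N), y_G = rep(y0, N), y_N = rep(y0, N),
                   y_E = rep(y0, N), y_I = rep(y0, N), y_T = rep(y0, N),
                   y_STN = y0, y_H = y0))
  structure(st, class = "bg_state")
}

#' Per-population net inputs
#'
#' Computes the instantaneous net input `x` for every population from the
#' current activities, the stimulus and the dopamine level:
#' \itemize{
#'   \item cortex: full stimulus drive, the raw lateral-inhibition state
#'     `u_L`, and the channel's thalamic feedback;
#'   \item lateral state: weighted sum of the other channels' cortical
#'     activities;
#'   \item Go: stimulus + channel cortex drive, the signed dopamine
#'     contrast term `alpha * DA * (y_G - theta_G)`, and cholinergic
#'     inhibition;
#'   \item NoGo: stimulus + channel cortex drive, plain dopamine inhibition
#'     `beta * DA`, and cholinergic excitation;
#'   \item GPe: NoGo inhibition, STN feedback excitation, tonic drive;
#'   \item GPi: Go inhibition, GPe inhibition, STN hyperdirect excitation,
#'     tonic drive;
#'   \item STN: conflict energy from the cortex and GPe inhibition;
#'   \item thalamus: GPi inhibition and channel cortex excitation;
#'   \item ChI: tonic drive plus dopamine inhibition `gamma * DA`.
#' }
#'
#' @param state A [network_state()] (or any list carrying the `u_L` and
#'   `y_*` fields).
#' @param s Stimulus vector, length `N`.
#' @param DA Dopamine level at the current instant.
#' @param w A [bg_weights()] object.
#' @param p A [bg_params()] object.
#' @return Named list of net inputs `x_C, x_L, x_G, x_N, x_E, x_I, x_STN,
#'   x_T, x_H`.
#' @export
net_inputs <- function(state, s, DA, w, p) {
  if (length(s) != p$N)
    stop("stimulus length ", length(s), " does not match N = ", p$N,
         call. = FALSE)
  y_C <- state$y_C
  list(
    x_C   = drop(w$W_CS %*% s) + state$u_L + diag(w$W_CT) * state$y_T,
    x_L   = drop(w$L %*% y_C),
    x_G   = drop(w$W_GS %*% s) + diag(w$W_GC) * y_C +
            p$alpha * DA * (state$y_G - p$theta_G) + w$w_GH * state$y_H,
    x_N   = drop(w$W_NS %*% s) + diag(w$W_NC) * y_C +
            p$beta * DA + w$w_NH * state$y_H,
    x_E   = diag(w$W_EN) * state$y_N + w$w_ESTN * state$y_STN + p$I_E,
    x_I   = diag(w$W_IG) * state$y_G + diag(w$W_IE) * state$y_E +
            w$w_ISTN * state$y_STN + p$I_I,
    x_STN = w$k_E * conflict_energy(y_C) + sum(w$W_STNE * state$y_E),
    x_T   = diag(w$W_TI) * state$y_I + diag(w$W_TC) * y_C,
    x_H   = p$I_H + p$gamma * DA
  )
}

# population labels used in traces and error messages
.populations <- c("C", "Go", "NoGo", "GPe", "GPi", "T", "STN", "ChI")

#' Simulate one trial of the coupled network
#'
#' Advances all populations by synchronous explicit Euler steps from the
#' zero initial state, under a stimulus held constant for the whole trial
#' and a dopamine schedule. Lesions are applied by clamping activities
#' (not inputs) after every step. Activities of every population, the
#' cortical conflict energy and the dopamine level are recorded at every
#' step, including the initial state at `t = 0`.
#'
#' @param w A [bg_weights()] object.
#' @param s Stimulus vector (length `N`, elements in `[0, 1]`) or a
#'   [stimulus()] object.
#' @param schedule A [dopamine_schedule()].
#' @param p A [bg_params()] object.
#' @param duration Trial length in ms. Default 500, long enough for the
#'   slowest default-network decision (conflict resolution with intact STN)
#'   to reach steady state, and containing the default phasic window.
#' @param lesions A [lesion_spec()].
#' @return An object of class `bg_trace`: list with `times` (ms grid),
#'   matrices `C, Go, NoGo, GPe, GPi, T` (steps x N), vectors `STN, ChI,
#'   E, DA`, and the `params`, `schedule` and `lesions` used.
#' @export
#' @examples
#' tr <- simulate_trial(bg_weights(), c(0.3, 0.8, 0.3, 0.2),
#'                      dopamine_schedule(), bg_params(), duration = 300)
#' detect_gating(tr)
simulate_trial <- function(w, s, schedule = dopamine_schedule(),
                           p = bg_params(), duration = 500,
                           lesions = lesion_spec()) {
  stopifnot(inherits(w, "bg_weights"), inherits(schedule, "dopamine_schedule"),
            inherits(p, "bg_params"), inherits(lesions, "lesion_spec"))
  s <- unclass(stimulus(unclass(s)))
  if (length(s) != p$N)
    stop("stimulus length must equal N = ", p$N, call. = FALSE)
  if (schedule$event_kind != "none" &&
      duration < schedule$event_onset + schedule$event_duration)
    stop("`duration` must cover the scheduled phasic event", call. = FALSE)
  dt <- p$integrator$dt; tau <- p$integrator$tau; tau_L <- p$integrator$tau_L
  nstep <- round(duration / dt)
  sp <- p$sigmoid
  chi_fix <- sigmoid(p$I_H + p$gamma * schedule$tonic, sp)

  # loop-invariant quantities, hoisted out of the time-stepping loop
  a <- sp$a; u0 <- sp$u0
  sig <- function(u) {
    z <- -a * (u - u0)
    z[z > 500] <- 500; z[z < -500] <- -500
    1 / (1 + exp(z))
  }
  kM <- dt / tau; kL <- dt / tau_L
  in_C <- drop(w$W_CS %*% s); in_G <- drop(w$W_GS %*% s)
  in_N <- drop(w$W_NS %*% s)
  wCT <- diag(w$W_CT); wGC <- diag(w$W_GC); wNC <- diag(w$W_NC)
  wEN <- diag(w$W_EN); wIE <- diag(w$W_IE); wIG <- diag(w$W_IG)
  wTC <- diag(w$W_TC); wTI <- diag(w$W_TI)
  L <- w$L; wSTNE <- w$W_STNE
  alpha <- p$alpha; beta <- p$beta; theta_G <- p$theta_G
  I_E <- p$I_E; I_I <- p$I_I
  DA_grid <- dopamine_at(schedule, seq(0, by = dt, length.out = nstep))

  st <- network_state(p)
  if (lesions$stn_off) st$y_STN <- 0
  if (lesions$chi_clamped) st$y_H <- chi_fix

  nrec <- nstep + 1L
  N <- p$N
  recC <- matrix(NA_real_, nrec, N); recG <- matrix(NA_real_, nrec, N)
  recN <- matrix(NA_real_, nrec, N); recE <- matrix(NA_real_, nrec, N)
  recI <- matrix(NA_real_, nrec, N); recT <- matrix(NA_real_, nrec, N)
  STN <- ChI <- E <- DAv <- numeric(nrec)
  recC[1L, ] <- st$y_C; recG[1L, ] <- st$y_G; recN[1L, ] <- st$y_N
  recE[1L, ] <- st$y_E; recI[1L, ] <- st$y_I; recT[1L, ] <- st$y_T
  STN[1L] <- st$y_STN; ChI[1L] <- st$y_H
  E[1L] <- conflict_energy(st$y_C); DAv[1L] <- dopamine_at(schedule, 0)

  u_C <- st$u_C; u_L <- st$u_L; u_G <- st$u_G; u_N <- st$u_N
  u_E <- st$u_E; u_I <- st$u_I; u_T <- st$u_T
  u_STN <- st$u_STN; u_H <- st$u_H
  y_C <- st$y_C; y_G <- st$y_G; y_N <- st$y_N; y_E <- st$y_E
  y_I <- st$y_I; y_T <- st$y_T; y_STN <- st$y_STN; y_H <- st$y_H
  stn_off <- lesions$stn_off; chi_clamped <- lesions$chi_clamped

  for (k in seq_len(nstep)) {
    DA <- DA_grid[k]
    # same formulas as net_inputs(), inlined with hoisted constants
    x_C <- in_C + u_L + wCT * y_T
    x_L <- drop(L %*% y_C)
    x_G <- in_G + wGC * y_C + alpha * DA * (y_G - theta_G) + w$w_GH * y_H
    x_N <- in_N + wNC * y_C + beta * DA + w$w_NH * y_H
    x_E <- wEN * y_N + w$w_ESTN * y_STN + I_E
    x_I <- wIG * y_G + wIE * y_E + w$w_ISTN * y_STN + I_I
    x_STN <- w$k_E * (sum(y_C)^2 - sum(y_C^2)) + sum(wSTNE * y_E)
    x_T <- wTI * y_I + wTC * y_C
    x_H <- p$I_H + p$gamma * DA
    u_L <- u_L + kL * (x_L - u_L)
    u_C <- u_C + kM * (x_C - u_C); u_G <- u_G + kM * (x_G - u_G)
    u_N <- u_N + kM * (x_N - u_N); u_E <- u_E + kM * (x_E - u_E)
    u_I <- u_I + kM * (x_I - u_I); u_T <- u_T + kM * (x_T - u_T)
    u_STN <- u_STN + kM * (x_STN - u_STN); u_H <- u_H + kM * (x_H - u_H)
    if (!all(is.finite(u_C), is.finite(u_G), is.finite(u_N), is.finite(u_E),
             is.finite(u_I), is.finite(u_T), is.finite(u_STN),
             is.finite(u_H))) {
      states <- list(C = u_C, Go = u_G, NoGo = u_N, GPe = u_E, GPi = u_I,
                     T = u_T, STN = u_STN, ChI = u_H)
      bad <- names(states)[vapply(states, function(v) any(!is.finite(v)),
                                  logical(1))][1]
      stop("integration failure: non-finite state in population ", bad,
           " at t = ", format(k * dt), " ms", call. = FALSE)
    }
    y_C <- sig(u_C); y_G <- sig(u_G); y_N <- sig(u_N); y_E <- sig(u_E)
    y_I <- sig(u_I); y_T <- sig(u_T); y_STN <- sig(u_STN); y_H <- sig(u_H)
    if (stn_off) y_STN <- 0
    if (chi_clamped) y_H <- chi_fix
    recC[k + 1L, ] <- y_C; recG[k + 1L, ] <- y_G
    recN[k + 1L, ] <- y_N; recE[k + 1L, ] <- y_E
    recI[k + 1L, ] <- y_I; recT[k + 1L, ] <- y_T
    STN[k + 1L] <- y_STN; ChI[k + 1L] <- y_H
    E[k + 1L] <- sum(y_C)^2 - sum(y_C^2); DAv[k + 1L] <- DA
  }
  st <- structure(list(u_C = u_C, u_L = u_L, u_G = u_G, u_N = u_N,
                       u_E = u_E, u_I = u_I, u_T = u_T, u_STN = u_STN,
                       u_H = u_H, y_C = y_C, y_G = y_G, y_N = y_N,
                       y_E = y_E, y_I = y_I, y_T = y_T, y_STN = y_STN,
                       y_H = y_H), class = "bg_state")

  structure(list(times = seq(0, by = dt, length.out = nrec),
                 C = recC, Go = recG, NoGo = recN, GPe = recE,
                 GPi = recI, T = recT, STN = STN, ChI = ChI,
                 E = E, DA = DAv,
                 final_state = st, params = p, schedule = schedule,
                 lesions = lesions, stimulus = s),
            class = "bg_trace")
}

#' End-of-trial activities
#'
#' The decision readout: activities of every population at the last
#' simulated step.
#'
#' @param trace A `bg_trace`.
#' @return Named list of final activities (`C, Go, NoGo, GPe, GPi, T`
#'   length-`N`; `STN, ChI` scalar).
#' @export
final_activities <- function(trace) {
  stopifnot(inherits(trace, "bg_trace"))
  n <- length(trace$times)
  list(C = trace$C[n, ], Go = trace$Go[n, ], NoGo = trace$NoGo[n, ],
       GPe = trace$GPe[n, ], GPi = trace$GPi[n, ], T = trace$T[n, ],
       STN = trace$STN[n], ChI = trace$ChI[n])
}

#' Detect gated responses in a trial trace
#'
#' A channel is gated when its cortical activity is at or above the action
#' threshold at trial end; its latency is the first time the threshold was
#' crossed. The winner is the gated channel with the earliest crossing,
#' ties broken by lowest channel index; an empty gated set has winner
#' `NA`.
#'
#' @param trace A `bg_trace` from [simulate_trial()].
#' @param action_threshold Gating criterion; defaults to the threshold in
#'   the trace's parameters.
#' @return An object of class `bg_gating`: list with integer vector
#'   `gated`, named numeric `latency_ms` (one entry per gated channel) and
#'   integer `winner` (`NA` if nothing gated).
#' @export
detect_gating <- function(trace, action_threshold = NULL) {
  stopifnot(inherits(trace, "bg_trace"))
  if (is.null(action_threshold))
    action_threshold <- trace$params$action_threshold
  n <- length(trace$times)
  if (n == 0L) stop("empty trace", call. = FALSE)
  finals <- trace$C[n, ]
  gated <- which(finals >= action_threshold)
  lat <- vapply(gated, function(i) {
    k <- which(trace$C[, i] >= action_threshold)[1]
    trace$times[k]
  }, numeric(1))
  names(lat) <- as.character(gated)
  winner <- if (length(gated)) gated[order(lat, gated)[1]] else NA_integer_
  structure(list(gated = as.integer(gated), latency_ms = lat,
                 winner = as.integer(winner),
                 action_threshold = action_threshold),
            class = "bg_gating")
}

#' @export
print.bg_gating <- function(x, ...) {
  if (!length(x$gated)) {
    cat("<bg_gating> no response gated (threshold", x$action_threshold, ")\n")
  } else {
    cat("<bg_gating> gated channel(s):", paste(x$gated, collapse = ", "),
        "| winner:", x$winner,
        "| latency:", format(x$latency_ms[as.character(x$winner)]), "ms\n")
  }
  invisible(x)
}

#' @export
print.bg_trace <- function(x, ...) {
  cat("<bg_trace>", length(x$times), "steps over",
      format(max(x$times)), "ms,", x$params$N, "channels")
  if (x$lesions$stn_off) cat(" [STN off]")
  if (x$lesions$chi_clamped) cat(" [ChI clamped]")
  cat("\n")
  g <- detect_gating(x)
  print(g)
  invisible(x)
}

#' Long-format view of a trial trace
#'
#' @param x A `bg_trace`.
#' @param row.names,optional,... Ignored; present for the generic.
#' @return Data frame with columns `time_ms`, `population`, `unit`,
#'   `activity`; the conflict energy `E` and dopamine `DA` appear as
#'   pseudo-populations with unit 0.
#' @export
as.data.frame.bg_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  N <- x$params$N
  t <- x$times
  blocks <- lapply(c("C", "Go", "NoGo", "GPe", "GPi", "T"), function(pop) {
    data.frame(time_ms = rep(t, N), population = pop,
               unit = rep(seq_len(N), each = length(t)),
               activity = as.vector(x[[pop]]))
  })
  scal <- lapply(c("STN", "ChI"), function(pop) {
    data.frame(time_ms = t, population = pop, unit = 1L, activity = x[[pop]])
  })
  pseudo <- lapply(c("E", "DA"), function(pop) {
    data.frame(time_ms = t, population = pop, unit = 0L, activity = x[[pop]])
  })
  out <- do.call(rbind, c(blocks, scal, pseudo))
  out[order(out$time_ms, out$population, out$unit), , drop = FALSE]
}
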