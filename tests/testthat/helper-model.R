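# shared fixtures: default configuration and a few canned simulations
`%||%` <- function(a, b) if (is.null(a)) b else a

default_p <- bg_params()
default_w <- bg_weights()
default_lp <- learning_params()

# a trace where only channel `ch` crosses the threshold, at a known time
synthetic_trace <- function(ch = 2, cross_ms = 80, duration = 200, dt = 1,
                            p = bg_params()) {
  times <- seq(0, duration, by = dt)
  n <- length(times)
  C <- matrix(0.01, n, p$N)
  C[times >= cross_ms, ch] <- 0.99
  tmpl <- matrix(0.01, n, p$N)
  structure(list(times = times, C = C, Go = tmpl, NoGo = tmpl, GPe = tmpl,
                 GPi = tmpl, T = tmpl, STN = rep(0.01, n),
                 ChI = rep(0.3, n), E = rep(0, n), DA = rep(0.45, n),
                 params = p, schedule = dopamine_schedule(),
                 lesions = lesion_spec(), stimulus = rep(0, p$N)),
            class = "bg_trace")
}

# striatal activities at the end of a phasic feedback window
feedback_displacement <- function(kind, chi_clamped = FALSE,
                                  s = bg_stimuli()$feedback) {
  sched <- dopamine_schedule(event_kind = kind)
  tr <- simulate_trial(default_w, s, sched, default_p, duration = 150,
                       lesions = lesion_spec(chi_clamped = chi_clamped))
  n <- length(tr$times)
  list(C = tr$C[n, ], Go = tr$Go[n, ], NoGo = tr$NoGo[n, ], ChI = tr$ChI[n],
       s = s)
}
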