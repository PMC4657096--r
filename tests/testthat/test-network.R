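test_that("dopamine schedule returns tonic level outside the event window", {
  expect_equal(dopamine_at(dopamine_schedule(), c(0, 120, 499)),
               rep(0.45, 3))
  pun <- dopamine_schedule(event_kind = "punishment")
  expect_equal(dopamine_at(pun, 120), 0)
  expect_equal(dopamine_at(pun, 200), 0.45)
  expect_equal(dopamine_at(pun, 100), 0)     # onset included
  expect_equal(dopamine_at(pun, 150), 0.45)  # offset excluded
  rew <- dopamine_schedule(event_kind = "reward")
  expect_equal(dopamine_at(rew, 120), 0.9)
  expect_error(dopamine_at(rew, -1), ">= 0")
})

test_that("conflict energy counts ordered cross-products of activity", {
  expect_equal(conflict_energy(c(0, 0, 0, 0)), 0)
  expect_equal(conflict_energy(c(1, 1, 0, 0)), 2)
  expect_equal(conflict_energy(rep(0.5, 4)), 3)
  expect_equal(conflict_energy(c(0, 0.7, 0, 0)), 0)  # one active unit
  expect_error(conflict_energy(c(1.2, 0, 0, 0)), "\\[0, 1\\]")
})

test_that("net inputs at a silenced state reduce to the tonic drives", {
  st <- network_state(default_p)
  for (nm in grep("^y_", names(st), value = TRUE))
    st[[nm]] <- st[[nm]] * 0
  x <- net_inputs(st, rep(0, 4), 0.45, default_w, default_p)
  expect_equal(x$x_I, rep(3, 4))
  expect_equal(x$x_E, rep(1, 4))
  expect_equal(x$x_H, 1.25 - 0.45)
  # dopamine contrast term vanishes exactly at the Go threshold
  st$y_G <- rep(default_p$theta_G, 4)
  x <- net_inputs(st, rep(0, 4), 0.45, default_w, default_p)
  expect_equal(x$x_G, rep(0, 4))
  expect_error(net_inputs(st, rep(0, 3), 0.45, default_w, default_p),
               "does not match N")
})

test_that("one simulator step agrees with net_inputs plus euler_step", {
  p <- default_p; w <- default_w; s <- bg_stimuli()$default
  dt <- p$integrator$dt
  st <- network_state(p)
  x <- net_inputs(st, s, 0.45, w, p)
  u_C1 <- euler_step(st$u_C, x$x_C, p$integrator$tau, dt)
  u_L1 <- euler_step(st$u_L, x$x_L, p$integrator$tau_L, dt)
  tr <- simulate_trial(w, s, dopamine_schedule(), p, duration = dt)
  expect_equal(tr$C[2, ], unname(sigmoid(u_C1, p$sigmoid)), tolerance = 1e-12)
})

test_that("the resting network keeps the gate closed", {
  f <- final_activities(simulate_trial(default_w, rep(0, 4), duration = 400))
  expect_true(all(f$GPi > 0.85))              # output gate near saturation
  expect_true(all(f$GPe > 0.3 & f$GPe < 0.7)) # half-maximal pallidal tone
  expect_true(all(f$C < 0.05))
  expect_true(all(f$T < 0.05))
  expect_true(all(f$GPi > f$GPe))
  g <- detect_gating(simulate_trial(default_w, rep(0, 4), duration = 300))
  expect_length(g$gated, 0)
  expect_true(is.na(g$winner))
})

test_that("a single strong candidate is gated and the STN stays quiet", {
  tr <- simulate_trial(default_w, bg_stimuli()$default, duration = 300)
  g <- detect_gating(tr)
  expect_equal(g$gated, 2L)
  expect_equal(g$winner, 2L)
  expect_lt(max(tr$STN), 0.2)
  f <- final_activities(tr)
  expect_gte(f$C[2], 0.95)
  expect_gt(f$T[2], 0.9)          # thalamic partner disinhibited
  expect_lt(f$GPi[2], min(f$GPi[-2]))  # winner's output unit inhibited
})

test_that("conflict without the hyperdirect brake gates three actions", {
  tr <- simulate_trial(default_w, bg_stimuli()$conflict,
                       lesions = lesion_spec(stn_off = TRUE), duration = 300)
  expect_true(all(tr$STN == 0))
  g <- detect_gating(tr)
  expect_equal(g$gated, c(1L, 2L, 3L))
})

test_that("the intact STN resolves conflict to a single slower winner", {
  tr <- simulate_trial(default_w, bg_stimuli()$conflict, duration = 500)
  g <- detect_gating(tr)
  expect_equal(g$gated, 2L)
  expect_equal(g$winner, 2L)
  # STN rises with the conflict, then returns toward silence
  expect_gt(max(tr$STN), 0.5)
  expect_lt(tr$STN[length(tr$STN)], 0.1 * max(tr$STN))
  # and the resolved decision is slower than the no-conflict one
  g0 <- detect_gating(simulate_trial(default_w, bg_stimuli()$default,
                                     duration = 500))
  expect_gt(g$latency_ms[["2"]], g0$latency_ms[["2"]])
})

test_that("gating detection reads latency and winner from a trace", {
  g <- detect_gating(synthetic_trace(ch = 2, cross_ms = 80))
  expect_equal(g$gated, 2L)
  expect_equal(g$winner, 2L)
  expect_equal(unname(g$latency_ms["2"]), 80)
  none <- synthetic_trace(ch = 2, cross_ms = 80)
  none$C[] <- 0.5
  g0 <- detect_gating(none)
  expect_length(g0$gated, 0)
  # ties break toward the lowest channel index
  tie <- synthetic_trace(ch = 1, cross_ms = 60)
  tie$C[tie$times >= 60, 3] <- 0.99
  expect_equal(detect_gating(tie)$winner, 1L)
})

test_that("winner-takes-all yields at most one gated channel intact", {
  for (peak in c(0.7, 0.85, 1.0)) {
    for (ch in c(1, 3)) {
      s <- rep(0.2, 4); s[ch] <- peak
      g <- detect_gating(simulate_trial(default_w, s, duration = 300))
      expect_lte(length(g$gated), 1)
      if (length(g$gated)) expect_equal(g$winner, ch)
    }
  }
})

test_that("lesioning the cholinergic unit pins it at its tonic fixed point", {
  tr <- simulate_trial(default_w, bg_stimuli()$feedback,
                       dopamine_schedule(event_kind = "punishment"),
                       duration = 200,
                       lesions = lesion_spec(chi_clamped = TRUE))
  fix <- sigmoid(default_p$I_H + default_p$gamma * 0.45, default_p$sigmoid)
  expect_true(all(abs(tr$ChI - fix) < 1e-12))
})

test_that("a trial trace converts to a tidy long data frame", {
  tr <- simulate_trial(default_w, bg_stimuli()$default, duration = 10)
  df <- as.data.frame(tr)
  expect_named(df, c("time_ms", "population", "unit", "activity"))
  expect_setequal(unique(df$population),
                  c("C", "Go", "NoGo", "GPe", "GPi", "T", "STN", "ChI",
                    "E", "DA"))
  n_t <- length(tr$times)
  expect_equal(nrow(df), n_t * (6 * 4 + 2 + 2))
  expect_equal(df$activity[df$population == "DA"], tr$DA)
})

test_that("simulation refuses a trial shorter than its phasic event", {
  expect_error(
    simulate_trial(default_w, rep(0.1, 4),
                   dopamine_schedule(event_kind = "reward"), duration = 120),
    "cover the scheduled phasic event")
})
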