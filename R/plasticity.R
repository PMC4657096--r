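#' Hebbian learning parameters
#'
#' The two-term thresholded Hebb rule: a weight changes by
#' `sigma * [y_pre - theta_pre]_+ * (y_post - theta_post)`. The rectified
#' presynaptic factor gates learning to synapses from active cortical
#' units and salient stimulus elements; the signed postsynaptic factor
#' decides between potentiation and depression. No explicit dopamine term
#' appears: phasic dopamine acts only by displacing striatal activity away
#' from `theta_post`.
#'
#' @param sigma Learning rate. Default 0.1.
#' @param theta_pre Presynaptic eligibility threshold in (0, 1). Default 0.5.
#' @param theta_post Postsynaptic potentiation/depression threshold in
#'   (0, 1), set at the winner's tonic activity level. Default 0.5.
#' @param w_max Upper weight bound; trained weights stay in `[0, w_max]`.
#'   Default 1.2, matching the [bg_weights()] validation bound.
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(sigma = 0.1, theta_pre = 0.5, theta_post = 0.5,
                            w_max = 1.2) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (theta_pre <= 0 || theta_pre >= 1 || theta_post <= 0 || theta_post >= 1)
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  if (w_max <= 0) stop("`w_max` must be positive", call. = FALSE)
  structure(list(sigma = sigma, theta_pre = theta_pre,
                 theta_post = theta_post, w_max = w_max),
            class = "learning_params")
}

#' Training protocol configuration
#'
#' @param epochs Number of training epochs. Default 100.
#' @param noise_sd Standard deviation of the additive Gaussian stimulus
#'   noise drawn fresh each epoch. Default 0.25.
#' @param target_channel The rewarded channel (1..N). Gating it triggers a
#'   phasic dopamine peak; gating any other channel triggers a dip; a trial
#'   that gates nothing delivers no feedback and no weight update.
#' @param seed RNG seed for the stimulus noise; recorded in the history.
#' @param feedback_onset Phasic event start, ms. Default 100 (after the
#'   decision has reached steady state).
#' @param feedback_duration Phasic event length, ms. Default 50.
#' @param feedback_sample_time Instant at which pre- and postsynaptic
#'   activities are read for the Hebb update. Default end of the phasic
#'   window (onset + duration), where striatal displacement is maximal.
#' @param update_without_feedback Also apply the Hebb rule on epochs with
#'   no feedback (the resulting changes are negligible because the winner's
#'   striatal activity sits near `theta_post`). Default `FALSE`.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 100, noise_sd = 0.25, target_channel = 4,
                            seed = 1, feedback_onset = 100,
                            feedback_duration = 50,
                            feedback_sample_time = feedback_onset +
                              feedback_duration,
                            update_without_feedback = FALSE) {
  if (epochs < 0 || epochs != round(epochs))
    stop("`epochs` must be a non-negative integer", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (target_channel < 1 || target_channel != round(target_channel))
    stop("`target_channel` must be a positive integer", call. = FALSE)
  structure(list(epochs = as.integer(epochs), noise_sd = noise_sd,
                 target_channel = as.integer(target_channel),
                 seed = seed, feedback_onset = feedback_onset,
                 feedback_duration = feedback_duration,
                 feedback_sample_time = feedback_sample_time,
                 update_without_feedback = isTRUE(update_without_feedback)),
            class = "training_config")
}

#' Two-term thresholded Hebb update with clipping
#'
#' Applies `delta_w[i, j] = sigma * [y_pre[j] - theta_pre]_+ *
#' (y_post[i] - theta_post)` to the entries selected by `mask`, then clips
#' the result to `[0, w_max]`.
#'
#' @param W Weight matrix (postsynaptic rows, presynaptic columns).
#' @param y_pre Presynaptic activities (length = ncol).
#' @param y_post Postsynaptic activities (length = nrow).
#' @param lp A [learning_params()] object.
#' @param mask 0/1 matrix of trainable entries, same shape as `W`.
#' @return Updated matrix.
#' @export
#' @examples
#' lp <- learning_params()
#' hebb_update(matrix(0.5), 0.9, 0.8, lp, matrix(1))  # 0.5 + 0.1*0.4*0.3
hebb_update <- function(W, y_pre, y_post, lp, mask) {
  stopifnot(inherits(lp, "learning_params"))
  if (!all(dim(mask) == dim(W)))
    stop("`mask` shape must match `W`", call. = FALSE)
  if (length(y_pre) != ncol(W) || length(y_post) != nrow(W))
    stop("activity lengths must match weight dimensions", call. = FALSE)
  dW <- lp$sigma * outer(y_post - lp$theta_post,
                         pmax(y_pre - lp$theta_pre, 0))
  pmin(pmax(W + dW * mask, 0), lp$w_max)
}

#' Add clipped Gaussian noise to a stimulus
#'
#' Element-wise `s + N(0, noise_sd)`, then clamped back to `[0, 1]`.
#' Draws from the current RNG stream; [run_training()] seeds it once per
#' run.
#'
#' @param s Stimulus vector.
#' @param noise_sd Noise standard deviation, `>= 0`.
#' @return Perturbed stimulus vector, elements in `[0, 1]`.
#' @export
noisy_stimulus <- function(s, noise_sd) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  s <- unclass(stimulus(unclass(s)))
  if (noise_sd == 0) return(s)
  pmin(pmax(s + stats::rnorm(length(s), 0, noise_sd), 0), 1)
}

#' Multi-epoch reward/punishment training
#'
#' Runs the full training protocol. Each epoch: (1) draw a noisy copy of
#' the stimulus; (2) simulate a trial under tonic dopamine and detect
#' gating; (3) if a response was gated, re-simulate with the phasic event
#' (a dopamine peak if the winner is the target channel, a dip otherwise)
#' and read cortical and stimulus activities (presynaptic) and Go/NoGo
#' activities (postsynaptic) at the feedback sample time; (4) apply the
#' Hebb rule to the four trainable corticostriatal matrices (diagonal mask
#' for the cortex-to-striatum pairs, full mask for the stimulus-to-striatum
#' pairs) from the same sampled activities. An epoch that gates nothing
#' delivers no feedback and, by default, no update.
#'
#' @param w0 Initial [bg_weights()].
#' @param s Stimulus vector (the context being trained).
#' @param cfg A [training_config()].
#' @param lp A [learning_params()].
#' @param p A [bg_params()].
#' @param lesions A [lesion_spec()] applied to every trial (e.g. ChI
#'   clamped, to probe the cholinergic contribution to learning).
#' @param duration Decision-trial length in ms, passed to
#'   [simulate_trial()].
#' @param keep_snapshots Record a copy of the four trainable matrices after
#'   every epoch (`TRUE`, default) or only first and last (`FALSE`).
#' @return An object of class `bg_weight_history`: list with `snapshots`
#'   (list of per-epoch named lists of the four matrices, the first being
#'   the pretraining state), `outcomes` (data frame: `epoch`, `winner`,
#'   `feedback`), `weights` (a full `bg_weights` with the trained matrices
#'   substituted), `seed` and `config`.
#' @export
run_training <- function(w0, s, cfg = training_config(),
                         lp = learning_params(), p = bg_params(),
                         lesions = lesion_spec(), duration = 500,
                         keep_snapshots = TRUE) {
  stopifnot(inherits(w0, "bg_weights"), inherits(cfg, "training_config"),
            inherits(lp, "learning_params"), inherits(p, "bg_params"))
  if (cfg$target_channel > p$N)
    stop("`target_channel` exceeds N = ", p$N, call. = FALSE)
  s <- unclass(stimulus(unclass(s)))
  set.seed(cfg$seed)
  w <- w0
  masks <- lapply(stats::setNames(trainable_weights(), trainable_weights()),
                  trainable_mask, N = p$N)
  snap <- function(w) lapply(w[trainable_weights()], identity)
  snapshots <- vector("list", cfg$epochs + 1L)
  snapshots[[1L]] <- snap(w)
  outcomes <- data.frame(epoch = integer(), winner = integer(),
                         feedback = character())
  tonic <- dopamine_schedule(event_kind = "none")
  fb_dur <- max(cfg$feedback_sample_time,
                cfg$feedback_onset + cfg$feedback_duration)

  for (ep in seq_len(cfg$epochs)) {
    s_ep <- noisy_stimulus(s, cfg$noise_sd)
    tr <- tryCatch(
      simulate_trial(w, s_ep, tonic, p, duration = duration,
                     lesions = lesions),
      error = function(e) stop("epoch ", ep, ": ", conditionMessage(e),
                               call. = FALSE))
    g <- detect_gating(tr)
    feedback <- "none"
    if (length(g$gated)) {
      feedback <- if (g$winner == cfg$target_channel) "reward" else
        "punishment"
      sched <- dopamine_schedule(tonic = tonic$tonic, event_kind = feedback,
                                 event_onset = cfg$feedback_onset,
                                 event_duration = cfg$feedback_duration)
      trf <- simulate_trial(w, s_ep, sched, p, duration = fb_dur,
                            lesions = lesions)
      k <- which.min(abs(trf$times - cfg$feedback_sample_time))
      y_C <- trf$C[k, ]; y_G <- trf$Go[k, ]; y_N <- trf$NoGo[k, ]
      w$W_GC <- hebb_update(w$W_GC, y_C, y_G, lp, masks$W_GC)
      w$W_NC <- hebb_update(w$W_NC, y_C, y_N, lp, masks$W_NC)
      w$W_GS <- hebb_update(w$W_GS, s_ep, y_G, lp, masks$W_GS)
      w$W_NS <- hebb_update(w$W_NS, s_ep, y_N, lp, masks$W_NS)
    } else if (cfg$update_without_feedback) {
      n <- length(tr$times)
      y_C <- tr$C[n, ]; y_G <- tr$Go[n, ]; y_N <- tr$NoGo[n, ]
      w$W_GC <- hebb_update(w$W_GC, y_C, y_G, lp, masks$W_GC)
      w$W_NC <- hebb_update(w$W_NC, y_C, y_N, lp, masks$W_NC)
      w$W_GS <- hebb_update(w$W_GS, s_ep, y_G, lp, masks$W_GS)
      w$W_NS <- hebb_update(w$W_NS, s_ep, y_N, lp, masks$W_NS)
    }
    if (keep_snapshots || ep == cfg$epochs) snapshots[[ep + 1L]] <- snap(w)
    outcomes <- rbind(outcomes,
                      data.frame(epoch = ep, winner = g$winner,
                                 feedback = feedback))
  }
  validate_weights(w)
  structure(list(snapshots = snapshots, outcomes = outcomes, weights = w,
                 seed = cfg$seed, config = cfg),
            class = "bg_weight_history")
}

#' Per-epoch trajectory of one trained weight
#'
#' @param history A `bg_weight_history`.
#' @param matrix_name One of [trainable_weights()].
#' @param i,j Entry indices.
#' @return Numeric vector of length `epochs + 1` (pretraining value first);
#'   `NA` where snapshots were not kept.
#' @export
weight_trajectory <- function(history, matrix_name, i, j) {
  stopifnot(inherits(history, "bg_weight_history"))
  matrix_name <- match.arg(matrix_name, trainable_weights())
  vapply(history$snapshots, function(sn) {
    if (is.null(sn)) NA_real_ else sn[[matrix_name]][i, j]
  }, numeric(1))
}

#' @export
print.bg_weight_history <- function(x, ...) {
  ne <- nrow(x$outcomes)
  cat("<bg_weight_history>", ne, "epochs, seed", x$seed, "\n")
  if (ne) {
    tab <- table(x$outcomes$feedback)
    cat("  feedback:", paste(names(tab), tab, sep = " = ", collapse = ", "),
        "\n")
  }
  fin <- x$weights
  cat("  final W_GC diag:", format(diag(fin$W_GC), digits = 3), "\n")
  cat("  final W_NC diag:", format(diag(fin$W_NC), digits = 3), "\n")
  invisible(x)
}
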