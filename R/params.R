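#' Model parameters
#'
#' Scalar constants governing the network in its default state: tonic
#' external drives to the pallidal segments and the cholinergic unit, the
#' dopamine gains on the three modulated targets, the Go contrast-enhancement
#' threshold, and the cortical action threshold that defines a gated
#' response.
#'
#' Dopamine acts with opposite sign on the two striatal compartments:
#' on a Go (D1) unit its effect is `alpha * DA * (y_G - theta_G)` --
#' excitatory once the unit is already above `theta_G`, inhibitory below
#' (contrast enhancement) -- while a NoGo (D2) unit receives the plain
#' inhibitory drive `beta * DA` (`beta < 0`). The cholinergic unit is
#' inhibited by dopamine through `gamma * DA` (`gamma < 0`).
#'
#' @param N Number of segregated action channels. Default 4.
#' @param theta_G Go-unit activity threshold of the dopamine contrast term.
#' @param alpha Dopamine gain on Go units, positive.
#' @param beta Dopamine gain on NoGo units, negative.
#' @param gamma Dopamine gain on the cholinergic unit, negative.
#' @param I_E,I_I,I_H Tonic external inputs to GPe, GPi and the cholinergic
#'   unit; they set the nuclei's rest activities (GPe about half-maximal,
#'   GPi near saturation, ChI tonically active).
#' @param action_threshold Cortical activity above which a response counts
#'   as gated; chosen close to saturation (0.95).
#' @param sigmoid A [sigmoid_params()] object shared by all units.
#' @param integrator An [integrator_config()] object.
#' @return An object of class `bg_params`.
#' @export
bg_params <- function(N = 4, theta_G = 0.3, alpha = 1, beta = -1, gamma = -1,
                      I_E = 1, I_I = 3, I_H = 1.25,
                      action_threshold = 0.95,
                      sigmoid = sigmoid_params(),
                      integrator = integrator_config()) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("`N` must be an integer >= 2", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  if (beta >= 0) stop("`beta` must be negative", call. = FALSE)
  if (gamma >= 0) stop("`gamma` must be negative", call. = FALSE)
  if (action_threshold <= 0 || action_threshold >= 1)
    stop("`action_threshold` must be in (0, 1)", call. = FALSE)
  stopifnot(inherits(sigmoid, "sigmoid_params"),
            inherits(integrator, "integrator_config"))
  structure(list(N = as.integer(N), theta_G = theta_G, alpha = alpha,
                 beta = beta, gamma = gamma, I_E = I_E, I_I = I_I, I_H = I_H,
                 action_threshold = action_threshold,
                 sigmoid = sigmoid, integrator = integrator),
            class = "bg_params")
}

#' @export
print.bg_params <- function(x, ...) {
  cat("<bg_params> N =", x$N, "channels\n")
  cat("  dopamine gains: alpha =", x$alpha, ", beta =", x$beta,
      ", gamma =", x$gamma, "; theta_G =", x$theta_G, "\n")
  cat("  tonic drives: I_E =", x$I_E, ", I_I =", x$I_I, ", I_H =", x$I_H, "\n")
  cat("  action threshold =", x$action_threshold, "\n")
  print(x$sigmoid); print(x$integrator)
  invisible(x)
}

# connection inventory: name, structure, sign, trainability
.weight_schema <- list(
  L      = list(shape = "extradiag", sign = -1, trainable = FALSE),
  W_CS   = list(shape = "full",      sign = +1, trainable = FALSE),
  W_CT   = list(shape = "diag",      sign = +1, trainable = FALSE),
  W_GC   = list(shape = "diag",      sign = +1, trainable = TRUE),
  W_GS   = list(shape = "full",      sign = +1, trainable = TRUE),
  W_NC   = list(shape = "diag",      sign = +1, trainable = TRUE),
  W_NS   = list(shape = "full",      sign = +1, trainable = TRUE),
  W_EN   = list(shape = "diag",      sign = -1, trainable = FALSE),
  W_IE   = list(shape = "diag",      sign = -1, trainable = FALSE),
  W_IG   = list(shape = "diag",      sign = -1, trainable = FALSE),
  W_TC   = list(shape = "diag",      sign = +1, trainable = FALSE),
  W_TI   = list(shape = "diag",      sign = -1, trainable = FALSE),
  w_ESTN = list(shape = "scalar",    sign = +1, trainable = FALSE),
  w_ISTN = list(shape = "scalar",    sign = +1, trainable = FALSE),
  k_E    = list(shape = "scalar",    sign = +1, trainable = FALSE),
  W_STNE = list(shape = "row",       sign = -1, trainable = FALSE),
  w_GH   = list(shape = "scalar",    sign = -1, trainable = FALSE),
  w_NH   = list(shape = "scalar",    sign = +1, trainable = FALSE)
)

.diag_mat <- function(v, N) diag(rep(v, length.out = N), N)

#' Synaptic weight set
#'
#' The 18 connection matrices and scalars of the network in its pretraining
#' default state. Diagonal matrices reflect the channel segregation of the
#' basal-ganglia loops; the cortical lateral-inhibition matrix `L` has zero
#' diagonal; four corticostriatal matrices (`W_GC`, `W_NC` diagonal;
#' `W_GS`, `W_NS` full) are trainable and constrained to `[0, w_max]`.
#'
#' Called with no arguments this returns the default pretraining weights.
#' Any entry can be overridden with a scalar (expanded to the matrix
#' structure) or a full matrix of the right shape.
#'
#' @param N Number of action channels. Default 4.
#' @param ... Named overrides among `L, W_CS, W_CT, W_GC, W_GS, W_NC, W_NS,
#'   W_EN, W_IE, W_IG, W_TC, W_TI, w_ESTN, w_ISTN, k_E, W_STNE, w_GH, w_NH`.
#' @param w_max Upper bound on trainable weights used for validation;
#'   the default (1.2) sits just above the largest pretraining trainable
#'   weight, so the default weight set is a valid starting point and the
#'   cortex-to-NoGo synapses keep headroom to potentiate.
#' @return An object of class `bg_weights`: a named list of matrices,
#'   scalars and one length-`N` row (`W_STNE`), plus attributes `N` and
#'   `w_max`.
#' @export
bg_weights <- function(N = 4, ..., w_max = 1.2) {
  w <- list(
    L      = { m <- matrix(-1.2, N, N); diag(m) <- 0; m },
    W_CS   = { m <- matrix(0.2, N, N); diag(m) <- 1.1; m },
    W_CT   = .diag_mat(4, N),
    W_GC   = .diag_mat(0.48, N),
    W_GS   = .diag_mat(0.9, N),
    W_NC   = .diag_mat(1.08, N),
    W_NS   = .diag_mat(0.1, N),
    W_EN   = .diag_mat(-2.2, N),
    W_IE   = .diag_mat(-3, N),
    W_IG   = .diag_mat(-12, N),
    W_TC   = .diag_mat(3, N),
    W_TI   = .diag_mat(-3, N),
    w_ESTN = 1,
    w_ISTN = 14,
    k_E    = 7,
    W_STNE = rep(-1, N),
    w_GH   = -1,
    w_NH   = 1
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(w))
  if (length(bad))
    stop("unknown weight name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(dots)) {
    v <- dots[[nm]]
    sch <- .weight_schema[[nm]]
    if (sch$shape %in% c("full", "diag", "extradiag")) {
      if (length(v) == 1L) {
        v <- switch(sch$shape,
          full = matrix(v, N, N),
          diag = .diag_mat(v, N),
          extradiag = { m <- matrix(v, N, N); diag(m) <- 0; m })
      }
      v <- as.matrix(v)
    }
    w[[nm]] <- v
  }
  out <- structure(w, class = "bg_weights", N = as.integer(N), w_max = w_max)
  validate_weights(out)
  out
}

#' Validate a synaptic weight set
#'
#' Checks dimensions, the diagonal/extradiagonal structure, the sign of
#' every connection (inhibitory entries <= 0, excitatory >= 0) and the
#' `[0, w_max]` bound on the trainable corticostriatal matrices. Called by
#' [bg_weights()] and after every learning update.
#'
#' @param w A `bg_weights` object.
#' @return `w`, invisibly; errors describe the first offending connection.
#' @export
validate_weights <- function(w) {
  stopifnot(inherits(w, "bg_weights"))
  N <- attr(w, "N"); w_max <- attr(w, "w_max")
  for (nm in names(.weight_schema)) {
    sch <- .weight_schema[[nm]]
    v <- w[[nm]]
    if (is.null(v) || any(!is.finite(v)))
      stop("weight `", nm, "` is missing or non-finite", call. = FALSE)
    if (sch$shape == "scalar" && length(v) != 1L)
      stop("weight `", nm, "` must be a scalar", call. = FALSE)
    if (sch$shape == "row" && length(v) != N)
      stop("weight `", nm, "` must have length N = ", N, call. = FALSE)
    if (sch$shape %in% c("full", "diag", "extradiag")) {
      if (!is.matrix(v) || !all(dim(v) == N))
        stop("weight `", nm, "` must be an ", N, "x", N, " matrix",
             call. = FALSE)
      if (sch$shape == "diag" && any(v[row(v) != col(v)] != 0))
        stop("weight `", nm, "` must be diagonal (zero off-diagonal)",
             call. = FALSE)
      if (sch$shape == "extradiag" && any(diag(v) != 0))
        stop("weight `", nm, "` must have zero diagonal", call. = FALSE)
    }
    chk <- if (sch$shape == "diag") diag(as.matrix(v)) else v
    if (sch$sign > 0 && any(chk < 0))
      stop("excitatory weight `", nm, "` has negative entries", call. = FALSE)
    if (sch$sign < 0 && any(chk > 0))
      stop("inhibitory weight `", nm, "` has positive entries", call. = FALSE)
    if (isTRUE(sch$trainable) && any(v < 0 | v > w_max))
      stop("trainable weight `", nm, "` outside [0, ", w_max, "]",
           call. = FALSE)
  }
  invisible(w)
}

#' Names of the trainable corticostriatal matrices
#' @return Character vector `c("W_GC", "W_NC", "W_GS", "W_NS")`.
#' @export
trainable_weights <- function() c("W_GC", "W_NC", "W_GS", "W_NS")

#' Trainable-entry mask for a corticostriatal matrix
#'
#' `W_GC` and `W_NC` are structurally diagonal (channel segregation), so
#' only their diagonals learn; `W_GS` and `W_NS` learn all entries.
#'
#' @param name One of [trainable_weights()].
#' @param N Number of channels.
#' @return An `N x N` 0/1 matrix.
#' @export
trainable_mask <- function(name, N = 4) {
  name <- match.arg(name, trainable_weights())
  if (name %in% c("W_GC", "W_NC")) diag(1, N) else matrix(1, N, N)
}

#' @export
print.bg_weights <- function(x, ...) {
  N <- attr(x, "N")
  cat("<bg_weights> ", N, "action channels, 18 connections\n")
  cat("  trainable (bounded to [0,", attr(x, "w_max"), "]):",
      paste(trainable_weights(), collapse = ", "), "\n")
  diags <- vapply(c("W_GC", "W_NC", "W_GS", "W_NS"),
                  function(nm) x[[nm]][1, 1], numeric(1))
  cat("  corticostriatal diagonals:",
      paste(names(diags), "=", format(diags), collapse = ", "), "\n")
  invisible(x)
}

#' Stimulus vector
#'
#' The input pattern: a cortical representation of the external context,
#' one element per action channel, each in `[0, 1]`.
#'
#' @param s Numeric vector with elements in `[0, 1]`.
#' @return `s`, validated, with class `bg_stimulus`.
#' @export
stimulus <- function(s) {
  if (!is.numeric(s) || any(!is.finite(s)))
    stop("stimulus must be finite numeric", call. = FALSE)
  if (any(s < 0 | s > 1))
    stop("stimulus elements must lie in [0, 1]", call. = FALSE)
  structure(as.numeric(s), class = "bg_stimulus")
}
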