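#' Write a trial trace as long-format CSV
#'
#' Columns `time_ms, population, unit, activity`; the conflict energy `E`
#' and dopamine level `DA` appear as pseudo-populations with unit 0.
#'
#' @param trace A `bg_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "bg_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Write a gating result as JSON
#'
#' @param gating A `bg_gating` from [detect_gating()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gating_json <- function(gating, path) {
  stopifnot(inherits(gating, "bg_gating"))
  obj <- list(gated = gating$gated,
              winner = if (is.na(gating$winner)) NULL else gating$winner,
              latency_ms = as.list(gating$latency_ms),
              action_threshold = gating$action_threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a training weight history as CSV
#'
#' One row per recorded entry: `epoch` (0 = pretraining), `matrix`, `i`,
#' `j`, `value`.
#'
#' @param history A `bg_weight_history` from [run_training()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weight_history_csv <- function(history, path) {
  stopifnot(inherits(history, "bg_weight_history"))
  rows <- list()
  for (ep in seq_along(history$snapshots)) {
    sn <- history$snapshots[[ep]]
    if (is.null(sn)) next
    for (nm in names(sn)) {
      m <- sn[[nm]]
      idx <- which(m == m, arr.ind = TRUE)  # all entries
      rows[[length(rows) + 1L]] <-
        data.frame(epoch = ep - 1L, matrix = nm,
                   i = idx[, 1], j = idx[, 2], value = as.vector(m))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

.weights_to_list <- function(w) {
  out <- lapply(unclass(w), function(v) {
    if (is.matrix(v)) apply(v, 1, identity, simplify = FALSE) else v
  })
  out
}

.params_to_list <- function(p) {
  list(N = p$N, tau = p$integrator$tau, tau_L = p$integrator$tau_L,
       dt = p$integrator$dt, a = p$sigmoid$a, u0 = p$sigmoid$u0,
       theta_G = p$theta_G, I_E = p$I_E, I_I = p$I_I, I_H = p$I_H,
       alpha = p$alpha, beta = p$beta, gamma = p$gamma,
       action_threshold = p$action_threshold)
}

#' Default model configuration as a plain list
#'
#' Two blocks: `params` (all scalar constants, time constants and sigmoid
#' shape) and `weights` (the 18 pretraining connection values, matrices as
#' lists of rows). [write_config()] serializes this structure;
#' [read_config()] restores it to `bg_params` / `bg_weights` objects.
#'
#' @param p,w Parameter and weight objects to export.
#' @return Named list with `params` and `weights` blocks.
#' @export
default_config <- function(p = bg_params(), w = bg_weights()) {
  list(params = .params_to_list(p), weights = .weights_to_list(w))
}

#' Write a model configuration to YAML or JSON
#'
#' @param config A list as produced by [default_config()].
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(config, path)
  } else if (ext == "json") {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported config extension: ", ext, call. = FALSE)
  invisible(path)
}

#' Read a model configuration from YAML or JSON
#'
#' Accepts the schema written by [write_config()]; missing entries fall
#' back to the defaults, so a partial file overriding a few values is
#' valid.
#'
#' @param path Config file path (`.yaml`, `.yml` or `.json`).
#' @return List with elements `params` (a [bg_params()]) and `weights`
#'   (a [bg_weights()]).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else stop("unsupported config extension: ", ext, call. = FALSE)
  def <- .params_to_list(bg_params())
  pl <- utils::modifyList(def, raw$params %||% list())
  p <- bg_params(N = pl$N, theta_G = pl$theta_G, alpha = pl$alpha,
                 beta = pl$beta, gamma = pl$gamma, I_E = pl$I_E,
                 I_I = pl$I_I, I_H = pl$I_H,
                 action_threshold = pl$action_threshold,
                 sigmoid = sigmoid_params(a = pl$a, u0 = pl$u0),
                 integrator = integrator_config(dt = pl$dt, tau = pl$tau,
                                                tau_L = pl$tau_L))
  wl <- raw$weights %||% list()
  wl <- lapply(wl, function(v) {
    if (is.list(v)) do.call(rbind, lapply(v, unlist))
    else if (is.matrix(v)) v
    else if (length(v) > 1L) v
    else v
  })
  w <- do.call(bg_weights, c(list(N = p$N), wl))
  list(params = p, weights = w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
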