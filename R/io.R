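#' Save / load parameter sets
#'
#' Parameters (with their configuration) are written to an R-native
#' serialized container next to a human-readable JSON echo of the
#' configuration, so a run directory is self-describing:
#' `<path>/params.rds` and `<path>/config.json`. Training fits
#' additionally write their validation history to `history.csv`.
#'
#' @param params An `"mpn_params"` or `"mpn_fit"`.
#' @param path Directory to write to (created if missing).
#' @return (Invisibly) `path`.
#' @export
save_params <- function(params, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fit <- NULL
  if (inherits(params, "mpn_fit")) {
    fit <- params
    params <- fit$params
    utils::write.csv(fit$history, file.path(path, "history.csv"),
                     row.names = FALSE)
  }
  cfg <- params$config
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       file.path(path, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(if (is.null(fit)) params else fit, file.path(path, "params.rds"))
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  readRDS(file.path(path, "params.rds"))
}

#' Read / write a model configuration as flat JSON
#'
#' @param config An [model_config()].
#' @param file JSON file path.
#' @return `write_config` returns `file` invisibly; `read_config` returns
#'   the `"mpn_config"`.
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "mpn_config"))
  jsonlite::write_json(config[!vapply(config, is.null, TRUE)], file,
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  model_config(family = x$family, d = x$d, n = x$n, N = x$N,
               rule = x$rule, activation = x$activation,
               lambda_max = x$lambda_max, m_b = x$m_b,
               hidden_bias = isTRUE(x$hidden_bias),
               readout_bias = isTRUE(x$readout_bias))
}

#' Export a generated dataset
#'
#' Writes a batch of generated sequences to a directory as plain files:
#' `inputs.csv` (one row per (example, t) with the d input columns),
#' `labels.csv` (label, evidence, per-step symbols collapsed), and a JSON
#' manifest recording the task spec.
#'
#' @param batch A batch from [sample_batch()].
#' @param spec The [task_spec()] that generated it.
#' @param path Output directory.
#' @return (Invisibly) `path`.
#' @export
export_dataset <- function(batch, spec, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(batch$X)[1]; Tn <- dim(batch$X)[2]; B <- dim(batch$X)[3]
  flat <- matrix(aperm(batch$X, c(2, 3, 1)), Tn * B, d)
  df <- data.frame(example = rep(seq_len(B), each = Tn),
                   t = rep(seq_len(Tn), times = B))
  utils::write.csv(cbind(df, as.data.frame(flat)),
                   file.path(path, "inputs.csv"), row.names = FALSE)
  utils::write.csv(data.frame(example = seq_len(B), label = batch$labels,
                              symbols = apply(batch$symbols, 2, paste,
                                              collapse = " ")),
                   file.path(path, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(spec)[!vapply(spec, is.null, TRUE)],
                       file.path(path, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
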