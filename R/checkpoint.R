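# Model checkpoints: a single-file weight archive plus a human-readable
# key-value sidecar describing the architecture.

#' Save a model checkpoint
#'
#' Writes the model (weights + configuration) as a single RDS archive and a
#' YAML sidecar `<path>.yml` with the configuration, for inspection without
#' loading the weights.
#'
#' @param model An `mrl_predictor` or `utr_generator`.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, c("mrl_predictor", "utr_generator"))) {
    stop("`model` must be an mrl_predictor or utr_generator", call. = FALSE)
  }
  model$opt_state <- NULL  # optimiser state is not part of the artifact
  saveRDS(model, path)
  meta <- c(list(class = class(model)[1L], trained = isTRUE(model$trained)),
            unclass(model$cfg))
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return The restored model object.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("checkpoint not found: %s", path), call. = FALSE)
  }
  model <- readRDS(path)
  if (!inherits(model, c("mrl_predictor", "utr_generator"))) {
    stop("file is not a ribolift checkpoint", call. = FALSE)
  }
  model
}
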