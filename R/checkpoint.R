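#' Save and load model checkpoints
#'
#' A checkpoint is a single file holding the model's spec, all parameters
#' (weights, biases, batch-norm state), the training configuration and
#' history, and the initialization seed, so a run can be resumed or
#' audited. Works for `dcae`, `stage1_model` and `stage2_model` objects.
#'
#' @param model a model object.
#' @param path checkpoint file path (conventionally `.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("dcae", "stage1_model", "stage2_model")))
    abort("save_model() supports dcae, stage1_model and stage2_model objects")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("checkpoint not found: ", path))
  model <- readRDS(path)
  if (!inherits(model, c("dcae", "stage1_model", "stage2_model")))
    abort("file is not a recognized model checkpoint")
  model
}
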