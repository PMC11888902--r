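#' Save / load a fitted model
#'
#' The fitted model is written as a serialized parameter bundle
#' (`model.rds`) next to a human-readable JSON sidecar (`model.json`)
#' recording the model class and its configuration, so a run directory is
#' self-describing.
#'
#' @param model a fitted classifier from this package.
#' @param dir directory to write into (created if missing).
#' @return `save_model` returns `dir` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, dir) {
  if (!inherits(model, "bcg_model")) stop_bcg("expected a fitted bcg model")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  cfg <- model$cfg
  sidecar <- list(
    model_class = class(model)[1],
    package = "bcgscreen",
    config = if (is.null(cfg)) NULL else unclass(cfg)
  )
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_model
#' @param dir directory written by `save_model`.
#' @export
load_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop_bcg("no model.rds under ", dir)
  model <- readRDS(path)
  if (!inherits(model, "bcg_model")) stop_bcg("not a bcgscreen model bundle")
  model
}
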