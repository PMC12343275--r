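# Checkpoints, YAML run configuration, and a small level-tagged logger.

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the trainable parameters, the
#' batch-norm state, the architecture configuration and the training
#' history, so a model restores to exactly the object that was saved.
#'
#' @param model A `cytoattn_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint`: invisibly, `path`; `load_checkpoint`: the
#'   restored `cytoattn_model`.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop("checkpoint not found: ", path,
         " (run training first, or point --checkpoint at an existing file)")
  m <- readRDS(path)
  if (!inherits(m, "cytoattn_model"))
    stop("file is not a cytoattn checkpoint: ", path)
  m
}

#' Read and validate a YAML run configuration
#'
#' The file may carry `dataset`, `architecture`, `training`,
#' `evaluation` and `visualization` sections; missing fields fall back to
#' package defaults. The resolved configuration is what every command
#' writes beside its outputs.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return List with `spec` ([dataset_spec()]), `arch` ([arch_config()]),
#'   `train` ([train_config()]), and `options` (remaining fields).
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("dataset", "architecture", "training", "evaluation",
             "visualization", "output_dir", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  ds <- raw$dataset
  counts <- if (!is.null(ds$per_class_counts))
    unlist(ds$per_class_counts) else formals(dataset_spec)$per_class_counts
  spec <- dataset_spec(
    per_class_counts = if (is.language(counts)) eval(counts) else counts,
    image_size = ds$image_size %||% c(128L, 128L),
    master_seed = ds$master_seed %||% raw$seed %||% 1L)
  ar <- raw$architecture
  arch <- arch_config(
    input_size = ar$input_size %||% c(64L, 64L),
    stem_channels = ar$stem_channels %||% 32L,
    stage_channels = ar$stage_channels %||% c(32L, 64L, 128L),
    attention_kernel = ar$attention_kernel %||% 1L,
    num_classes = ar$num_classes %||% length(spec$per_class_counts),
    class_names = ar$class_names %||% names(spec$per_class_counts),
    stem_stride = ar$stem_stride %||% 2L)
  tr <- raw$training
  train <- train_config(
    epochs = tr$epochs %||% 30L,
    batch_size = tr$batch_size %||% 32L,
    base_lr = tr$base_lr %||% 1e-3,
    lr_halving_period = tr$lr_halving_period %||% 10L,
    seed = tr$seed %||% raw$seed %||% 1L,
    split_fraction = tr$split_fraction %||% 0.5)
  list(spec = spec, arch = arch, train = train,
       options = raw[c("evaluation", "visualization", "output_dir")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the resolved run configuration beside run outputs
#' @param cfg List from [read_run_config()].
#' @param dir Output directory.
#' @return Invisibly, the YAML path.
#' @export
write_run_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, "resolved_config.yaml")
  yaml::write_yaml(list(
    dataset = list(per_class_counts = as.list(cfg$spec$per_class_counts),
                   image_size = cfg$spec$image_size,
                   master_seed = cfg$spec$master_seed),
    architecture = unclass(cfg$arch),
    training = unclass(cfg$train)), p)
  invisible(p)
}

# timestamped level-tagged logger writing to stderr and (optionally) a file
make_logger <- function(logfile = NULL) {
  function(level, ...) {
    line <- sprintf("[%s] %-5s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    level, paste0(...))
    message(line)
    if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  }
}
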