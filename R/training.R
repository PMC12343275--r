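# Training: seeded stratified splitting, the halving learning-rate
# schedule, and mini-batch Adam over the hand-derived backward pass.

#' Training configuration
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param base_lr Initial Adam learning rate.
#' @param lr_halving_period The learning rate is halved every this many
#'   epochs.
#' @param seed Seed driving the per-epoch batch shuffles (each epoch
#'   through its own derived seed); weight initialization is seeded
#'   separately when the model is built.
#' @param split_fraction Fraction of each class assigned to the training
#'   set by [stratified_split()] (default 0.5, a 50/50 split).
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, base_lr = 1e-3,
                         lr_halving_period = 10L, seed = 1L,
                         split_fraction = 0.5,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(epochs >= 0L, batch_size >= 1L, base_lr > 0,
            lr_halving_period >= 1L,
            split_fraction > 0, split_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 base_lr = base_lr,
                 lr_halving_period = as.integer(lr_halving_period),
                 seed = as.integer(seed),
                 split_fraction = split_fraction,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' The schedule halves the base learning rate every
#' `lr_halving_period` epochs: `base_lr * 0.5^floor(epoch / period)`
#' with `epoch` counted from 0.
#'
#' @param epoch Zero-based epoch index.
#' @param config A [train_config()].
#' @return The learning rate in effect during that epoch.
#' @examples
#' lr_at_epoch(25, train_config(base_lr = 1e-3, lr_halving_period = 10))
#' # 0.00025
#' @export
lr_at_epoch <- function(epoch, config) {
  stopifnot(all(epoch >= 0))
  config$base_lr * 0.5^(floor(epoch / config$lr_halving_period))
}

#' Seeded stratified train/test split
#'
#' Splits a manifest per class: each class contributes
#' `round-to-training(fraction * n)` samples to the training set, the rest
#' to the test set (with an odd count, the extra sample goes to training).
#' The two parts are disjoint and their union is the input; the split is
#' deterministic for a given seed.
#'
#' @param manifest Data frame with a `label` column.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` manifests.
#' @export
stratified_split <- function(manifest, fraction = 0.5, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1, "label" %in% names(manifest))
  counts <- table(manifest$label)
  small <- names(counts)[counts < 2L]
  if (length(small))
    stop("class(es) with fewer than 2 samples cannot be split: ",
         paste(small, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  train_idx <- integer()
  for (cls in names(counts)) {
    idx <- which(manifest$label == cls)
    n_train <- ceiling(fraction * length(idx)) # extra sample to training
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = manifest[train_idx, , drop = FALSE],
       test = manifest[setdiff(seq_len(nrow(manifest)), train_idx), ,
                       drop = FALSE])
}

# one Adam step over the flat parameter list; opt carries (m, v, t)
adam_step <- function(params, grads, opt, lr, cfg) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- cfg$beta1 * opt$m[[nm]] + (1 - cfg$beta1) * g
    opt$v[[nm]] <- cfg$beta2 * opt$v[[nm]] + (1 - cfg$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + cfg$adam_eps)
  }
  list(params = params, opt = opt)
}

#' Train a model
#'
#' Mini-batch training with cross-entropy loss, the Adam optimizer and the
#' halving learning-rate schedule. Batches are reshuffled every epoch with
#' a seeded generator; given the same data, configuration and seed, two
#' runs produce bit-identical parameters and history.
#'
#' @param model A `cytoattn_model` (any of the three architectures),
#'   trained starting from its current weights.
#' @param images List of `(H, W, 3)` pixel arrays in `[0, 255]`, or a list
#'   of `image_sample`s.
#' @param labels Character/factor vector of class labels (taken from the
#'   samples when `images` are `image_sample`s).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @param epoch_hook Optional `function(model, epoch)` called after each
#'   epoch (used e.g. to probe attention-map stability).
#' @return The trained model, with a `history` data frame attached
#'   (per-epoch mean training loss, learning rate, training accuracy).
#' @export
train_model <- function(model, images, labels = NULL,
                        config = train_config(), verbose = FALSE,
                        epoch_hook = NULL) {
  if (length(images) && inherits(images[[1L]], "image_sample")) {
    if (is.null(labels))
      labels <- vapply(images, `[[`, character(1), "label")
    images <- lapply(images, `[[`, "pixels")
  }
  if (length(images) == 0L) stop("empty training set")
  stopifnot(length(labels) == length(images))
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), model$config$class_names)
  if (length(unknown))
    stop("label(s) not in the model's class set: ",
         paste(unknown, collapse = ", "))

  x_all <- as_batch(images, model$config$input_size)
  y_all <- match(labels, model$config$class_names)
  n <- length(y_all)

  opt <- list(m = lapply(model$params, function(p) p * 0),
              v = lapply(model$params, function(p) p * 0), t = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                     accuracy = numeric())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  for (ep in seq_len(config$epochs)) {
    lr <- lr_at_epoch(ep - 1L, config)
    set.seed(derive_seed(config$seed, 2L, ep))
    ord <- sample.int(n)
    losses <- numeric()
    ncorrect <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x_all[, , , idx, drop = FALSE]
      yb <- y_all[idx]
      fw <- sa_dispatch_forward(model, xb, training = TRUE)
      model$state <- fw$state
      loss <- cross_entropy(fw$probs, yb)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep,
             " (learning rate ", lr, "); try a smaller base_lr")
      losses <- c(losses, loss)
      ncorrect <- ncorrect + sum(apply(fw$probs, 2L, which.max) == yb)
      dscores <- fw$probs
      dscores[cbind(yb, seq_along(yb))] <-
        dscores[cbind(yb, seq_along(yb))] - 1
      dscores <- dscores / length(yb)
      bw <- sa_dispatch_backward(model, fw$caches, dscores)
      upd <- adam_step(model$params, bw$grads, opt, lr, config)
      model$params <- upd$params
      opt <- upd$opt
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses), lr = lr,
                                   accuracy = ncorrect / n))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.3f",
                      ep, lr, mean(losses), ncorrect / n))
    if (!is.null(epoch_hook)) epoch_hook(model, ep)
  }
  model$history <- hist
  model$train_config <- config
  model
}
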