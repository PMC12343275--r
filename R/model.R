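# The classifier: conv + BN stem, three residual stages, a spatial
# attention module after stage 1, global average pooling and a fully
# connected head. Trainable parameters live in a flat named list (easy to
# walk for Adam and for finite-difference checks); batch-norm running
# moments live in a parallel non-trainable state list.

#' Architecture configuration
#'
#' @param input_size Integer vector `(rows, cols)` the network expects after
#'   preprocessing.
#' @param stem_channels Channels produced by the stem convolution.
#' @param stage_channels Three nondecreasing integers: channels of the three
#'   residual stages.
#' @param attention_kernel Odd kernel size of the attention convolution that
#'   compresses the stage-1 feature map to a single channel (default 1x1).
#' @param num_classes Number of output classes.
#' @param class_names Optional character vector of length `num_classes`.
#' @param stem_stride Stride of the stem convolution. The default 2 halves
#'   the spatial grid before the residual stages, which keeps single-CPU
#'   training practical at 64x64 input; set 1 for full-resolution stage 1.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(input_size = c(64L, 64L),
                        stem_channels = 32L,
                        stage_channels = c(32L, 64L, 128L),
                        attention_kernel = 1L,
                        num_classes = 5L,
                        class_names = NULL,
                        stem_stride = 2L) {
  stopifnot(length(input_size) == 2L, all(input_size >= 8L),
            length(stage_channels) == 3L,
            !is.unsorted(stage_channels),
            attention_kernel %% 2L == 1L,
            num_classes >= 2L,
            stem_stride %in% c(1L, 2L))
  if (is.null(class_names)) {
    class_names <- paste0("class", seq_len(num_classes))
  }
  stopifnot(length(class_names) == num_classes)
  structure(list(
    input_size = as.integer(input_size),
    stem_channels = as.integer(stem_channels),
    stage_channels = as.integer(stage_channels),
    attention_kernel = as.integer(attention_kernel),
    num_classes = as.integer(num_classes),
    class_names = as.character(class_names),
    stem_stride = as.integer(stem_stride)
  ), class = "arch_config")
}

# He-initialized convolution kernel (kh, kw, cin, cout)
.init_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, cin, cout))
}

.init_block <- function(params, state, prefix, cin, cout, stride) {
  params[[paste0(prefix, ".conv1.w")]] <- .init_conv(3L, 3L, cin, cout)
  params[[paste0(prefix, ".conv1.b")]] <- numeric(cout)
  params[[paste0(prefix, ".conv2.w")]] <- .init_conv(3L, 3L, cout, cout)
  params[[paste0(prefix, ".conv2.b")]] <- numeric(cout)
  for (bn in c(".bn1", ".bn2")) {
    params[[paste0(prefix, bn, ".gamma")]] <- rep(1, cout)
    params[[paste0(prefix, bn, ".beta")]] <- numeric(cout)
    state[[paste0(prefix, bn, ".mean")]] <- numeric(cout)
    state[[paste0(prefix, bn, ".var")]] <- rep(1, cout)
  }
  if (stride != 1L || cin != cout) {
    params[[paste0(prefix, ".proj.w")]] <- .init_conv(1L, 1L, cin, cout)
    params[[paste0(prefix, ".proj.b")]] <- numeric(cout)
    params[[paste0(prefix, ".projbn.gamma")]] <- rep(1, cout)
    params[[paste0(prefix, ".projbn.beta")]] <- numeric(cout)
    state[[paste0(prefix, ".projbn.mean")]] <- numeric(cout)
    state[[paste0(prefix, ".projbn.var")]] <- rep(1, cout)
  }
  list(params = params, state = state)
}

#' Build an untrained spatial-attention CNN
#'
#' Weights are He-initialized from the given seed, so two models built with
#' the same configuration and seed are identical.
#'
#' @param config An [arch_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `cytoattn_model` object (config, trainable params, BN state).
#' @export
build_model <- function(config = arch_config(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ch <- config$stage_channels
  params <- list()
  state <- list()

  params[["stem.conv.w"]] <- .init_conv(3L, 3L, 3L, config$stem_channels)
  params[["stem.conv.b"]] <- numeric(config$stem_channels)
  params[["stem.bn.gamma"]] <- rep(1, config$stem_channels)
  params[["stem.bn.beta"]] <- numeric(config$stem_channels)
  state[["stem.bn.mean"]] <- numeric(config$stem_channels)
  state[["stem.bn.var"]] <- rep(1, config$stem_channels)

  r <- .init_block(params, state, "stage1", config$stem_channels, ch[1L], 1L)
  r <- .init_block(r$params, r$state, "stage2", ch[1L], ch[2L], 2L)
  r <- .init_block(r$params, r$state, "stage3", ch[2L], ch[3L], 2L)
  params <- r$params
  state <- r$state

  ak <- config$attention_kernel
  params[["attn.w"]] <- .init_conv(ak, ak, ch[1L], 1L)
  params[["attn.b"]] <- 0

  params[["fc.w"]] <- matrix(rnorm(config$num_classes * ch[3L],
                                   sd = sqrt(1 / ch[3L])),
                             nrow = config$num_classes)
  params[["fc.b"]] <- numeric(config$num_classes)

  structure(list(config = config, params = params, state = state,
                 arch = "spatial_attention", seed = as.integer(seed)),
            class = "cytoattn_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- residual block ----------------------------------------------------

resnet_block_fw <- function(x, params, state, prefix, stride, training) {
  g <- function(s) params[[paste0(prefix, s)]]
  c1 <- conv2d_fw(x, g(".conv1.w"), g(".conv1.b"), stride = stride, pad = 1L)
  b1 <- bn_fw(c1, g(".bn1.gamma"), g(".bn1.beta"),
              state[[paste0(prefix, ".bn1.mean")]],
              state[[paste0(prefix, ".bn1.var")]], training)
  state[[paste0(prefix, ".bn1.mean")]] <- b1$run_mean
  state[[paste0(prefix, ".bn1.var")]] <- b1$run_var
  r1 <- relu(b1$y)
  c2 <- conv2d_fw(r1, g(".conv2.w"), g(".conv2.b"), stride = 1L, pad = 1L)
  b2 <- bn_fw(c2, g(".bn2.gamma"), g(".bn2.beta"),
              state[[paste0(prefix, ".bn2.mean")]],
              state[[paste0(prefix, ".bn2.var")]], training)
  state[[paste0(prefix, ".bn2.mean")]] <- b2$run_mean
  state[[paste0(prefix, ".bn2.var")]] <- b2$run_var

  has_proj <- !is.null(params[[paste0(prefix, ".proj.w")]])
  if (has_proj) {
    cp <- conv2d_fw(x, g(".proj.w"), g(".proj.b"), stride = stride, pad = 0L)
    bp <- bn_fw(cp, g(".projbn.gamma"), g(".projbn.beta"),
                state[[paste0(prefix, ".projbn.mean")]],
                state[[paste0(prefix, ".projbn.var")]], training)
    state[[paste0(prefix, ".projbn.mean")]] <- bp$run_mean
    state[[paste0(prefix, ".projbn.var")]] <- bp$run_var
    shortcut <- bp$y
  } else {
    if (!identical(dim(b2$y), dim(x)))
      stop("residual shortcut shape mismatch in ", prefix,
           ": input ", paste(dim(x), collapse = "x"),
           " vs main path ", paste(dim(b2$y), collapse = "x"))
    cp <- NULL
    bp <- NULL
    shortcut <- x
  }
  s <- b2$y + shortcut
  out <- relu(s)
  list(y = out, state = state,
       cache = list(x = x, r1 = r1, b1cache = b1$cache, b2cache = b2$cache,
                    s = s, cp = !is.null(cp), bpcache = bp$cache,
                    stride = stride))
}

resnet_block_bw <- function(dout, params, cache, prefix) {
  g <- function(s) params[[paste0(prefix, s)]]
  grads <- list()
  ds <- relu_bw(dout, cache$s)

  b2 <- bn_bw(ds, cache$b2cache)
  grads[[paste0(prefix, ".bn2.gamma")]] <- b2$dgamma
  grads[[paste0(prefix, ".bn2.beta")]] <- b2$dbeta
  c2 <- conv2d_bw(cache$r1, g(".conv2.w"), b2$dx, stride = 1L, pad = 1L)
  grads[[paste0(prefix, ".conv2.w")]] <- c2$dw
  grads[[paste0(prefix, ".conv2.b")]] <- c2$db
  dr1 <- relu_bw(c2$dx, cache$r1)
  b1 <- bn_bw(dr1, cache$b1cache)
  grads[[paste0(prefix, ".bn1.gamma")]] <- b1$dgamma
  grads[[paste0(prefix, ".bn1.beta")]] <- b1$dbeta
  c1 <- conv2d_bw(cache$x, g(".conv1.w"), b1$dx, stride = cache$stride, pad = 1L)
  grads[[paste0(prefix, ".conv1.w")]] <- c1$dw
  grads[[paste0(prefix, ".conv1.b")]] <- c1$db
  dx <- c1$dx

  if (cache$cp) {
    bp <- bn_bw(ds, cache$bpcache)
    grads[[paste0(prefix, ".projbn.gamma")]] <- bp$dgamma
    grads[[paste0(prefix, ".projbn.beta")]] <- bp$dbeta
    pp <- conv2d_bw(cache$x, g(".proj.w"), bp$dx, stride = cache$stride, pad = 0L)
    grads[[paste0(prefix, ".proj.w")]] <- pp$dw
    grads[[paste0(prefix, ".proj.b")]] <- pp$db
    dx <- dx + pp$dx
  } else {
    dx <- dx + ds
  }
  list(dx = dx, grads = grads)
}

# ---- spatial attention -------------------------------------------------

#' Spatial attention: compress, squash, reweight
#'
#' A convolution collapses the multi-channel feature map `X` to a
#' single-channel map `M`; a sigmoid squashes `M` into the attention map
#' `A` with entries in (0, 1); the output is the elementwise product
#' `Y[k, i, j] = X[k, i, j] * A[i, j]`, broadcast over channels, so
#' spatially important positions are amplified and unimportant ones
#' suppressed.
#'
#' @param x Feature map, an `(H, W, C)` or `(H, W, C, N)` array.
#' @param w Attention convolution kernel: an `(kh, kw, C, 1)` array, or a
#'   length-`C` numeric vector interpreted as a 1x1 kernel.
#' @param b Scalar bias of the attention convolution.
#' @return A list with `A` (the attention map, same spatial dims as `x`,
#'   single channel) and `Y` (the reweighted feature map, same shape as
#'   `x`).
#' @examples
#' x <- array(1:8, dim = c(2, 2, 2))
#' att <- spatial_attention(x, w = c(0, 0), b = 0)
#' all(att$A == 0.5) # sigmoid(0)
#' @export
spatial_attention <- function(x, w, b = 0) {
  squeeze <- FALSE
  if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
    squeeze <- TRUE
  }
  stopifnot(length(dim(x)) == 4L)
  C <- dim(x)[3L]
  if (is.null(dim(w))) {
    stopifnot(length(w) == C)
    w <- array(w, dim = c(1L, 1L, C, 1L))
  }
  r <- attention_fw(x, w, b)
  A <- r$A
  Y <- r$y
  if (squeeze) {
    A <- A[, , 1L, 1L]
    dim(Y) <- dim(Y)[1:3]
  }
  list(A = A, Y = Y)
}

attention_fw <- function(x, w, b) {
  pad <- (dim(w)[1L] - 1L) %/% 2L
  M <- conv2d_fw(x, w, b, stride = 1L, pad = pad)
  A <- sigmoid(M)
  C <- dim(x)[3L]
  Arep <- A[, , rep(1L, C), , drop = FALSE]
  y <- x * Arep
  list(y = y, A = A, cache = list(x = x, A = A, Arep = Arep, w = w, pad = pad))
}

attention_bw <- function(dy, cache) {
  x <- cache$x
  A <- cache$A
  d <- dim(x)
  C <- d[3L]; N <- d[4L]
  dx <- dy * cache$Arep
  # dA[i,j,n] = sum_k dy[i,j,k,n] * x[i,j,k,n]
  prod <- dy * x
  dim(prod) <- c(d[1L] * d[2L], C * N)
  dA <- array(0, dim = c(d[1L], d[2L], 1L, N))
  dAm <- matrix(0, d[1L] * d[2L], N)
  for (n in seq_len(N))
    dAm[, n] <- rowSums(prod[, ((n - 1L) * C + 1L):(n * C), drop = FALSE])
  dA[] <- dAm
  dM <- dA * A * (1 - A)
  cw <- conv2d_bw(x, cache$w, dM, stride = 1L, pad = cache$pad)
  list(dx = dx + cw$dx, dw = cw$dw, db = cw$db, dA = dA)
}

# ---- full network ------------------------------------------------------

# Forward pass of the primary model. Returns scores/probs plus the stage-1
# attention map, tagged activations (for Grad-CAM), per-layer caches (for
# the backward pass) and the possibly-updated BN state.
sa_forward <- function(model, x, training = FALSE, keep_caches = training) {
  p <- model$params
  st <- model$state
  caches <- list()

  c0 <- conv2d_fw(x, p[["stem.conv.w"]], p[["stem.conv.b"]],
                  stride = model$config$stem_stride, pad = 1L)
  b0 <- bn_fw(c0, p[["stem.bn.gamma"]], p[["stem.bn.beta"]],
              st[["stem.bn.mean"]], st[["stem.bn.var"]], training)
  st[["stem.bn.mean"]] <- b0$run_mean
  st[["stem.bn.var"]] <- b0$run_var
  r0 <- relu(b0$y)

  s1 <- resnet_block_fw(r0, p, st, "stage1", 1L, training)
  st <- s1$state
  at <- attention_fw(s1$y, p[["attn.w"]], p[["attn.b"]])
  s2 <- resnet_block_fw(at$y, p, st, "stage2", 2L, training)
  st <- s2$state
  s3 <- resnet_block_fw(s2$y, p, st, "stage3", 2L, training)
  st <- s3$state

  gp <- gap_fw(s3$y)
  scores <- fc_fw(gp$h, p[["fc.w"]], p[["fc.b"]])
  probs <- softmax(scores)

  if (keep_caches) {
    caches <- list(x = x, b0cache = b0$cache, r0 = r0, s1 = s1$cache,
                   at = at$cache, s2 = s2$cache, s3 = s3$cache,
                   gp = gp, h = gp$h)
  }
  list(scores = scores, probs = probs, attention = at$A,
       activations = list(stage1 = s1$y, attn = at$y, stage2 = s2$y,
                          stage3 = s3$y, last = s3$y),
       caches = caches, state = st)
}

# Backward pass given d(loss)/d(scores). Also reports gradients with
# respect to the tagged activations (used by Grad-CAM).
sa_backward <- function(model, caches, dscores) {
  p <- model$params
  grads <- list()
  act_grads <- list()

  fcb <- fc_bw(dscores, caches$h, p[["fc.w"]])
  grads[["fc.w"]] <- fcb$dw
  grads[["fc.b"]] <- fcb$db
  ds3 <- gap_bw(fcb$dh, caches$gp$d)
  act_grads$stage3 <- ds3
  act_grads$last <- ds3

  b3 <- resnet_block_bw(ds3, p, caches$s3, "stage3")
  grads <- c(grads, b3$grads)
  act_grads$stage2 <- b3$dx
  b2 <- resnet_block_bw(b3$dx, p, caches$s2, "stage2")
  grads <- c(grads, b2$grads)
  act_grads$attn <- b2$dx

  ab <- attention_bw(b2$dx, caches$at)
  grads[["attn.w"]] <- ab$dw
  grads[["attn.b"]] <- ab$db
  act_grads$stage1 <- ab$dx

  b1 <- resnet_block_bw(ab$dx, p, caches$s1, "stage1")
  grads <- c(grads, b1$grads)

  dr0 <- relu_bw(b1$dx, caches$r0)
  b0 <- bn_bw(dr0, caches$b0cache)
  grads[["stem.bn.gamma"]] <- b0$dgamma
  grads[["stem.bn.beta"]] <- b0$dbeta
  c0 <- conv2d_bw(caches$x, p[["stem.conv.w"]], b0$dx,
                  stride = model$config$stem_stride, pad = 1L)
  grads[["stem.conv.w"]] <- c0$dw
  grads[["stem.conv.b"]] <- c0$db

  list(grads = grads, act_grads = act_grads, dx = c0$dx)
}

#' Run the classifier on a batch of images
#'
#' @param model A `cytoattn_model` (see [build_model()], [train_model()]).
#' @param images An `(H, W, 3)` array, an `(H, W, 3, N)` batch, or a list of
#'   `(H, W, 3)` arrays, with values in `[0, 255]` or already standardized.
#' @param preprocess If `TRUE` (default) scale to `[0, 1]` and standardize
#'   with mean 0.5, sd 0.5, resizing to the model's input size if needed.
#' @return A list: `scores` (`num_classes x N`), `probs` (softmax of the
#'   scores, columns sum to 1), `attention` (stage-1 attention maps,
#'   `(h, w, 1, N)`, entries in (0, 1)), and `predicted` (factor of class
#'   labels).
#' @export
model_forward <- function(model, images, preprocess = TRUE) {
  x <- as_batch(images, model$config$input_size, preprocess = preprocess)
  out <- sa_dispatch_forward(model, x, training = FALSE, keep_caches = FALSE)
  pred <- factor(model$config$class_names[apply(out$probs, 2L, which.max)],
                 levels = model$config$class_names)
  list(scores = out$scores, probs = out$probs, attention = out$attention,
       predicted = pred)
}

# arch dispatch shared by training/eval/visualization
sa_dispatch_forward <- function(model, x, training = FALSE,
                                keep_caches = training) {
  switch(model$arch,
         spatial_attention = sa_forward(model, x, training, keep_caches),
         self_attention = sqnet_forward(model, x, training, keep_caches),
         multilayer = mlcnn_forward(model, x, training, keep_caches),
         stop("unknown architecture tag: ", model$arch))
}

sa_dispatch_backward <- function(model, caches, dscores) {
  switch(model$arch,
         spatial_attention = sa_backward(model, caches, dscores),
         self_attention = sqnet_backward(model, caches, dscores),
         multilayer = mlcnn_backward(model, caches, dscores),
         stop("unknown architecture tag: ", model$arch))
}

#' @export
print.cytoattn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<cytoattn_model>", x$arch, "\n",
      " input ", paste(x$config$input_size, collapse = "x"),
      ", classes: ", paste(x$config$class_names, collapse = ", "), "\n",
      " trainable parameters: ", np, "\n", sep = "")
  invisible(x)
}
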