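# Comparison architectures. (1) A randomly initialized small residual
# backbone with a query-key-value self-attention block inserted before the
# final residual stage — a desk-scale stand-in for a pretrained ResNet50
# with self-attention, which is out of scope (no pretrained weights are
# used anywhere in this package; the divergence is deliberate and
# documented). (2) A plain multi-layer CNN (conv/BN/ReLU stacks, no
# shortcuts) with one convolutional spatial-attention module mid-stack.
# Both train through the same Adam loop and evaluate through the same
# report machinery as the primary model.

#' Residual backbone with a self-attention block
#'
#' Same stem and three residual stages as the primary model, but the
#' spatial attention module is replaced by a query-key-value
#' self-attention block (1x1-conv projections, dot-product weights
#' softmaxed over spatial positions, residual add) inserted between
#' stages 2 and 3. Visualization for this model goes through Grad-CAM.
#'
#' @param config An [arch_config()].
#' @param seed Integer seed for weight initialization.
#' @param dk Query/key projection depth (default `ceiling(C/8)` of the
#'   stage-2 channels).
#' @return A `cytoattn_model` with `arch = "self_attention"`.
#' @export
build_self_attention_model <- function(config = arch_config(), seed = 1L,
                                       dk = NULL) {
  m <- build_model(config, seed = seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed) + 1L)
  C <- config$stage_channels[2L]
  if (is.null(dk)) dk <- as.integer(ceiling(C / 8))
  m$params[["attn.w"]] <- NULL
  m$params[["attn.b"]] <- NULL
  m$params[["selfattn.q.w"]] <- matrix(rnorm(dk * C, sd = sqrt(1 / C)), dk, C)
  m$params[["selfattn.k.w"]] <- matrix(rnorm(dk * C, sd = sqrt(1 / C)), dk, C)
  m$params[["selfattn.v.w"]] <- matrix(rnorm(C * C, sd = sqrt(1 / C)), C, C)
  m$arch <- "self_attention"
  m$dk <- dk
  m
}

#' Self-attention block over spatial positions
#'
#' Flattens the feature map to `C x P` (`P = H * W`), projects queries,
#' keys and values with 1x1 convolutions, forms attention weights
#' `softmax(Q'K / sqrt(dk))` across positions, and adds the re-weighted
#' values back to the input (residual form): with zero value weights the
#' block is an exact identity.
#'
#' @param x `(H, W, C)` or `(H, W, C, N)` feature map.
#' @param wq,wk `dk x C` projection matrices.
#' @param wv `C x C` value projection.
#' @return List with `y` (same shape as `x`) and `attn` (list of `P x P`
#'   weight matrices, one per batch item).
#' @export
self_attention_block <- function(x, wq, wk, wv) {
  squeeze <- FALSE
  if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
    squeeze <- TRUE
  }
  r <- selfattn_fw(x, wq, wk, wv)
  y <- r$y
  if (squeeze) dim(y) <- dim(y)[1:3]
  list(y = y, attn = lapply(r$cache$per, `[[`, "A"))
}

selfattn_fw <- function(x, wq, wk, wv) {
  d <- dim(x)
  P <- d[1L] * d[2L]
  scale <- 1 / sqrt(nrow(wq))
  y <- x
  per <- vector("list", d[4L])
  for (n in seq_len(d[4L])) {
    Xi <- t(matrix(x[, , , n], nrow = P))          # C x P
    Q <- wq %*% Xi; K <- wk %*% Xi; V <- wv %*% Xi
    S <- scale * crossprod(Q, K)                   # P x P
    S <- sweep(S, 1L, apply(S, 1L, max))
    E <- exp(S)
    A <- E / rowSums(E)
    O <- V %*% t(A)                                # C x P
    y[, , , n] <- as.numeric(x[, , , n]) + as.numeric(t(O))
    per[[n]] <- list(Xi = Xi, Q = Q, K = K, V = V, A = A)
  }
  list(y = y, cache = list(per = per, d = d, scale = scale,
                           wq = wq, wk = wk, wv = wv))
}

selfattn_bw <- function(dy, cache) {
  d <- cache$d
  P <- d[1L] * d[2L]
  wq <- cache$wq; wk <- cache$wk; wv <- cache$wv
  dwq <- wq * 0; dwk <- wk * 0; dwv <- wv * 0
  dx <- dy # identity path
  for (n in seq_len(d[4L])) {
    pc <- cache$per[[n]]
    dO <- t(matrix(dy[, , , n], nrow = P))         # C x P
    dV <- dO %*% pc$A                               # C x P
    dA <- crossprod(dO, pc$V)                       # P x P
    # softmax backward, row-wise
    dS <- (dA - rowSums(dA * pc$A)) * pc$A
    dQ <- cache$scale * pc$K %*% t(dS)              # dk x P
    dK <- cache$scale * pc$Q %*% dS                 # dk x P
    dXi <- crossprod(wq, dQ) + crossprod(wk, dK) + crossprod(wv, dV)
    dx[, , , n] <- as.numeric(dx[, , , n]) + as.numeric(t(dXi))
    dwq <- dwq + tcrossprod(dQ, pc$Xi)
    dwk <- dwk + tcrossprod(dK, pc$Xi)
    dwv <- dwv + tcrossprod(dV, pc$Xi)
  }
  list(dx = dx, dwq = dwq, dwk = dwk, dwv = dwv)
}

sqnet_forward <- function(model, x, training = FALSE, keep_caches = training) {
  p <- model$params
  st <- model$state
  c0 <- conv2d_fw(x, p[["stem.conv.w"]], p[["stem.conv.b"]],
                  stride = model$config$stem_stride, pad = 1L)
  b0 <- bn_fw(c0, p[["stem.bn.gamma"]], p[["stem.bn.beta"]],
              st[["stem.bn.mean"]], st[["stem.bn.var"]], training)
  st[["stem.bn.mean"]] <- b0$run_mean; st[["stem.bn.var"]] <- b0$run_var
  r0 <- relu(b0$y)
  s1 <- resnet_block_fw(r0, p, st, "stage1", 1L, training); st <- s1$state
  s2 <- resnet_block_fw(s1$y, p, st, "stage2", 2L, training); st <- s2$state
  sa <- selfattn_fw(s2$y, p[["selfattn.q.w"]], p[["selfattn.k.w"]],
                    p[["selfattn.v.w"]])
  s3 <- resnet_block_fw(sa$y, p, st, "stage3", 2L, training); st <- s3$state
  gp <- gap_fw(s3$y)
  scores <- fc_fw(gp$h, p[["fc.w"]], p[["fc.b"]])
  caches <- if (keep_caches)
    list(x = x, b0cache = b0$cache, r0 = r0, s1 = s1$cache, s2 = s2$cache,
         sa = sa$cache, s3 = s3$cache, gp = gp, h = gp$h) else list()
  list(scores = scores, probs = softmax(scores), attention = NULL,
       activations = list(stage1 = s1$y, stage2 = s2$y, selfattn = sa$y,
                          stage3 = s3$y, last = s3$y),
       caches = caches, state = st)
}

sqnet_backward <- function(model, caches, dscores) {
  p <- model$params
  grads <- list()
  act_grads <- list()
  fcb <- fc_bw(dscores, caches$h, p[["fc.w"]])
  grads[["fc.w"]] <- fcb$dw; grads[["fc.b"]] <- fcb$db
  ds3 <- gap_bw(fcb$dh, caches$gp$d)
  act_grads$stage3 <- ds3; act_grads$last <- ds3
  b3 <- resnet_block_bw(ds3, p, caches$s3, "stage3")
  grads <- c(grads, b3$grads)
  act_grads$selfattn <- b3$dx
  sab <- selfattn_bw(b3$dx, caches$sa)
  grads[["selfattn.q.w"]] <- sab$dwq
  grads[["selfattn.k.w"]] <- sab$dwk
  grads[["selfattn.v.w"]] <- sab$dwv
  act_grads$stage2 <- sab$dx
  b2 <- resnet_block_bw(sab$dx, p, caches$s2, "stage2")
  grads <- c(grads, b2$grads)
  act_grads$stage1 <- b2$dx
  b1 <- resnet_block_bw(b2$dx, p, caches$s1, "stage1")
  grads <- c(grads, b1$grads)
  dr0 <- relu_bw(b1$dx, caches$r0)
  b0 <- bn_bw(dr0, caches$b0cache)
  grads[["stem.bn.gamma"]] <- b0$dgamma; grads[["stem.bn.beta"]] <- b0$dbeta
  c0 <- conv2d_bw(caches$x, p[["stem.conv.w"]], b0$dx,
                  stride = model$config$stem_stride, pad = 1L)
  grads[["stem.conv.w"]] <- c0$dw; grads[["stem.conv.b"]] <- c0$db
  list(grads = grads, act_grads = act_grads, dx = c0$dx)
}

#' Plain multi-layer CNN with convolutional attention
#'
#' A stack of conv/BN/ReLU layers with no residual shortcuts, one
#' convolutional spatial-attention module mid-stack (the same operation as
#' the primary model's), then average pooling and a fully connected head.
#'
#' @param config An [arch_config()].
#' @param seed Integer seed for weight initialization.
#' @param depth Number of convolutional layers (default 6).
#' @return A `cytoattn_model` with `arch = "multilayer"`.
#' @export
build_multilayer_cnn <- function(config = arch_config(), seed = 1L,
                                 depth = 6L) {
  stopifnot(depth >= 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # channel ramp ending at the configured top width; stride 2 every other
  # layer starting at layer 1 keeps the head size comparable to the
  # primary model
  top <- config$stage_channels[3L]
  channels <- round(exp(seq(log(config$stem_channels / 2), log(top),
                            length.out = depth)))
  strides <- rep(1L, depth)
  strides[seq(1L, depth, by = 2L)] <- 2L
  params <- list(); state <- list()
  cin <- 3L
  for (l in seq_len(depth)) {
    pre <- paste0("ml", l)
    params[[paste0(pre, ".conv.w")]] <- .init_conv(3L, 3L, cin, channels[l])
    params[[paste0(pre, ".conv.b")]] <- numeric(channels[l])
    params[[paste0(pre, ".bn.gamma")]] <- rep(1, channels[l])
    params[[paste0(pre, ".bn.beta")]] <- numeric(channels[l])
    state[[paste0(pre, ".bn.mean")]] <- numeric(channels[l])
    state[[paste0(pre, ".bn.var")]] <- rep(1, channels[l])
    cin <- channels[l]
  }
  mid <- depth %/% 2L
  params[["attn.w"]] <- .init_conv(1L, 1L, channels[mid], 1L)
  params[["attn.b"]] <- 0
  params[["fc.w"]] <- matrix(rnorm(config$num_classes * top,
                                   sd = sqrt(1 / top)),
                             nrow = config$num_classes)
  params[["fc.b"]] <- numeric(config$num_classes)
  structure(list(config = config, params = params, state = state,
                 arch = "multilayer", depth = as.integer(depth),
                 channels = channels, strides = strides,
                 attn_after = mid, seed = as.integer(seed)),
            class = "cytoattn_model")
}

mlcnn_forward <- function(model, x, training = FALSE, keep_caches = training) {
  p <- model$params
  st <- model$state
  layer_caches <- vector("list", model$depth)
  att_cache <- NULL
  A <- NULL
  cur <- x
  for (l in seq_len(model$depth)) {
    pre <- paste0("ml", l)
    cc <- conv2d_fw(cur, p[[paste0(pre, ".conv.w")]],
                    p[[paste0(pre, ".conv.b")]],
                    stride = model$strides[l], pad = 1L)
    bb <- bn_fw(cc, p[[paste0(pre, ".bn.gamma")]],
                p[[paste0(pre, ".bn.beta")]],
                st[[paste0(pre, ".bn.mean")]],
                st[[paste0(pre, ".bn.var")]], training)
    st[[paste0(pre, ".bn.mean")]] <- bb$run_mean
    st[[paste0(pre, ".bn.var")]] <- bb$run_var
    out <- relu(bb$y)
    layer_caches[[l]] <- list(x = cur, bncache = bb$cache, out = out)
    cur <- out
    if (l == model$attn_after) {
      at <- attention_fw(cur, p[["attn.w"]], p[["attn.b"]])
      att_cache <- at$cache
      A <- at$A
      cur <- at$y
    }
  }
  gp <- gap_fw(cur)
  scores <- fc_fw(gp$h, p[["fc.w"]], p[["fc.b"]])
  caches <- if (keep_caches)
    list(layers = layer_caches, at = att_cache, gp = gp, h = gp$h) else list()
  list(scores = scores, probs = softmax(scores), attention = A,
       activations = list(attn = if (!is.null(att_cache)) att_cache$x,
                          last = cur),
       caches = caches, state = st)
}

mlcnn_backward <- function(model, caches, dscores) {
  p <- model$params
  grads <- list()
  act_grads <- list()
  fcb <- fc_bw(dscores, caches$h, p[["fc.w"]])
  grads[["fc.w"]] <- fcb$dw; grads[["fc.b"]] <- fcb$db
  dcur <- gap_bw(fcb$dh, caches$gp$d)
  act_grads$last <- dcur
  for (l in rev(seq_len(model$depth))) {
    if (l == model$attn_after) {
      ab <- attention_bw(dcur, caches$at)
      grads[["attn.w"]] <- ab$dw; grads[["attn.b"]] <- ab$db
      dcur <- ab$dx
      act_grads$attn <- dcur
    }
    pre <- paste0("ml", l)
    lc <- caches$layers[[l]]
    dout <- relu_bw(dcur, lc$out)
    bb <- bn_bw(dout, lc$bncache)
    grads[[paste0(pre, ".bn.gamma")]] <- bb$dgamma
    grads[[paste0(pre, ".bn.beta")]] <- bb$dbeta
    cb <- conv2d_bw(lc$x, p[[paste0(pre, ".conv.w")]], bb$dx,
                    stride = model$strides[l], pad = 1L)
    grads[[paste0(pre, ".conv.w")]] <- cb$dw
    grads[[paste0(pre, ".conv.b")]] <- cb$db
    dcur <- cb$dx
  }
  list(grads = grads, act_grads = act_grads, dx = dcur)
}

#' Normalized attention map of any of the three architectures
#'
#' The primary model's stage-1 attention, or a Grad-CAM map at the last
#' convolutional layer for the baselines; upsampled to image resolution
#' and min-max normalized. This puts all three models on a common footing
#' for visualization studies.
#'
#' @param model Trained `cytoattn_model`.
#' @param image `(H, W, 3)` pixel array.
#' @return Normalized single-channel matrix at image resolution.
#' @export
probe_attention <- function(model, image) {
  attention_overlay(model, image)$map
}

#' Attention-map stability across training epochs
#'
#' Mean per-pixel absolute change of the normalized attention map between
#' consecutive epochs, averaged over a fixed set of probe images: 0 means
#' the visualized regions never move, larger values mean they keep
#' changing.
#'
#' @param maps_by_epoch List (one element per epoch) of lists of
#'   probe-image attention maps, e.g. collected with an `epoch_hook` that
#'   calls [probe_attention()].
#' @return Mean absolute per-pixel change.
#' @export
attention_stability <- function(maps_by_epoch) {
  stopifnot(length(maps_by_epoch) >= 2L)
  deltas <- numeric()
  for (e in 2:length(maps_by_epoch)) {
    prev <- maps_by_epoch[[e - 1L]]
    curr <- maps_by_epoch[[e]]
    stopifnot(length(prev) == length(curr))
    deltas <- c(deltas, vapply(seq_along(curr), function(i)
      mean(abs(curr[[i]] - prev[[i]])), numeric(1)))
  }
  mean(deltas)
}
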