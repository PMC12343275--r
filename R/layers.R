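# Layer primitives. Feature maps are dense double arrays with
# dim = c(H, W, C, N) (rows, cols, channels, batch); convolution kernels
# are c(kh, kw, cin, cout). Every forward has a matching hand-derived
# backward so the whole network trains without an autodiff framework.

#' Rectified linear unit
#'
#' Elementwise `f(x) = max(0, x)`, the activation used throughout the
#' network.
#'
#' @param x A numeric vector, matrix or array.
#' @return An object of the same shape with negative entries set to zero.
#' @examples
#' relu(c(-1, 0, 2)) # 0 0 2
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bw <- function(dy, x) {
  dy[x <= 0] <- 0
  dy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- convolution (im2col + GEMM in C++) -------------------------------

conv2d_fw <- function(x, w, b, stride = 1L, pad = 1L) {
  stopifnot(length(dim(x)) == 4L, length(dim(w)) == 4L)
  .conv2d_fw_cpp(x, w, as.numeric(b), as.integer(stride), as.integer(pad))
}

conv2d_bw <- function(x, w, dy, stride = 1L, pad = 1L) {
  .conv2d_bw_cpp(x, w, dy, as.integer(stride), as.integer(pad))
}

# ---- batch normalization ----------------------------------------------

# Column-major (H,W,C,N) reshapes for free to an (H*W) x (C*N) matrix with
# column index c + C*(n-1); per-channel statistics are then rowMeans over
# the C x N fold of the column statistics, and per-channel sweeps recycle
# rep(v, N). This avoids any aperm copy on the hot path.
.per_channel_mean <- function(m, C, N) {
  rowMeans(matrix(.colMeans(m, nrow(m), ncol(m)), C, N))
}

.per_channel_sum <- function(m, C, N) {
  rowSums(matrix(.colSums(m, nrow(m), ncol(m)), C, N))
}

# column-constant sweep without base::sweep (which transposes via aperm):
# v holds one value per column of m
.csweep <- function(m, v, op = `-`) op(m, rep(v, each = nrow(m)))

# training = TRUE uses batch statistics (biased variance, 1/m) and updates
# the running moments in the returned state; inference uses running moments.
bn_fw <- function(x, gamma, beta, run_mean, run_var, training,
                  momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[3L]; N <- d[4L]
  xm <- x
  dim(xm) <- c(d[1L] * d[2L], C * N)
  if (training) {
    mu <- .per_channel_mean(xm, C, N)
    xc <- .csweep(xm, rep(mu, N))
    v <- .per_channel_mean(xc * xc, C, N)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- .csweep(xm, rep(mu, N))
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- .csweep(xc, rep(inv_sd, N), `*`)
  ym <- .csweep(.csweep(xhat, rep(gamma, N), `*`), rep(beta, N), `+`)
  dim(ym) <- d
  list(
    y = ym,
    cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, d = d,
                 training = training),
    run_mean = run_mean, run_var = run_var
  )
}

bn_bw <- function(dy, cache) {
  d <- cache$d
  C <- d[3L]; N <- d[4L]
  dym <- dy
  dim(dym) <- c(d[1L] * d[2L], C * N)
  dgamma <- .per_channel_sum(dym * cache$xhat, C, N)
  dbeta <- .per_channel_sum(dym, C, N)
  dxhat <- .csweep(dym, rep(cache$gamma, N), `*`)
  if (cache$training) {
    m <- nrow(dym) * N
    # dx = inv_sd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    t1 <- .csweep(dxhat, rep(.per_channel_sum(dxhat, C, N) / m, N))
    t2 <- .csweep(cache$xhat,
                  rep(.per_channel_sum(dxhat * cache$xhat, C, N) / m, N), `*`)
    dxm <- .csweep(t1 - t2, rep(cache$inv_sd, N), `*`)
  } else {
    dxm <- .csweep(dxhat, rep(cache$inv_sd, N), `*`)
  }
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

# ---- global average pooling and the classifier head -------------------

gap_fw <- function(x) {
  d <- dim(x)
  # (C x N) matrix of spatial means
  m <- matrix(colMeans(matrix(x, nrow = d[1L] * d[2L])), nrow = d[3L])
  list(h = m, d = d)
}

gap_bw <- function(dh, d) {
  scale <- 1 / (d[1L] * d[2L])
  array(rep(as.numeric(dh), each = d[1L] * d[2L]) * scale, dim = d)
}

fc_fw <- function(h, w, b) {
  sweep(w %*% h, 1L, b, `+`) # (num_classes x N)
}

fc_bw <- function(dy, h, w) {
  list(dh = crossprod(w, dy), dw = tcrossprod(dy, h), db = rowSums(dy))
}

# ---- softmax / cross-entropy ------------------------------------------

# column-wise softmax of a (num_classes x N) score matrix, numerically
# stabilized by subtracting the column maximum
softmax <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L)
  z <- sweep(scores, 2L, apply(scores, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

#' Cross-entropy loss of predicted class probabilities
#'
#' Returns `-log(p)` where `p` is the probability the model assigns to the
#' true class. Probabilities are clamped below at `eps` so a zero
#' probability yields a large finite loss rather than `Inf`.
#'
#' @param probabilities Numeric vector of class probabilities (one sample),
#'   or a `num_classes x n` matrix (one sample per column).
#' @param true_label Integer class index (1-based), or a vector of indices
#'   when `probabilities` is a matrix.
#' @param eps Lower clamp applied to the selected probability.
#' @return Mean negative log-probability of the true classes.
#' @examples
#' cross_entropy(rep(0.2, 5), 3) # log(5)
#' @export
cross_entropy <- function(probabilities, true_label, eps = 1e-12) {
  if (is.null(dim(probabilities))) {
    probabilities <- matrix(probabilities, ncol = 1L)
  }
  stopifnot(length(true_label) == ncol(probabilities))
  p <- probabilities[cbind(as.integer(true_label), seq_len(ncol(probabilities)))]
  mean(-log(pmax(p, eps)))
}
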