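# Network mechanics: layer contracts, residual identity, attention
# algebra, softmax normalization, backprop correctness.

test_that("relu is max(0, x) elementwise", {
  expect_identical(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_identical(relu(c(-5, -0.1)), c(0, 0))
  x <- matrix(c(0.5, 1, 2, 3), 2)
  expect_identical(relu(x), x) # identity on the nonnegative cone
})

test_that("convolution matches a naive direct implementation", {
  set.seed(31)
  x <- array(rnorm(9 * 8 * 2 * 2), c(9, 8, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  for (stride in 1:2) {
    got <- cytoattn:::conv2d_fw(x, w, b, stride, 1L)
    want <- naive_conv(x, w, b, stride, 1L)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # 1x1 kernel, no padding
  w1 <- array(rnorm(2 * 4), c(1, 1, 2, 4))
  expect_equal(cytoattn:::conv2d_fw(x, w1, rep(0, 4), 2L, 0L),
               naive_conv(x, w1, rep(0, 4), 2L, 0L), tolerance = 1e-12)
})

test_that("residual block is the identity at zero weights, halves size at stride 2", {
  cfg <- tiny_arch()
  m <- build_model(cfg, seed = 2)
  p <- m$params
  for (nm in grep("^stage1\\.conv", names(p), value = TRUE)) p[[nm]][] <- 0
  x <- array(abs(rnorm(8 * 8 * 4 * 2)), c(8, 8, 4, 2)) # nonnegative input
  out <- cytoattn:::resnet_block_fw(x, p, m$state, "stage1", 1L,
                                    training = FALSE)
  expect_equal(out$y, x, tolerance = 1e-12)

  # stride-2 stage: 32x32 in, 16x16 out, channels per config
  x2 <- array(rnorm(32 * 32 * 4 * 1), c(32, 32, 4, 1))
  out2 <- cytoattn:::resnet_block_fw(x2, m$params, m$state, "stage2", 2L,
                                     training = FALSE)
  expect_identical(dim(out2$y), c(16L, 16L, 8L, 1L))
})

test_that("residual block matches an independent straight-line evaluation", {
  cfg <- tiny_arch()
  m <- build_model(cfg, seed = 8)
  x <- array(rnorm(6 * 6 * 4 * 1), c(6, 6, 4, 1))
  got <- cytoattn:::resnet_block_fw(x, m$params, m$state, "stage1", 1L,
                                    training = FALSE)$y
  # hand composition: conv -> BN(inference) -> relu -> conv -> BN -> +x -> relu
  g <- function(s) m$params[[paste0("stage1", s)]]
  bn_inf <- function(v, gam, bet, mu, va, eps = 1e-5) {
    for (c in seq_len(dim(v)[3]))
      v[, , c, ] <- gam[c] * (v[, , c, ] - mu[c]) / sqrt(va[c] + eps) + bet[c]
    v
  }
  h <- naive_conv(x, g(".conv1.w"), g(".conv1.b"), 1, 1)
  h <- bn_inf(h, g(".bn1.gamma"), g(".bn1.beta"),
              m$state[["stage1.bn1.mean"]], m$state[["stage1.bn1.var"]])
  h <- pmax(h, 0)
  h <- naive_conv(h, g(".conv2.w"), g(".conv2.b"), 1, 1)
  h <- bn_inf(h, g(".bn2.gamma"), g(".bn2.beta"),
              m$state[["stage1.bn2.mean"]], m$state[["stage1.bn2.var"]])
  want <- pmax(h + x, 0)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("spatial attention: sigmoid gate, channel broadcast, saturation", {
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  # zero weights -> A = 0.5 everywhere, Y = X/2
  att <- spatial_attention(x, w = c(0, 0, 0), b = 0)
  expect_true(all(att$A == 0.5))
  expect_equal(att$Y, 0.5 * x, tolerance = 1e-12)
  # saturated gate: bias +10 -> Y ~ X to 5e-5 relative
  att10 <- spatial_attention(x, w = c(0, 0, 0), b = 10)
  expect_lte(max(abs(att10$Y - x)), 5e-5 * max(abs(x)))
  # 1-channel scalar oracle: y = x * sigmoid(x)
  x1 <- array(c(1, 3, 2, 4), c(2, 2, 1)) # column-major: [[1,2],[3,4]]
  att1 <- spatial_attention(x1, w = 1, b = 0)
  expect_equal(round(as.numeric(att1$Y), 4),
               c(0.7311, 2.8577, 1.7616, 3.9281))
})

test_that("attention damps nonnegative features and broadcasts over channels", {
  cfg <- tiny_arch()
  m <- build_model(cfg, seed = 5)
  x <- array(abs(rnorm(8 * 8 * 4 * 3)), c(8, 8, 4, 3))
  at <- cytoattn:::attention_fw(x, m$params[["attn.w"]], m$params[["attn.b"]])
  expect_true(all(at$y >= 0 & at$y <= x))
  # the gating ratio is channel-independent wherever x != 0
  ratio <- at$y / x
  for (k in 2:4)
    expect_equal(ratio[, , k, ], ratio[, , 1, ], tolerance = 1e-12)
})

test_that("forward emits a softmax simplex and is deterministic in inference", {
  cfg <- tiny_arch()
  m <- build_model(cfg, seed = 4)
  img <- array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3))
  out1 <- model_forward(m, img)
  out2 <- model_forward(m, img)
  expect_identical(out1$scores, out2$scores)
  expect_true(all(out1$probs > 0 & out1$probs < 1))
  expect_lte(abs(sum(out1$probs) - 1), 1e-6)
  # probabilities equal an independent exp/sum of the returned scores
  s <- out1$scores[, 1]
  expect_equal(out1$probs[, 1], exp(s) / sum(exp(s)), tolerance = 1e-12)
  # attention map comes back at stage-1 resolution, gated to (0,1)
  expect_true(all(out1$attention > 0 & out1$attention < 1))
})

test_that("cross-entropy has the right analytic values and a finite floor", {
  expect_equal(cross_entropy(rep(0.2, 5), 3), log(5), tolerance = 1e-12)
  expect_equal(cross_entropy(c(1, 0, 0), 1), 0, tolerance = 1e-12)
  expect_equal(cross_entropy(c(0.5, 0.5), 2), log(2), tolerance = 1e-12)
  expect_true(is.finite(cross_entropy(c(0, 1), 1))) # clamped, not Inf
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_arch()
  m <- build_model(cfg, seed = 3)
  set.seed(77)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- c(1L, 3L)
  loss_at <- function(params) {
    mm <- m
    mm$params <- params
    fw <- cytoattn:::sa_forward(mm, x, training = TRUE)
    cross_entropy(fw$probs, y)
  }
  fw <- cytoattn:::sa_forward(m, x, training = TRUE)
  ds <- fw$probs
  ds[cbind(y, 1:2)] <- ds[cbind(y, 1:2)] - 1
  ds <- ds / 2
  bw <- cytoattn:::sa_backward(m, fw$caches, ds)
  for (nm in c("stem.conv.w", "stage1.conv2.w", "attn.w", "attn.b",
               "stage2.proj.w", "stage3.bn2.gamma", "fc.w")) {
    theta <- m$params[[nm]]
    idx <- sample(length(theta), min(3L, length(theta)))
    num <- fd_grad(function(th) {
      p <- m$params
      p[[nm]] <- if (is.null(dim(theta))) th else array(th, dim(theta))
      loss_at(p)
    }, theta, idx)
    ana <- bw$grads[[nm]][idx]
    denom <- pmax(abs(num), abs(ana), 1e-6)
    expect_lt(max(abs(num - ana) / denom), 1e-3)
  }
})
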