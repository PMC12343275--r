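# Image preprocessing: bilinear resizing and the [0,1] -> mean 0.5 / sd 0.5
# standardization applied before the network.

#' Bilinear resize
#'
#' Resizes a single-channel map or multi-channel image with bilinear
#' interpolation (corner-aligned sampling, so the four corners are
#' preserved exactly and a 2x2 -> 3x3 resize places the average of the four
#' corners at the center). Interpolated values never leave
#' `[min(x), max(x)]`.
#'
#' @param x A matrix `(H, W)` or array `(H, W, C)`.
#' @param target_size Integer vector `(rows, cols)` of the output.
#' @return The resized matrix or array.
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2)
#' resize_bilinear(m, c(3, 3))[2, 2] # 0.5
#' @export
resize_bilinear <- function(x, target_size) {
  stopifnot(length(target_size) == 2L, all(target_size >= 1L))
  d <- dim(x)
  is_mat <- length(d) == 2L
  if (is_mat) dim(x) <- c(d, 1L)
  d <- dim(x)
  oh <- as.integer(target_size[1L])
  ow <- as.integer(target_size[2L])
  if (oh == d[1L] && ow == d[2L]) {
    if (is_mat) dim(x) <- d[1:2]
    return(x)
  }
  src <- function(n_out, n_in) {
    if (n_out == 1L || n_in == 1L) rep(0, n_out)
    else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  ri <- src(oh, d[1L])
  ci <- src(ow, d[2L])
  r0 <- pmin(floor(ri), d[1L] - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), d[2L] - 1L); fc <- ci - c0
  r1 <- pmin(r0 + 1L, d[1L] - 1L)
  c1 <- pmin(c0 + 1L, d[2L] - 1L)
  out <- array(0, dim = c(oh, ow, d[3L]))
  wr <- matrix(fr, oh, ow)        # row fraction
  wc <- matrix(fc, oh, ow, byrow = TRUE)
  for (ch in seq_len(d[3L])) {
    p <- x[, , ch]
    g <- function(r, c) p[cbind(rep(r + 1L, times = ow),
                                rep(c + 1L, each = oh))]
    tl <- matrix(g(r0, c0), oh, ow)
    tr <- matrix(g(r0, c1), oh, ow)
    bl <- matrix(g(r1, c0), oh, ow)
    br <- matrix(g(r1, c1), oh, ow)
    out[, , ch] <- (1 - wr) * ((1 - wc) * tl + wc * tr) +
      wr * ((1 - wc) * bl + wc * br)
  }
  if (is_mat && d[3L] == 1L) out <- out[, , 1L]
  out
}

# standardize a [0,255] image batch: /255 then (x - 0.5) / 0.5
standardize_pixels <- function(x) (x / 255 - 0.5) / 0.5

# Coerce images (single array, batch array, or list) to a standardized
# (H, W, 3, N) batch at the given input size.
as_batch <- function(images, input_size, preprocess = TRUE) {
  if (is.list(images)) {
    imgs <- images
  } else if (length(dim(images)) == 3L) {
    imgs <- list(images)
  } else if (length(dim(images)) == 4L) {
    imgs <- lapply(seq_len(dim(images)[4L]), function(i) images[, , , i])
  } else {
    stop("images must be an (H, W, 3) array, an (H, W, 3, N) batch, or a list")
  }
  n <- length(imgs)
  x <- array(0, dim = c(input_size[1L], input_size[2L], 3L, n))
  for (i in seq_len(n)) {
    im <- imgs[[i]]
    if (length(dim(im)) != 3L || dim(im)[3L] != 3L)
      stop("image ", i, " is not an (H, W, 3) RGB array")
    if (!identical(dim(im)[1:2], as.integer(input_size)))
      im <- resize_bilinear(im, input_size)
    x[, , , i] <- im
  }
  if (preprocess) x <- standardize_pixels(x)
  x
}
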