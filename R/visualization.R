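# Attention visualization: upsample the stage-1 attention map to image
# resolution, min-max normalize, map through a blue-cyan-green-yellow-red
# colormap, and alpha-blend over the original image. Grad-CAM provides the
# analogous map for architectures without an explicit attention module.

#' Piecewise-linear attention colormap
#'
#' Anchors run from cold to warm — blue, cyan, green, yellow, red — so
#' warmth encodes attention (red strongest, blue weakest).
#'
#' @param anchors Data frame with columns `pos` (strictly increasing in
#'   `[0, 1]`, first 0, last 1), `r`, `g`, `b` (in `[0, 255]`).
#' @return A `colormap_spec`.
#' @export
colormap_spec <- function(anchors = data.frame(
                            pos = c(0, 0.25, 0.5, 0.75, 1),
                            r = c(0, 0, 0, 255, 255),
                            g = c(0, 255, 255, 255, 0),
                            b = c(255, 255, 0, 0, 0))) {
  stopifnot(is.data.frame(anchors),
            all(c("pos", "r", "g", "b") %in% names(anchors)),
            anchors$pos[1L] == 0, anchors$pos[nrow(anchors)] == 1,
            all(diff(anchors$pos) > 0))
  structure(anchors, class = c("colormap_spec", "data.frame"))
}

#' Upsample a single-channel map
#'
#' Bilinear interpolation to the target size; interpolated values stay
#' within `[min(A), max(A)]`.
#'
#' @param A Numeric matrix.
#' @param target_size Integer `(rows, cols)`.
#' @return The resized matrix.
#' @export
upsample_map <- function(A, target_size) {
  stopifnot(is.matrix(A), length(A) > 0)
  resize_bilinear(A, target_size)
}

#' Min-max normalize a map to \[0, 1\]
#'
#' `(A - min) / (max - min)`; a constant map maps to 0.5 everywhere by
#' convention (no position is more important than another).
#'
#' @param A Numeric matrix or array with finite entries.
#' @return Same shape, values in `[0, 1]`.
#' @export
normalize_map <- function(A) {
  stopifnot(all(is.finite(A)))
  rng <- range(A)
  if (rng[1L] == rng[2L]) {
    A[] <- 0.5
    return(A)
  }
  (A - rng[1L]) / (rng[2L] - rng[1L])
}

#' Map values in \[0, 1\] to colors
#'
#' Piecewise-linear interpolation between the colormap anchors. Values
#' outside `[0, 1]` are clipped (with a single warning).
#'
#' @param v Numeric vector/matrix of values.
#' @param spec A [colormap_spec()].
#' @return An `length(v) x 3` matrix of RGB values in `[0, 255]` (the
#'   spatial shape is preserved in an `(H, W, 3)` array when `v` is a
#'   matrix).
#' @examples
#' apply_colormap(c(0, 0.5, 1)) # blue, green, red rows
#' @export
apply_colormap <- function(v, spec = colormap_spec()) {
  d <- dim(v)
  v <- as.numeric(v)
  if (any(v < 0 | v > 1)) {
    warning("values outside [0, 1] clipped before colormap")
    v <- pmin(pmax(v, 0), 1)
  }
  out <- vapply(c("r", "g", "b"), function(ch)
    approx(spec$pos, spec[[ch]], xout = v)$y, numeric(length(v)))
  if (!is.null(d)) array(out, dim = c(d, 3L)) else out
}

#' @importFrom stats approx
NULL

#' Alpha-blend a heatmap over an image
#'
#' `composite = (1 - alpha) * image + alpha * heatmap`, per channel,
#' rounded to integers. `alpha = 0` returns the image bit-identically.
#'
#' @param image `(H, W, 3)` integer array in `[0, 255]`.
#' @param heatmap `(H, W, 3)` array in `[0, 255]`.
#' @param alpha Blend weight in `[0, 1]` (default 0.4).
#' @return `(H, W, 3)` integer composite.
#' @export
overlay <- function(image, heatmap, alpha = 0.4) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!identical(dim(image)[1:2], dim(heatmap)[1:2]))
    stop("image and heatmap spatial dimensions differ: ",
         paste(dim(image)[1:2], collapse = "x"), " vs ",
         paste(dim(heatmap)[1:2], collapse = "x"))
  if (alpha == 0) return(image)
  comp <- (1 - alpha) * image + alpha * heatmap
  array(as.integer(round(comp)), dim = dim(image))
}

#' Attention overlay for one image
#'
#' Runs the model, takes its stage-1 attention map (or a Grad-CAM map for
#' architectures without one), upsamples it to image resolution,
#' normalizes, colors and blends it.
#'
#' @param model Trained `cytoattn_model`.
#' @param image `(H, W, 3)` pixel array in `[0, 255]`.
#' @param alpha Blend weight.
#' @param spec Colormap.
#' @return List with `map` (normalized image-resolution attention),
#'   `heatmap` (`(H, W, 3)` colors), `composite` (blended image), and
#'   `predicted`.
#' @export
attention_overlay <- function(model, image, alpha = 0.4,
                              spec = colormap_spec()) {
  fw <- model_forward(model, image)
  if (model$arch == "spatial_attention") {
    A <- fw$attention[, , 1L, 1L]
  } else {
    cls <- which.max(fw$probs[, 1L])
    A <- grad_cam(model, image, target_class = cls, layer_tag = "last")
  }
  A_img <- normalize_map(upsample_map(A, dim(image)[1:2]))
  heat <- apply_colormap(A_img, spec)
  list(map = A_img, heatmap = heat,
       composite = overlay(image, heat, alpha),
       predicted = as.character(fw$predicted))
}

#' Grad-CAM map
#'
#' Gradient-weighted class activation mapping at a tagged layer: channel
#' weights are the spatial means of the gradient of the target class score
#' with respect to the layer's activations; the map is the ReLU of the
#' weighted channel sum.
#'
#' @param model Trained `cytoattn_model`.
#' @param image `(H, W, 3)` pixel array.
#' @param target_class Class index (integer) or name; defaults to the
#'   predicted class.
#' @param layer_tag One of the model's tagged activations (default
#'   `"last"`, the final convolutional stage of any architecture).
#' @return Single-channel matrix at the layer's resolution (not
#'   normalized).
#' @export
grad_cam <- function(model, image, target_class = NULL,
                     layer_tag = "last") {
  x <- as_batch(list(image), model$config$input_size)
  fw <- sa_dispatch_forward(model, x, training = FALSE, keep_caches = TRUE)
  tags <- names(fw$activations)
  if (!layer_tag %in% tags)
    stop("unknown layer_tag '", layer_tag, "'; available: ",
         paste(tags, collapse = ", "))
  if (is.null(target_class)) target_class <- which.max(fw$probs[, 1L])
  if (is.character(target_class))
    target_class <- match(target_class, model$config$class_names)
  stopifnot(target_class >= 1, target_class <= model$config$num_classes)

  # backprop the raw class score (not the softmax)
  dscores <- matrix(0, nrow = model$config$num_classes, ncol = 1L)
  dscores[target_class, 1L] <- 1
  bw <- sa_dispatch_backward(model, fw$caches, dscores)
  act <- fw$activations[[layer_tag]]
  grad <- bw$act_grads[[layer_tag]]

  d <- dim(act)
  wts <- colMeans(matrix(grad[, , , 1L], nrow = d[1L] * d[2L])) # per channel
  m <- matrix(matrix(act[, , , 1L], nrow = d[1L] * d[2L]) %*% wts,
              nrow = d[1L])
  relu(m)
}

#' Three-row attention figure (original / heatmap / overlay)
#'
#' Writes one column per sample: the original image on top, the colored
#' attention heatmap in the middle, and the alpha-blended composite at
#' the bottom. Individual layers are saved alongside.
#'
#' @param model Trained `cytoattn_model`.
#' @param images List of `(H, W, 3)` pixel arrays.
#' @param path Output PNG path.
#' @param alpha Blend weight.
#' @param labels Optional column titles.
#' @return Invisibly, `path`.
#' @export
attention_figure <- function(model, images, path, alpha = 0.4,
                             labels = NULL) {
  n <- length(images)
  overlays <- lapply(images, function(im)
    attention_overlay(model, im, alpha = alpha))
  h <- dim(images[[1L]])[1L]; w <- dim(images[[1L]])[2L]
  canvas <- array(1, dim = c(3L * h, n * w, 3L))
  for (j in seq_len(n)) {
    cols <- ((j - 1L) * w + 1L):(j * w)
    canvas[1:h, cols, ] <- images[[j]] / 255
    canvas[(h + 1L):(2L * h), cols, ] <- overlays[[j]]$heatmap / 255
    canvas[(2L * h + 1L):(3L * h), cols, ] <- overlays[[j]]$composite / 255
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(canvas, path)
  base <- sub("\\.png$", "", path)
  for (j in seq_len(n)) {
    tag <- if (!is.null(labels)) gsub("[^A-Za-z0-9_-]", "_", labels[j]) else j
    png::writePNG(overlays[[j]]$heatmap / 255,
                  sprintf("%s_heatmap_%s.png", base, tag))
    png::writePNG(overlays[[j]]$composite / 255,
                  sprintf("%s_overlay_%s.png", base, tag))
  }
  invisible(path)
}

#' Mean attention inside vs outside a mask
#'
#' Quantifies attention localization on synthetic data: upsamples and
#' normalizes the model's attention for an image and compares its mean
#' inside the ground-truth cell mask with the mean outside.
#'
#' @param model Trained `cytoattn_model`.
#' @param sample An `image_sample` (with `cell_mask`).
#' @return Named vector `c(inside, outside)`.
#' @export
attention_mask_contrast <- function(model, sample) {
  ov <- attention_overlay(model, sample$pixels)
  m <- sample$cell_mask
  c(inside = mean(ov$map[m]), outside = mean(ov$map[!m]))
}
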