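# Synthetic single-cell smear generator. Each image holds one cell —
# elliptical cytoplasm, a nucleus whose shape/size/hue are class-specific,
# optional granularity speckles and rod-shaped inclusions emulating Auer
# rods — on a pale noisy background, with pixel-level ground-truth masks.
# All randomness flows through per-sample seeds derived from a master seed.

#' Define a synthetic cell class signature
#'
#' A signature is the visual recipe for one class: nucleus shape
#' (round / bilobed / lobulated), nucleus-to-cell area fraction, cytoplasm
#' and nucleus hues, cytoplasmic granularity, and how many Auer-rod-like
#' inclusions a cell may carry.
#'
#' @param class_name Label string.
#' @param nucleus_shape One of `"round"`, `"bilobed"`, `"lobulated"`.
#' @param nucleus_fraction Nucleus area / cell area, in (0, 1).
#' @param cytoplasm_hue,nucleus_hue RGB triples in `[0, 255]`.
#' @param granularity_density Speckles per 1000 px^2 of cytoplasm (>= 0).
#' @param rod_count_range Integer `c(min, max)` of rod inclusions per cell.
#' @return A `class_signature` object.
#' @export
class_signature <- function(class_name, nucleus_shape, nucleus_fraction,
                            cytoplasm_hue, nucleus_hue,
                            granularity_density = 0,
                            rod_count_range = c(0L, 0L)) {
  nucleus_shape <- match.arg(nucleus_shape, c("round", "bilobed", "lobulated"))
  stopifnot(is.character(class_name), length(class_name) == 1L,
            nucleus_fraction > 0, nucleus_fraction < 1,
            length(cytoplasm_hue) == 3L, all(cytoplasm_hue >= 0),
            all(cytoplasm_hue <= 255),
            length(nucleus_hue) == 3L, all(nucleus_hue >= 0),
            all(nucleus_hue <= 255),
            granularity_density >= 0,
            length(rod_count_range) == 2L, all(rod_count_range >= 0),
            rod_count_range[1L] <= rod_count_range[2L])
  structure(list(class_name = class_name, nucleus_shape = nucleus_shape,
                 nucleus_fraction = nucleus_fraction,
                 cytoplasm_hue = as.numeric(cytoplasm_hue),
                 nucleus_hue = as.numeric(nucleus_hue),
                 granularity_density = granularity_density,
                 rod_count_range = as.integer(rod_count_range)),
            class = "class_signature")
}

#' Default signatures of the five APL fusion-gene subtypes
#'
#' Five visually separable recipes named after the APL fusion-gene
#' subtypes. The PML-RARA signature is the only one whose cells always
#' carry rod inclusions (1-3 per cell), mirroring the Auer rods
#' characteristic of classical APL promyelocytes; the remaining classes
#' differ in nucleus shape, nucleus size, stain hue and granularity.
#'
#' @return Named list of five [class_signature()] objects.
#' @export
apl_signatures <- function() {
  sigs <- list(
    class_signature("PML-RARA", "bilobed", 0.50,
                    cytoplasm_hue = c(225, 185, 200),
                    nucleus_hue = c(95, 60, 140),
                    granularity_density = 2.5,
                    rod_count_range = c(1L, 3L)),
    class_signature("TTMV-RARA", "round", 0.68,
                    cytoplasm_hue = c(205, 195, 225),
                    nucleus_hue = c(60, 45, 125),
                    granularity_density = 0.8),
    class_signature("NPM1-RARA", "lobulated", 0.45,
                    cytoplasm_hue = c(235, 210, 195),
                    nucleus_hue = c(125, 75, 150),
                    granularity_density = 1.5),
    class_signature("STAT5B-RARA", "round", 0.35,
                    cytoplasm_hue = c(210, 225, 235),
                    nucleus_hue = c(80, 85, 160),
                    granularity_density = 0.3),
    class_signature("NUP98-RARG", "bilobed", 0.60,
                    cytoplasm_hue = c(240, 215, 230),
                    nucleus_hue = c(145, 90, 120),
                    granularity_density = 4.0)
  )
  names(sigs) <- vapply(sigs, `[[`, character(1), "class_name")
  sigs
}

#' Dataset specification
#'
#' Defaults reproduce the study's class-imbalance: 509, 98, 58, 38 and 12
#' images for PML-RARA, TTMV-RARA, NPM1-RARA, STAT5B-RARA and NUP98-RARG.
#'
#' @param per_class_counts Named integer vector, one count (>= 0) per
#'   signature class name.
#' @param image_size Integer `(rows, cols)`, at least 32x32.
#' @param master_seed Integer; drives every per-sample seed.
#' @param signatures Named list of [class_signature()]s.
#' @return A `dataset_spec` object.
#' @export
dataset_spec <- function(per_class_counts = c("PML-RARA" = 509L,
                                              "TTMV-RARA" = 98L,
                                              "NPM1-RARA" = 58L,
                                              "STAT5B-RARA" = 38L,
                                              "NUP98-RARG" = 12L),
                         image_size = c(128L, 128L),
                         master_seed = 1L,
                         signatures = apl_signatures()) {
  if (is.null(names(per_class_counts)) || any(!nzchar(names(per_class_counts))))
    stop("per_class_counts must be a named vector")
  unknown <- setdiff(names(per_class_counts), names(signatures))
  if (length(unknown))
    stop("unknown class name(s) in per_class_counts: ",
         paste(unknown, collapse = ", "))
  stopifnot(all(per_class_counts >= 0), all(image_size >= 32L))
  structure(list(per_class_counts = vapply(per_class_counts, as.integer,
                                           integer(1)),
                 image_size = as.integer(image_size),
                 master_seed = as.integer(master_seed),
                 signatures = signatures),
            class = "dataset_spec")
}

# per-sample seed derived from (master, class index, sample index); kept
# below 2^31 - 1 so it is a valid R integer seed
derive_seed <- function(master_seed, class_index, sample_index) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) * 2654435761
  s <- (s + as.numeric(class_index) * 97003) %% m
  as.integer((s * 48271 + as.numeric(sample_index) * 7919) %% m)
}

# filled-ellipse mask on a pixel grid; (cy, cx) center, (ry, rx) radii,
# theta rotation in radians
.ellipse_mask <- function(h, w, cy, cx, ry, rx, theta = 0) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  (u / rx)^2 + (v / ry)^2 <= 1
}

.rect_mask <- function(h, w, cy, cx, len, wid, theta) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  abs(u) <= len / 2 & abs(v) <= wid / 2
}

.paint <- function(pixels, mask, hue) {
  for (ch in 1:3) {
    p <- pixels[, , ch]
    p[mask] <- hue[ch]
    pixels[, , ch] <- p
  }
  pixels
}

#' Render one synthetic cell image
#'
#' Draws a single cell according to its class signature: elliptical
#' cytoplasm with random jitter, eccentricity and rotation; a round,
#' bilobed or lobulated nucleus scaled to the signature's area fraction;
#' granularity speckles; rod inclusions (thin rotated rectangles, clipped
#' to the cytoplasm) when the signature requests them; and a pale
#' (230-level) background with additive Gaussian noise. Bit-reproducible
#' for a given seed.
#'
#' @param signature A [class_signature()].
#' @param image_size Integer `(rows, cols)`, at least 32x32.
#' @param seed Integer seed for this sample.
#' @return An `image_sample`: list with `pixels` (`(H, W, 3)` integer array
#'   in `[0, 255]`), `label`, `cell_mask` and `rod_mask` (`(H, W)` logical,
#'   `rod_mask` a subset of `cell_mask`), and `seed`.
#' @export
render_cell <- function(signature, image_size = c(128L, 128L), seed = 1L) {
  stopifnot(inherits(signature, "class_signature"))
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 32L))
    stop("image_size must be at least 32x32 to contain the minimum cell radius")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  h <- image_size[1L]; w <- image_size[2L]
  scale <- min(h, w) / 128

  # background
  pixels <- array(230 + rnorm(h * w * 3, sd = 5), dim = c(h, w, 3L))

  # cytoplasm ellipse, jittered center, mild eccentricity
  cy <- h / 2 + runif(1, -0.05, 0.05) * h
  cx <- w / 2 + runif(1, -0.05, 0.05) * w
  r0 <- 0.32 * min(h, w) * runif(1, 0.9, 1.1)
  ecc <- runif(1, 0.85, 1.18)
  th <- runif(1, 0, pi)
  ry <- r0 * ecc; rx <- r0 / ecc
  cell <- .ellipse_mask(h, w, cy, cx, ry, rx, th)
  pixels <- .paint(pixels, cell, signature$cytoplasm_hue)

  # granularity: speckles in the cytoplasm
  n_spk <- round(signature$granularity_density * sum(cell) / 1000)
  if (n_spk > 0) {
    idx <- which(cell)
    pick <- idx[sample.int(length(idx), min(n_spk, length(idx)))]
    spk_hue <- signature$cytoplasm_hue * 0.55
    rr <- ((pick - 1L) %% h) + 1L
    cc <- ((pick - 1L) %/% h) + 1L
    for (dy in -1:1) for (dx in -1:1) {
      if (abs(dy) + abs(dx) > 1) next
      r2 <- pmin(pmax(rr + dy, 1L), h)
      c2 <- pmin(pmax(cc + dx, 1L), w)
      for (ch in 1:3) pixels[cbind(r2, c2, ch)] <- spk_hue[ch]
    }
  }

  # nucleus: round, bilobed, or lobulated, sized to the area fraction
  f <- signature$nucleus_fraction
  nuc <- switch(signature$nucleus_shape,
    round = {
      .ellipse_mask(h, w, cy + runif(1, -2, 2) * scale,
                    cx + runif(1, -2, 2) * scale,
                    ry * sqrt(f), rx * sqrt(f), th)
    },
    bilobed = {
      rl <- sqrt(f / 1.7)
      ang <- runif(1, 0, pi)
      off <- 0.55 * r0 * rl / sqrt(f) * sqrt(f) # lobe separation
      m1 <- .ellipse_mask(h, w, cy + off * sin(ang), cx + off * cos(ang),
                          ry * rl, rx * rl, th)
      m2 <- .ellipse_mask(h, w, cy - off * sin(ang), cx - off * cos(ang),
                          ry * rl, rx * rl, th)
      m1 | m2
    },
    lobulated = {
      rl <- sqrt(f / 2.4)
      m <- matrix(FALSE, h, w)
      angs <- runif(1, 0, 2 * pi) + (0:2) * 2 * pi / 3
      for (a in angs) {
        off <- 0.45 * r0 * rl / sqrt(f) * sqrt(f)
        m <- m | .ellipse_mask(h, w, cy + off * sin(a), cx + off * cos(a),
                               ry * rl, rx * rl, th)
      }
      m
    })
  nuc <- nuc & cell
  pixels <- .paint(pixels, nuc, signature$nucleus_hue)

  # rod inclusions (Auer-rod-like), clipped to the cytoplasm
  rod_mask <- matrix(FALSE, h, w)
  rng <- signature$rod_count_range
  n_rod <- if (rng[2L] > 0L) sample(seq(rng[1L], rng[2L]), 1L) else 0L
  if (n_rod > 0L) {
    rod_hue <- c(165, 60, 90)
    for (i in seq_len(n_rod)) {
      # center well inside the cell so each rod contributes pixels
      a <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0.15, 0.6)
      rcy <- cy + rad * ry * sin(a)
      rcx <- cx + rad * rx * cos(a)
      rod <- .rect_mask(h, w, rcy, rcx,
                        len = runif(1, 9, 15) * scale,
                        wid = max(2, 2.5 * scale),
                        theta = runif(1, 0, pi)) & cell
      rod_mask <- rod_mask | rod
      pixels <- .paint(pixels, rod, rod_hue)
    }
  }

  # sensor-style additive noise over everything
  pixels <- pixels + rnorm(h * w * 3, sd = 4)
  pixels <- array(as.integer(pmin(pmax(round(pixels), 0), 255)),
                  dim = c(h, w, 3L))
  structure(list(pixels = pixels, label = signature$class_name,
                 cell_mask = cell, rod_mask = rod_mask,
                 seed = as.integer(seed)),
            class = "image_sample")
}

#' Generate a labeled synthetic dataset
#'
#' Renders `per_class_counts[cls]` samples per class. Per-sample seeds are
#' derived deterministically from the master seed, the class index and the
#' sample index, so the whole dataset — and any per-class subset — is
#' bit-reproducible.
#'
#' @param spec A [dataset_spec()].
#' @param dir Optional output directory. When given, images are written as
#'   `<dir>/<class>/img_<idx>.png` with parallel `*_cellmask.png` /
#'   `*_rodmask.png` files and a `manifest.csv` (path, label, seed).
#' @return A list with `samples` (list of `image_sample`s) and `manifest`
#'   (data frame: path, label, seed).
#' @export
generate_dataset <- function(spec = dataset_spec(), dir = NULL) {
  stopifnot(inherits(spec, "dataset_spec"))
  samples <- list()
  rows <- list()
  classes <- names(spec$per_class_counts)
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    n <- spec$per_class_counts[[cls]]
    if (n == 0L) next
    sig <- spec$signatures[[cls]]
    for (j in seq_len(n)) {
      s <- derive_seed(spec$master_seed, ci, j)
      smp <- render_cell(sig, spec$image_size, seed = s)
      samples[[length(samples) + 1L]] <- smp
      rows[[length(rows) + 1L]] <- data.frame(
        path = file.path(cls, sprintf("img_%04d.png", j)),
        label = cls, seed = s, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
              else data.frame(path = character(), label = character(),
                              seed = integer())
  if (!is.null(dir)) write_dataset(samples, manifest, dir)
  list(samples = samples, manifest = manifest)
}

#' Write a generated dataset to disk
#'
#' @param samples List of `image_sample`s.
#' @param manifest Manifest data frame as produced by [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path to the written manifest CSV.
#' @export
write_dataset <- function(samples, manifest, dir) {
  stopifnot(nrow(manifest) == length(samples))
  for (i in seq_along(samples)) {
    p <- file.path(dir, manifest$path[i])
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    png::writePNG(samples[[i]]$pixels / 255, p)
    base <- sub("\\.png$", "", p)
    png::writePNG(samples[[i]]$cell_mask * 1, paste0(base, "_cellmask.png"))
    png::writePNG(samples[[i]]$rod_mask * 1, paste0(base, "_rodmask.png"))
  }
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load images listed in a manifest
#'
#' @param manifest Data frame with `path` and `label` columns (paths
#'   relative to `dir`).
#' @param dir Dataset root directory.
#' @return List of `(H, W, 3)` integer pixel arrays in `[0, 255]`.
#' @export
load_images <- function(manifest, dir) {
  lapply(manifest$path, function(p) {
    im <- png::readPNG(file.path(dir, p))
    if (length(dim(im)) == 2L) im <- array(rep(im, 3L), dim = c(dim(im), 3L))
    array(as.integer(round(im[, , 1:3] * 255)), dim = c(dim(im)[1:2], 3L))
  })
}

# color/shape summary features used by the separability gate: per-channel
# means and sds, dark-pixel fractions at two luminance thresholds, and a
# local-contrast (gradient) summary
.summary_features <- function(pixels) {
  p <- pixels / 255
  lum <- 0.299 * p[, , 1L] + 0.587 * p[, , 2L] + 0.114 * p[, , 3L]
  g <- abs(diff(lum))
  c(mean(p[, , 1L]), mean(p[, , 2L]), mean(p[, , 3L]),
    sd(p[, , 1L]), sd(p[, , 2L]), sd(p[, , 3L]),
    mean(lum < 0.45), mean(lum < 0.62), mean(g), mean(g > 0.15))
}

#' Leave-one-out nearest-centroid separability of a dataset
#'
#' A deliberately simple gate on the generator: each image is summarized by
#' ten color/shape features (channel means and spreads, dark-pixel
#' fractions, local contrast), standardized, and classified by its nearest
#' class centroid with the sample itself left out. Returns the resulting
#' accuracy in `[0, 1]`. Classes whose synthetic recipes carry real signal
#' score far above chance; identical recipes score at chance.
#'
#' @param samples List of `image_sample`s, or a list as returned by
#'   [generate_dataset()].
#' @param labels Optional character vector of labels (defaults to the
#'   samples' own labels).
#' @return Leave-one-out nearest-centroid accuracy.
#' @export
class_separability_check <- function(samples, labels = NULL) {
  if (!is.null(samples$samples)) samples <- samples$samples
  if (is.null(labels))
    labels <- vapply(samples, `[[`, character(1), "label")
  stopifnot(length(labels) == length(samples))
  if (length(unique(labels)) < 2L)
    stop("separability is undefined for a single class")
  feats <- t(vapply(samples, function(s) .summary_features(s$pixels),
                    numeric(10)))
  mu <- colMeans(feats)
  sdv <- apply(feats, 2L, sd)
  sdv[sdv == 0] <- 1
  feats <- sweep(sweep(feats, 2L, mu), 2L, sdv, `/`)

  classes <- unique(labels)
  sums <- rowsum(feats, labels)
  counts <- as.vector(table(labels)[rownames(sums)])
  correct <- 0L
  for (i in seq_along(samples)) {
    best <- NA_character_; bestd <- Inf
    for (ci in seq_len(nrow(sums))) {
      cls <- rownames(sums)[ci]
      n <- counts[ci] - (labels[i] == cls)
      if (n == 0L) next # left-out singleton class has no centroid
      cen <- (sums[ci, ] - (labels[i] == cls) * feats[i, ]) / n
      d <- sum((feats[i, ] - cen)^2)
      if (d < bestd) { bestd <- d; best <- cls }
    }
    correct <- correct + identical(best, labels[i])
  }
  correct / length(samples)
}
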