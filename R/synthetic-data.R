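# Synthetic labeled shapes with ground-truth masks: the desk-scale stand-in
# for a natural-image benchmark. Each class is a distinct high-intensity
# glyph placed at a random position and scale on class-independent background
# noise; the binary mask marks the glyph pixels (the discriminative region).

glyph_kinds <- c("disk", "ring", "bar", "cross", "square", "diag")

glyph_mask <- function(kind, h, w, cy, cx, r) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- yy - cy
  dx <- xx - cx
  d2 <- dy^2 + dx^2
  switch(kind,
    disk = d2 <= r^2,
    ring = d2 <= r^2 & d2 >= (r - 2)^2,
    bar = abs(dx) <= 1 & abs(dy) <= r,
    cross = (abs(dx) <= 1 & abs(dy) <= r) | (abs(dy) <= 1 & abs(dx) <= r),
    square = pmax(abs(dy), abs(dx)) <= r & pmax(abs(dy), abs(dx)) >= r - 1,
    diag = abs(dy - dx) <= 1 & d2 <= 2 * r^2,
    stopf("unknown glyph kind '%s'", kind))
}

#' Generate a synthetic labeled-shape dataset
#'
#' Single-channel images (`image_size x image_size`, intensities 0-255) in
#' which each class is one glyph type (disk, ring, bar, cross, square frame,
#' diagonal stroke) drawn at intensity 200 +/- 20 at a random position and
#' scale, over uniform background noise in `[0, noise_level * 255]`. The
#' binary mask marks glyph pixels; mask area always lies between 5% and 40%
#' of the image. Classes are balanced and each class is split
#' `train_frac` / `1 - train_frac` into train and test.
#'
#' @param n_classes Number of classes (2..6).
#' @param image_size Image side length, `>= 12`.
#' @param n_per_class Images per class.
#' @param noise_level Background noise amplitude in `[0, 1]`.
#' @param seed Integer seed; the dataset is bitwise-reproducible.
#' @param train_frac Fraction of each class tagged `"train"`.
#' @return A `shape_dataset`: list with `images` `(1, H, W, n)`, `labels`
#'   (1-based), `masks` `(H, W, n)`, `split`, `n_classes`, `glyphs`, and the
#'   generation parameters.
#' @export
make_shape_dataset <- function(n_classes = 4L, image_size = 16L,
                               n_per_class = 100L, noise_level = 0.3,
                               seed = 1L, train_frac = 0.75) {
  n_classes <- as.integer(n_classes)
  image_size <- as.integer(image_size)
  if (n_classes < 2L) stopf("need at least 2 classes")
  if (n_classes > length(glyph_kinds)) {
    stopf("at most %d classes available (one glyph each)", length(glyph_kinds))
  }
  if (image_size < 12L) stopf("image_size must be >= 12")
  n <- n_classes * n_per_class
  h <- image_size
  area <- h * h
  min_area <- ceiling(0.05 * area)
  max_area <- floor(0.40 * area)
  images <- array(0, c(1L, h, h, n))
  masks <- array(0, c(h, h, n))
  labels <- rep(seq_len(n_classes), each = n_per_class)
  glyphs <- glyph_kinds[seq_len(n_classes)]
  with_seed(seed, {
    for (i in seq_len(n)) {
      kind <- glyphs[labels[i]]
      repeat {
        r <- sample(3:max(3L, floor(h / 4)), 1L)
        cy <- sample((r + 1):(h - r), 1L)
        cx <- sample((r + 1):(h - r), 1L)
        m <- glyph_mask(kind, h, h, cy, cx, r)
        if (sum(m) >= min_area && sum(m) <= max_area) break
      }
      img <- matrix(stats::runif(area, 0, noise_level * 255), h, h)
      img[m] <- clamp(200 + stats::runif(sum(m), -20, 20), 0, 255)
      images[1, , , i] <- round(img)
      masks[, , i] <- m * 1
    }
  })
  split <- rep("test", n)
  n_train <- round(train_frac * n_per_class)
  for (k in seq_len(n_classes)) {
    split[which(labels == k)[seq_len(n_train)]] <- "train"
  }
  structure(list(images = images, labels = labels, masks = masks,
                 split = split, n_classes = n_classes,
                 image_size = image_size, n_per_class = as.integer(n_per_class),
                 noise_level = noise_level, seed = as.integer(seed),
                 glyphs = glyphs),
            class = "shape_dataset")
}

#' Stack two images vertically for the sensory-suppression probe
#'
#' Concatenates two equal-width images top over bottom and offsets the second
#' mask by the first image's height. The classifier must tolerate variable
#' input resolution (global average pooling makes predictions
#' resolution-independent).
#'
#' @param image_a,image_b Arrays `(C, H, W)` with equal channel count and
#'   width.
#' @param mask_a,mask_b Binary `H x W` matrices for the two images.
#' @return List with the stacked `image` `(C, Ha + Hb, W)` and full-size
#'   `mask_a`, `mask_b` (each `(Ha + Hb) x W`).
#' @export
compose_two_object <- function(image_a, image_b, mask_a, mask_b) {
  da <- dim(image_a)
  db <- dim(image_b)
  if (length(da) != 3L || length(db) != 3L) stopf("images must be (C, H, W)")
  if (da[1] != db[1] || da[3] != db[3]) {
    stopf("images must share channel count and width")
  }
  ha <- da[2]
  hb <- db[2]
  out <- array(0, c(da[1], ha + hb, da[3]))
  out[, seq_len(ha), ] <- image_a
  out[, ha + seq_len(hb), ] <- image_b
  ma <- matrix(0, ha + hb, da[3])
  mb <- matrix(0, ha + hb, da[3])
  ma[seq_len(ha), ] <- as.matrix(mask_a)
  mb[ha + seq_len(hb), ] <- as.matrix(mask_b)
  list(image = out, mask_a = ma, mask_b = mb)
}
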