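#' Augmentation configuration
#'
#' Settings for the four-step joint augmentation of image/mask pairs:
#' rotations by 90/180/270 degrees, a horizontal flip, additive colour noise
#' applied to the image only, and a border zoom. Together with the original
#' this yields seven variations per training pair.
#'
#' @param noise_sigma Standard deviation of the additive Gaussian colour
#'   noise, in 8-bit intensity units (default 10).
#' @param zoom_border Fraction of each image dimension removed by the zoom
#'   step in total (default 0.25, i.e. 12.5 % per side); must be in (0, 0.5).
#' @param seed Integer seed driving the noise step.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(noise_sigma = 10, zoom_border = 0.25, seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (zoom_border <= 0 || zoom_border >= 0.5) stop("zoom_border must be in (0, 0.5)")
  structure(
    list(
      rotation_angles = c(90L, 180L, 270L),
      noise_sigma = noise_sigma,
      zoom_border = zoom_border,
      seed = as.integer(seed)
    ),
    class = "augment_config"
  )
}

rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

rotate_matrix <- function(m, angle) {
  switch(as.character(angle),
    "90" = rot90_cw(m),
    "180" = rot90_cw(rot90_cw(m)),
    "270" = rot90_cw(rot90_cw(rot90_cw(m)))
  )
}

apply_channels <- function(image, f) {
  ch <- lapply(1:3, function(k) f(unclass(image)[, , k]))
  rgb_image(array(unlist(ch), dim = c(dim(ch[[1]]), 3L)))
}

#' Rotate an image/mask pair
#'
#' Rotates both members clockwise by the same multiple of 90 degrees, so the
#' per-class pixel histogram of the mask is preserved exactly; 90 and 270
#' degree rotations swap width and height.
#'
#' @param image An [rgb_image()].
#' @param mask The paired [label_mask()].
#' @param angle One of 90, 180, 270.
#' @return List with elements `image` and `mask`.
#' @export
rotate_pair <- function(image, mask, angle) {
  if (!angle %in% c(90, 180, 270)) stop("angle must be one of 90, 180, 270")
  check_pair(image, mask)
  list(
    image = apply_channels(image, function(m) rotate_matrix(m, angle)),
    mask = label_mask(rotate_matrix(unclass(mask), angle))
  )
}

#' Flip an image/mask pair horizontally
#'
#' Mirrors both members about the vertical axis; applying it twice restores
#' the input.
#'
#' @inheritParams rotate_pair
#' @return List with elements `image` and `mask`.
#' @export
flip_pair <- function(image, mask) {
  check_pair(image, mask)
  flip <- function(m) m[, ncol(m):1, drop = FALSE]
  list(
    image = apply_channels(image, flip),
    mask = label_mask(flip(unclass(mask)))
  )
}

#' Add random colour noise to the image of a pair
#'
#' Seeded per-pixel, per-channel additive Gaussian noise, clipped to
#' `[0, 255]`. The mask is returned bit-identical: ground-truth labels must
#' not change in the presence of noise.
#'
#' @inheritParams rotate_pair
#' @param sigma Noise standard deviation in intensity units.
#' @param seed Integer seed; the same seed reproduces the same noisy image.
#' @return List with elements `image` and `mask`.
#' @export
noise_image <- function(image, mask, sigma = 10, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  check_pair(image, mask)
  px <- unclass(image)
  if (sigma > 0) {
    noise <- withr::with_seed(
      as.integer(seed),
      stats::rnorm(length(px), mean = 0, sd = sigma)
    )
    px <- pmin(pmax(round(px + noise), 0), 255)
  }
  list(image = rgb_image(array(px, dim = dim(image))), mask = mask)
}

#' Zoom in on an image/mask pair by removing its borders
#'
#' Crops the central `(1 - border_fraction)` of each dimension (the crop
#' window is `floor((1 - f) * dim)`, centred, with any odd leftover pixel on
#' the trailing side) and resizes back to the original resolution. The image
#' is resized bilinearly; the mask with nearest-neighbour so labels stay
#' categorical. Items lying wholly inside the removed border disappear.
#'
#' @inheritParams rotate_pair
#' @param border_fraction Fraction of each dimension removed in total;
#'   default 0.25 as in the buffet augmentation recipe.
#' @return List with elements `image` and `mask`.
#' @export
zoom_pair <- function(image, mask, border_fraction = 0.25) {
  if (border_fraction <= 0 || border_fraction >= 0.5) {
    stop("border_fraction must be in (0, 0.5)")
  }
  check_pair(image, mask)
  h <- img_height(image)
  w <- img_width(image)
  ch <- floor((1 - border_fraction) * h)
  cw <- floor((1 - border_fraction) * w)
  if (ch < 1 || cw < 1) stop("crop window smaller than 1 pixel")
  r0 <- floor((h - ch) / 2)
  c0 <- floor((w - cw) / 2)
  rows <- r0 + seq_len(ch)
  cols <- c0 + seq_len(cw)
  crop_img <- unclass(image)[rows, cols, , drop = FALSE]
  crop_mask <- unclass(mask)[rows, cols, drop = FALSE]
  list(
    image = resize_image(rgb_image(crop_img), w, h),
    mask = resize_mask(label_mask(crop_mask), w, h)
  )
}

# EBImage stores images as (x, y[, channel]); transpose in and out.
resize_image <- function(image, width, height) {
  arr <- aperm(unclass(image), c(2, 1, 3)) / 255
  img <- EBImage::Image(arr, colormode = "Color")
  out <- EBImage::resize(img, w = width, h = height, filter = "bilinear")
  out <- aperm(EBImage::imageData(out), c(2, 1, 3))
  rgb_image(pmin(pmax(round(out * 255), 0), 255))
}

resize_mask <- function(mask, width, height) {
  img <- EBImage::Image(t(unclass(mask)))
  out <- EBImage::resize(img, w = width, h = height, filter = "none")
  label_mask(t(EBImage::imageData(out)))
}

#' Generate the seven training variants of one image/mask pair
#'
#' The variant set is the original plus its three rotations, the horizontal
#' flip, the colour-noise copy and the border zoom.
#'
#' @inheritParams rotate_pair
#' @param config An [augment_config()].
#' @param seed Seed for the noise variant (defaults to the config seed).
#' @return Named list of seven `(image, mask)` pairs, names
#'   `orig, r90, r180, r270, flip, noise, zoom`.
#' @export
augment_pair <- function(image, mask, config = augment_config(), seed = config$seed) {
  check_pair(image, mask)
  list(
    orig = list(image = image, mask = mask),
    r90 = rotate_pair(image, mask, 90),
    r180 = rotate_pair(image, mask, 180),
    r270 = rotate_pair(image, mask, 270),
    flip = flip_pair(image, mask),
    noise = noise_image(image, mask, sigma = config$noise_sigma, seed = seed),
    zoom = zoom_pair(image, mask, border_fraction = config$zoom_border)
  )
}

#' Expand the training subset of a manifest with augmentation
#'
#' Every training pair is replaced by its seven variants (written as PNGs
#' with suffixes `_orig, _r90, _r180, _r270, _flip, _noise, _zoom`);
#' validation and testing pairs are left untouched, so a manifest with
#' subset sizes (T, V, S) grows to exactly `7 T + V + S` items — (85, 12, 24)
#' becomes the 631-image augmented set.
#'
#' @param manifest A `dataset_manifest` (see [split_dataset()]).
#' @param out_dir Directory receiving the variant PNGs.
#' @param config An [augment_config()].
#' @return The augmented `dataset_manifest`.
#' @export
augment_training_set <- function(manifest, out_dir, config = augment_config()) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(manifest))
  train_idx <- 0L
  for (i in seq_len(nrow(manifest))) {
    if (manifest$subset[i] != "training") {
      rows[[i]] <- manifest[i, ]
      next
    }
    train_idx <- train_idx + 1L
    image <- read_image(manifest$image[i])
    mask <- read_mask(manifest$mask[i])
    variants <- augment_pair(image, mask, config,
      seed = (config$seed + train_idx) %% .Machine$integer.max
    )
    stem <- sub("\\.png$", "", basename(manifest$image[i]))
    rows[[i]] <- dplyr::bind_rows(lapply(names(variants), function(v) {
      ip <- file.path(out_dir, sprintf("%s_%s.png", stem, v))
      mp <- file.path(out_dir, sprintf("%s_%s_mask.png", stem, v))
      write_image(variants[[v]]$image, ip)
      write_mask(variants[[v]]$mask, mp)
      tibble::tibble(image = ip, mask = mp, subset = "training")
    }))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dataset_manifest", class(out))
  out
}

check_pair <- function(image, mask) {
  stopifnot(inherits(image, "rgb_image"), inherits(mask, "label_mask"))
  if (!identical(dim(image)[1:2], dim(mask)[1:2])) {
    stop("image and mask dimensions differ")
  }
  invisible(TRUE)
}
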