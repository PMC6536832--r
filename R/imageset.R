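#' Construct an RGB image object
#'
#' An `rgb_image` is a `height x width x 3` integer array of channel
#' intensities in `[0, 255]`, row-major with the origin at the top-left.
#'
#' @param pixels Numeric array of dimension `c(height, width, 3)` with values
#'   in `[0, 255]`.
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("format error: an RGB image must be a height x width x 3 array")
  }
  if (any(dim(pixels)[1:2] < 1L)) {
    stop("format error: image dimensions must be positive")
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255)) {
    stop("format error: channel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_image")
}

#' Construct a pixel-level label mask
#'
#' A `label_mask` is a single-channel integer matrix giving the class index of
#' every pixel; class 0 is the background. When a registry is supplied every
#' label must be a valid registry index.
#'
#' @param labels Integer matrix of class indices (`height x width`).
#' @param registry Optional [class_registry()] to validate labels against.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, registry = NULL) {
  if (!is.matrix(labels)) {
    stop("format error: a label mask must be a single-channel matrix")
  }
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels))) {
    stop("validation error: labels must be non-negative integers")
  }
  storage.mode(labels) <- "integer"
  if (!is.null(registry)) {
    n_cl <- nrow(registry)
    bad <- labels[labels >= n_cl]
    if (length(bad)) {
      stop(sprintf(
        "validation error: label %d is not a valid class index (registry has indices 0-%d)",
        bad[1], n_cl - 1L
      ))
    }
  }
  structure(labels, class = "label_mask")
}

#' Dimensions helpers
#' @param x An `rgb_image` or `label_mask`.
#' @return Integer width or height in pixels.
#' @export
img_width <- function(x) dim(x)[2]

#' @rdname img_width
#' @export
img_height <- function(x) dim(x)[1]

#' Read an 8-bit RGB PNG
#'
#' @param path Path to a PNG file with exactly three channels.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) {
    stop("format error: ", path, " is not a 3-channel RGB image")
  }
  rgb_image(round(px * 255))
}

#' Write an RGB image as an 8-bit PNG
#' @param image An [rgb_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' Read a single-channel label mask PNG
#'
#' Masks are stored as 8-bit single-channel PNGs holding raw class indices
#' (not palette colours), so the encoding is lossless for up to 256 classes.
#'
#' @param path Path to a single-channel PNG.
#' @param registry Optional [class_registry()]; labels are validated against
#'   it when given.
#' @return A [label_mask()].
#' @export
read_mask <- function(path, registry = NULL) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  px <- png::readPNG(path)
  if (!is.matrix(px)) {
    stop("format error: ", path, " is not a single-channel mask PNG")
  }
  label_mask(round(px * 255), registry = registry)
}

#' Write a label mask as an 8-bit single-channel PNG
#' @param mask A [label_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (any(mask > 255L)) stop("format error: 8-bit masks support at most 256 classes")
  png::writePNG(unclass(mask) / 255, path)
  invisible(path)
}

#' Construct a class registry
#'
#' The registry is the ordered mapping of class index to food-class name and
#' palette colour. Index 0 is always the background. The buffet study setting
#' uses 55 food classes plus background (56 classes in total), but any
#' contiguous registry is accepted.
#'
#' @param df Data frame with columns `index`, `name`, `r`, `g`, `b`.
#' @return A tibble of class `class_registry`.
#' @export
class_registry <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("index", "name", "r", "g", "b")
  if (!all(need %in% names(df))) {
    stop("registry must have columns index,name,r,g,b")
  }
  df <- df[order(df$index), need]
  if (!identical(as.integer(df$index), seq_len(nrow(df)) - 1L)) {
    stop("registry indices must be contiguous from 0")
  }
  if (df$name[1] != "background") stop("registry index 0 must be named 'background'")
  if (anyDuplicated(df$name)) stop("registry names must be unique")
  if (anyDuplicated(df[c("r", "g", "b")])) stop("registry palette colours must be unique")
  if (any(df$r < 0 | df$r > 255 | df$g < 0 | df$g > 255 | df$b < 0 | df$b > 255)) {
    stop("palette colours must lie in [0, 255]")
  }
  class(df) <- c("class_registry", class(df))
  df
}

#' Build a registry from food-class names
#'
#' Assigns each class a palette colour from the `{0, 85, 170, 255}^3` grid,
#' whose minimum pairwise distance (85 intensity units along one channel)
#' makes nearest-colour decoding of synthetic scenes unambiguous. Background
#' (index 0) is black.
#'
#' @param class_names Character vector of food-class names (background is
#'   added automatically and must not be included).
#' @return A [class_registry()].
#' @export
make_registry <- function(class_names) {
  if ("background" %in% class_names) stop("'background' is added automatically")
  n <- length(class_names) + 1L
  lv <- c(0L, 85L, 170L, 255L)
  grid <- expand.grid(b = lv, g = lv, r = lv)[, c("r", "g", "b")]
  if (n > nrow(grid)) stop("at most ", nrow(grid) - 1L, " food classes supported")
  class_registry(tibble::tibble(
    index = 0:(n - 1L),
    name = c("background", class_names),
    r = grid$r[seq_len(n)], g = grid$g[seq_len(n)], b = grid$b[seq_len(n)]
  ))
}

#' Read / write a class registry CSV (`index,name,r,g,b`)
#' @param path CSV path.
#' @return A [class_registry()].
#' @export
read_registry <- function(path) {
  class_registry(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_registry
#' @param registry A [class_registry()].
#' @export
write_registry <- function(registry, path) {
  readr::write_csv(tibble::as_tibble(unclass(registry)), path)
  invisible(path)
}

#' Randomly split an image set into training / validation / testing
#'
#' Simple random split with validation = round-half-up(0.10 N) and
#' testing = round-half-up(0.20 N); training takes the remainder, so for the
#' 121 buffet photographs the subsets are 85 / 12 / 24. Every image lands in
#' exactly one subset and the split is reproducible for a fixed seed.
#'
#' @param items Character vector of image paths, or a data frame with columns
#'   `image` and `mask`.
#' @param seed Integer seed making the split deterministic.
#' @return A `dataset_manifest` tibble with columns `image`, `mask`, `subset`.
#' @export
split_dataset <- function(items, seed) {
  if (is.character(items)) {
    items <- tibble::tibble(image = items, mask = mask_path_for(items))
  }
  items <- tibble::as_tibble(items)
  stopifnot(all(c("image", "mask") %in% names(items)))
  n <- nrow(items)
  if (n < 3L) stop("need at least 3 images to populate three subsets")
  n_val <- round_half_up(0.10 * n)
  n_test <- round_half_up(0.20 * n)
  ord <- withr::with_seed(as.integer(seed), sample.int(n))
  subset <- character(n)
  subset[ord[seq_len(n_val)]] <- "validation"
  subset[ord[n_val + seq_len(n_test)]] <- "testing"
  subset[subset == ""] <- "training"
  out <- tibble::tibble(image = items$image, mask = items$mask, subset = subset)
  class(out) <- c("dataset_manifest", class(out))
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Default mask path convention: `<stem>_mask.png` next to the image
#' @param image_path Image path(s).
#' @return Mask path(s).
#' @export
mask_path_for <- function(image_path) {
  sub("\\.png$", "_mask.png", image_path)
}

#' Read / write a dataset manifest CSV (`image,mask,subset`)
#' @param path CSV path.
#' @return A `dataset_manifest` tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("image", "mask", "subset") %in% names(m)))
  bad <- setdiff(unique(m$subset), c("training", "validation", "testing"))
  if (length(bad)) stop("unknown subset tag: ", bad[1])
  class(m) <- c("dataset_manifest", class(m))
  m
}

#' @rdname read_manifest
#' @param manifest A `dataset_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(tibble::as_tibble(unclass(manifest)), path)
  invisible(path)
}

#' Enumerate food-item regions of a mask
#'
#' A food (or drink) item is one 4-connected component of one non-background
#' class, matching how individual items are counted on a buffet photograph.
#'
#' @param mask A [label_mask()].
#' @return Tibble with columns `class_index`, `component_id` (1-based within
#'   class) and `pixel_count`; zero rows for an all-background mask.
#' @export
mask_to_items <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  classes <- sort(unique(as.vector(mask)))
  classes <- classes[classes != 0L]
  out <- lapply(classes, function(k) {
    lab <- EBImage::bwlabel(EBImage::Image(t(unclass(mask) == k)))
    counts <- tabulate(EBImage::imageData(lab))
    tibble::tibble(
      class_index = k,
      component_id = seq_along(counts),
      pixel_count = counts
    )
  })
  if (!length(out)) {
    return(tibble::tibble(
      class_index = integer(), component_id = integer(), pixel_count = integer()
    ))
  }
  dplyr::bind_rows(out)
}
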