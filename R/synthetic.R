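#' Specification of a synthetic buffet scene
#'
#' Describes a synthetic stand-in for a buffet photograph: coloured food
#' regions (discs, rectangles, blobs) on a dark background, at the study's
#' working resolution of 500 x 375 pixels, with 5-15 items per scene
#' (buffet images hold over eleven foods on average). Regions are painted in
#' each class's palette colour plus mild seeded texture, and the paired mask
#' holds the exact class indices, so ground truth is known by construction.
#'
#' @param width,height Scene size in pixels (default 500 x 375).
#' @param n_items Length-2 integer range for the number of food items
#'   (default `c(5, 15)`); a scalar fixes the count.
#' @param classes Registry indices to draw items from; `NULL` means all
#'   non-background classes.
#' @param shapes Shape vocabulary, a subset of disc / rectangle / blob.
#' @param texture_amplitude Half-width of the uniform per-pixel texture noise
#'   in intensity units (default 8; small relative to the 85-unit palette
#'   spacing, so nearest-colour decoding stays exact).
#' @param seed Integer seed; the scene is a pure function of (spec, seed).
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width = 500, height = 375, n_items = c(5, 15),
                       classes = NULL, shapes = c("disc", "rectangle", "blob"),
                       texture_amplitude = 8, seed = 1L) {
  if (length(n_items) == 1L) n_items <- c(n_items, n_items)
  stopifnot(
    width > 0, height > 0, all(n_items >= 0), n_items[1] <= n_items[2],
    texture_amplitude >= 0, all(shapes %in% c("disc", "rectangle", "blob"))
  )
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      n_items = as.integer(n_items), classes = classes, shapes = shapes,
      texture_amplitude = texture_amplitude, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

#' Generate a synthetic buffet image with exact ground truth
#'
#' Items are laid out one per cell of a coarse grid, so no item occludes
#' another and every drawn class is present in the mask. Each region is
#' painted with its class's palette colour plus uniform texture in
#' `[-texture_amplitude, texture_amplitude]`; the mask receives the raw
#' class index. Deterministic for a fixed spec seed.
#'
#' @param spec A [scene_spec()].
#' @param registry A [class_registry()].
#' @return List with elements `image` ([rgb_image()]) and `mask`
#'   ([label_mask()]).
#' @export
generate_scene <- function(spec, registry) {
  stopifnot(inherits(spec, "scene_spec"), inherits(registry, "class_registry"))
  pool <- spec$classes
  if (is.null(pool)) pool <- registry$index[registry$index != 0L]
  stopifnot(all(pool %in% registry$index), !0L %in% pool)
  withr::with_seed(spec$seed, {
    h <- spec$height
    w <- spec$width
    n <- if (spec$n_items[1] == spec$n_items[2]) {
      spec$n_items[1]
    } else {
      sample(spec$n_items[1]:spec$n_items[2], 1)
    }
    n <- min(n, length(pool))
    classes <- if (n > 0) sample_vec(pool, n) else integer()

    mask <- matrix(0L, h, w)
    r_idx <- row(mask)
    c_idx <- col(mask)

    if (n > 0) {
      ncx <- ceiling(sqrt(n))
      ncy <- ceiling(n / ncx)
      cw <- w / ncx
      chh <- h / ncy
      for (i in seq_len(n)) {
        cell_x <- (i - 1) %% ncx
        cell_y <- (i - 1) %/% ncx
        cx <- cell_x * cw + stats::runif(1, 0.35, 0.65) * cw
        cy <- cell_y * chh + stats::runif(1, 0.35, 0.65) * chh
        rad <- max(2, stats::runif(1, 0.12, 0.3) * min(cw, chh))
        shape <- sample_vec(spec$shapes, 1)
        inside <- switch(shape,
          disc = (r_idx - cy)^2 + (c_idx - cx)^2 <= rad^2,
          rectangle = abs(r_idx - cy) <= rad * stats::runif(1, 0.6, 1.4) &
            abs(c_idx - cx) <= rad * stats::runif(1, 0.6, 1.4),
          blob = {
            hit <- matrix(FALSE, h, w)
            for (k in seq_len(3)) {
              dx <- stats::runif(1, -0.5, 0.5) * rad
              dy <- stats::runif(1, -0.5, 0.5) * rad
              hit <- hit |
                (r_idx - cy - dy)^2 + (c_idx - cx - dx)^2 <= (0.7 * rad)^2
            }
            hit
          }
        )
        mask[inside] <- classes[i]
      }
    }

    palette <- as.matrix(registry[, c("r", "g", "b")])
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(palette[mask + 1L, ch], h, w)
      if (spec$texture_amplitude > 0) {
        plane <- plane +
          round(stats::runif(h * w, -spec$texture_amplitude, spec$texture_amplitude))
      }
      px[, , ch] <- pmin(pmax(plane, 0), 255)
    }
    list(image = rgb_image(px), mask = label_mask(mask, registry))
  })
}

# sample() treats a length-1 x as 1:x; this keeps set semantics
sample_vec <- function(x, n) x[sample.int(length(x), n)]

#' Randomly corrupt a label mask
#'
#' Each pixel is independently relabeled, with probability `error_rate`, to a
#' uniformly random *different* class, so the expected pixel accuracy against
#' the original is exactly `1 - error_rate`. Used as the oracle for the
#' measure-recovery tests.
#'
#' @param mask A [label_mask()].
#' @param error_rate Per-pixel corruption probability in `[0, 1]`.
#' @param n_cl Number of classes (labels drawn from `0:(n_cl-1)`).
#' @param seed Integer seed.
#' @return A [label_mask()] of the same shape.
#' @export
perturb_mask <- function(mask, error_rate, n_cl, seed = 1L) {
  stopifnot(inherits(mask, "label_mask"), error_rate >= 0, error_rate <= 1)
  n_cl <- as.integer(n_cl)
  if (any(mask >= n_cl)) stop("mask contains a label >= n_cl")
  withr::with_seed(as.integer(seed), {
    v <- as.vector(unclass(mask))
    flip <- stats::runif(length(v)) < error_rate
    # adding 1..n_cl-1 modulo n_cl never returns the original label
    offset <- sample.int(n_cl - 1L, sum(flip), replace = TRUE)
    v[flip] <- (v[flip] + offset) %% n_cl
    label_mask(matrix(v, nrow(mask), ncol(mask)))
  })
}

#' Toy food catalogue for worked examples and tests
#'
#' A small FoodEx2-like catalogue spanning all four food categories and
#' containing, among others, "salad dressing", "herrings", "fresh pasta" and
#' "dried pasta" — the entries needed by the worked matching examples — plus
#' plain raw foods such as "tomato" and "pear".
#'
#' @return A [food_catalogue()] with 24 entries.
#' @export
toy_catalogue <- function() {
  entries <- tibble::tribble(
    ~code, ~name, ~category,
    "A01AA", "tomato", "raw",
    "A01AB", "pear", "raw",
    "A01AC", "apple", "raw",
    "A01AD", "carrot", "raw",
    "A01AE", "cucumber", "raw",
    "A01AF", "banana", "raw",
    "A01AG", "lettuce", "raw",
    "A01AH", "herrings", "raw",
    "A01AJ", "chicken breast", "raw",
    "A01AK", "egg", "raw",
    "A02BA", "salad dressing", "derivative",
    "A02BB", "fresh pasta", "derivative",
    "A02BC", "dried pasta", "derivative",
    "A02BD", "apple juice", "derivative",
    "A02BE", "tomato sauce", "derivative",
    "A02BF", "smoked salmon", "derivative",
    "A02BG", "white bread", "derivative",
    "A02BH", "cheese", "derivative",
    "A03CA", "rice with peas", "simple composite",
    "A03CB", "bread with butter", "simple composite",
    "A04DA", "pasta salad with tuna and egg", "aggregated composite",
    "A04DB", "vegetable soup", "aggregated composite",
    "A04DC", "chicken sandwich", "aggregated composite",
    "A04DD", "margherita pizza", "aggregated composite"
  )
  food_catalogue(entries)
}

#' Toy food composition table covering the toy catalogue
#'
#' One nutrient record per catalogue code with plausible, deterministic
#' non-negative amounts per 100 g, so every standardized toy food links.
#'
#' @param catalogue A [food_catalogue()] (default [toy_catalogue()]).
#' @return An [fcdb()] tibble.
#' @export
toy_fcdb <- function(catalogue = toy_catalogue()) {
  i <- seq_len(length(catalogue))
  fcdb(tibble::tibble(
    code = catalogue$entries$code,
    name = catalogue$entries$name,
    energy_kcal = 40 + (i * 37) %% 360,
    protein_g = (i * 13) %% 30,
    carbohydrate_g = (i * 17) %% 60,
    fat_g = (i * 7) %% 40
  ))
}

#' Registry of the toy food classes
#'
#' Background plus the toy catalogue's food names, with grid palette colours
#' (see [make_registry()]).
#'
#' @param catalogue A [food_catalogue()] (default [toy_catalogue()]).
#' @return A [class_registry()].
#' @export
toy_registry <- function(catalogue = toy_catalogue()) {
  make_registry(catalogue$entries$name)
}

#' Nearest-palette-colour segmentation
#'
#' Desk-scale reference segmenter: assigns each pixel the registry class
#' whose palette colour is nearest in Euclidean RGB distance (ties broken by
#' lower class index). On synthetic scenes, whose palette colours are
#' separated by at least 85 intensity units, this recovers the ground-truth
#' mask exactly under the default texture, giving the pipeline an
#' end-to-end identity check. It is a geometric decoder for synthetic
#' fixtures, not a model of real food imagery.
#'
#' @param image An [rgb_image()].
#' @param registry A [class_registry()] with distinct palette colours.
#' @return A [label_mask()].
#' @export
baseline_segment <- function(image, registry) {
  stopifnot(inherits(image, "rgb_image"), inherits(registry, "class_registry"))
  palette <- as.matrix(registry[, c("r", "g", "b")])
  n_cl <- nrow(palette)
  h <- img_height(image)
  w <- img_width(image)
  px <- matrix(as.numeric(unclass(image)), h * w, 3)
  d2 <- matrix(0, h * w, n_cl)
  for (k in seq_len(n_cl)) {
    d2[, k] <- (px[, 1] - palette[k, 1])^2 +
      (px[, 2] - palette[k, 2])^2 +
      (px[, 3] - palette[k, 3])^2
  }
  best <- max.col(-d2, ties.method = "first") - 1L
  label_mask(matrix(best, h, w), registry)
}

#' Simulate a full synthetic data set on disk
#'
#' Writes `n_images` scene/mask PNG pairs, a split manifest, the registry,
#' the toy catalogue and the toy FCDB into `out_dir`, making every pipeline
#' stage runnable offline.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_images Number of scenes (at least 3, to populate the split).
#' @param registry A [class_registry()] (default [toy_registry()]).
#' @param seed Integer seed for scenes and split.
#' @param spec Template [scene_spec()]; its seed is re-derived per image.
#' @return The `dataset_manifest`, invisibly; files land in `out_dir`.
#' @export
simulate_dataset <- function(out_dir, n_images, registry = toy_registry(),
                             seed = 1L, spec = scene_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  paths <- character(n_images)
  for (i in seq_len(n_images)) {
    s <- spec
    s$seed <- (seed * 1000L + i) %% .Machine$integer.max
    scene <- generate_scene(s, registry)
    ip <- file.path(out_dir, sprintf("scene_%03d.png", i))
    write_image(scene$image, ip)
    write_mask(scene$mask, mask_path_for(ip))
    paths[i] <- ip
  }
  manifest <- split_dataset(paths, seed)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  write_registry(registry, file.path(out_dir, "registry.csv"))
  catalogue <- toy_catalogue()
  write_catalogue(catalogue, file.path(out_dir, "catalogue.csv"))
  write_fcdb(toy_fcdb(catalogue), file.path(out_dir, "fcdb.csv"))
  invisible(manifest)
}
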