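test_that("image and mask PNG round-trips are lossless", {
  withr::with_seed(11, {
    dir <- withr::local_tempdir()
    for (trial in 1:3) {
      pair <- random_pair(h = 9, w = 7, n_cl = 6)
      ip <- file.path(dir, "img.png")
      mp <- file.path(dir, "img_mask.png")
      write_image(pair$image, ip)
      write_mask(pair$mask, mp)
      expect_identical(unclass(read_image(ip)), unclass(pair$image))
      expect_identical(unclass(read_mask(mp)), unclass(pair$mask))
    }
  })
})

test_that("read_image enforces the 3-channel contract", {
  dir <- withr::local_tempdir()
  grey <- file.path(dir, "grey.png")
  png::writePNG(matrix(runif(12), 3, 4), grey)
  expect_error(read_image(grey), "format error")
  expect_error(read_image(file.path(dir, "absent.png")), "I/O error")
  white <- file.path(dir, "white.png")
  png::writePNG(array(1, c(1, 1, 3)), white)
  img <- read_image(white)
  expect_identical(dim(img), c(1L, 1L, 3L))
  expect_true(all(img == 255L))
})

test_that("read_mask validates labels against the registry", {
  dir <- withr::local_tempdir()
  reg56 <- make_registry(sprintf("food%02d", 1:55))
  expect_identical(nrow(reg56), 56L)
  ok <- file.path(dir, "ok.png")
  png::writePNG(matrix(c(0, 55) / 255, 1, 2), ok)
  expect_s3_class(read_mask(ok, reg56), "label_mask")
  bad <- file.path(dir, "bad.png")
  png::writePNG(matrix(c(0, 56) / 255, 1, 2), bad)
  expect_error(read_mask(bad, reg56), "label 56")
  rgbf <- file.path(dir, "rgb.png")
  png::writePNG(array(runif(12), c(2, 2, 3)), rgbf)
  expect_error(read_mask(rgbf), "single-channel")
})

test_that("registry invariants are enforced", {
  base <- data.frame(
    index = 0:2, name = c("background", "a", "b"),
    r = c(0, 85, 170), g = c(0, 0, 0), b = c(0, 0, 0)
  )
  expect_s3_class(class_registry(base), "class_registry")
  dup_name <- base
  dup_name$name[3] <- "a"
  expect_error(class_registry(dup_name), "unique")
  dup_col <- base
  dup_col$r[3] <- 85
  expect_error(class_registry(dup_col), "unique")
  gap <- base
  gap$index[3] <- 5
  expect_error(class_registry(gap), "contiguous")
  nobg <- base
  nobg$name[1] <- "table"
  expect_error(class_registry(nobg), "background")
  expect_error(make_registry(c("a", "background")), "automatically")
})

test_that("split follows the round-half-up 70/10/20 rule", {
  m121 <- split_dataset(sprintf("i%03d.png", 1:121), seed = 4)
  expect_identical(
    as.integer(table(m121$subset)[c("training", "validation", "testing")]),
    c(85L, 12L, 24L)
  )
  m10 <- split_dataset(sprintf("i%02d.png", 1:10), seed = 4)
  expect_identical(
    as.integer(table(m10$subset)[c("training", "validation", "testing")]),
    c(7L, 1L, 2L)
  )
  expect_error(split_dataset(c("a.png", "b.png"), seed = 1), "at least 3")
})

test_that("split is deterministic, disjoint and complete", {
  paths <- sprintf("i%03d.png", 1:37)
  a <- split_dataset(paths, seed = 99)
  b <- split_dataset(paths, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a$subset, split_dataset(paths, seed = 100)$subset))
  # each image exactly once, sizes always consistent with the rounding rule
  withr::with_seed(5, {
    for (n in sample(3:200, 8)) {
      m <- split_dataset(sprintf("x%d.png", 1:n), seed = n)
      expect_setequal(m$image, sprintf("x%d.png", 1:n))
      sizes <- table(factor(m$subset, c("training", "validation", "testing")))
      expect_identical(as.integer(sizes[["validation"]]), as.integer(floor(0.1 * n + 0.5)))
      expect_identical(as.integer(sizes[["testing"]]), as.integer(floor(0.2 * n + 0.5)))
      expect_identical(as.integer(sum(sizes)), n)
    }
  })
})

test_that("mask_to_items matches a brute-force flood fill", {
  # all background -> no items
  empty <- label_mask(matrix(0L, 5, 5))
  expect_identical(nrow(mask_to_items(empty)), 0L)

  # two disjoint squares of one class -> two regions of that class
  m <- matrix(0L, 8, 8)
  m[1:2, 1:2] <- 5L
  m[6:7, 6:7] <- 5L
  items <- mask_to_items(label_mask(m))
  expect_identical(nrow(items), 2L)
  expect_true(all(items$class_index == 5L))
  expect_identical(sort(items$pixel_count), c(4L, 4L))

  # touching squares of different classes stay separate regions
  m2 <- matrix(0L, 4, 6)
  m2[2:3, 1:3] <- 2L
  m2[2:3, 4:6] <- 3L
  items2 <- mask_to_items(label_mask(m2))
  expect_identical(sort(items2$class_index), c(2L, 3L))

  # random masks: regions agree with the oracle and conserve the histogram
  withr::with_seed(21, {
    for (trial in 1:6) {
      mk <- random_mask(sample(4:10, 1), sample(4:10, 1), 4)
      got <- mask_to_items(mk)
      want <- oracle_regions(unclass(mk))
      key <- function(d) sort(paste(d$class_index, d$pixel_count))
      expect_identical(key(got), key(want))
      hist_got <- tapply(got$pixel_count, got$class_index, sum)
      hist_mask <- table(as.vector(unclass(mk)))
      for (k in names(hist_got)) {
        expect_identical(as.integer(hist_got[[k]]), as.integer(hist_mask[[k]]))
      }
      expect_identical(sum(got$pixel_count), sum(unclass(mk) != 0L))
    }
  })
})

test_that("manifest CSV round-trips and rejects unknown subsets", {
  dir <- withr::local_tempdir()
  m <- split_dataset(sprintf("i%d.png", 1:12), seed = 3)
  p <- file.path(dir, "manifest.csv")
  write_manifest(m, p)
  back <- read_manifest(p)
  expect_identical(back$subset, m$subset)
  writeLines("image,mask,subset\na.png,b.png,holdout", p)
  expect_error(read_manifest(p), "unknown subset")
})
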