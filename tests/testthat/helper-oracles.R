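# Independent brute-force oracles and small fixture builders.
# These deliberately share no code with the package implementation.

# Per-pixel double-loop confusion matrix
oracle_confusion <- function(truth, pred, n_cl) {
  cm <- matrix(0L, n_cl, n_cl)
  for (r in seq_len(nrow(truth))) {
    for (c in seq_len(ncol(truth))) {
      i <- truth[r, c] + 1L
      j <- pred[r, c] + 1L
      cm[i, j] <- cm[i, j] + 1L
    }
  }
  cm
}

# The four measures from explicit per-class loops
oracle_measures <- function(cm) {
  n_cl <- nrow(cm)
  t_i <- sapply(seq_len(n_cl), function(i) sum(cm[i, ]))
  p_j <- sapply(seq_len(n_cl), function(j) sum(cm[, j]))
  pa <- sum(diag(cm)) / sum(cm)
  acc <- c()
  iu_present <- c()
  fw <- 0
  for (i in seq_len(n_cl)) {
    if (t_i[i] > 0) acc <- c(acc, cm[i, i] / t_i[i])
    if (t_i[i] > 0 || p_j[i] > 0) {
      iu <- cm[i, i] / (t_i[i] + p_j[i] - cm[i, i])
      iu_present <- c(iu_present, iu)
      if (t_i[i] > 0) fw <- fw + t_i[i] * iu
    }
  }
  list(
    pixel_accuracy = pa,
    mean_accuracy = mean(acc),
    mean_iu = mean(iu_present),
    freq_weighted_iu = fw / sum(t_i)
  )
}

# Exponential recursive edit distance (insert / delete / substitute, unit costs)
oracle_lev <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  ra <- substr(a, 2, nchar(a))
  rb <- substr(b, 2, nchar(b))
  min(
    oracle_lev(ra, b) + 1L,
    oracle_lev(a, rb) + 1L,
    oracle_lev(ra, rb) + (substr(a, 1, 1) != substr(b, 1, 1))
  )
}

# 4-connected flood fill; returns per-region (class, pixel count)
oracle_regions <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  out <- list()
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (seen[r, c] || mask[r, c] == 0L) next
      k <- mask[r, c]
      stack <- list(c(r, c))
      seen[r, c] <- TRUE
      npix <- 0L
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        npix <- npix + 1L
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 && q[2] <= ncol(mask) &&
            !seen[q[1], q[2]] && mask[q[1], q[2]] == k) {
            seen[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
      out[[length(out) + 1L]] <- c(class_index = k, pixel_count = npix)
    }
  }
  if (!length(out)) {
    return(data.frame(class_index = integer(), pixel_count = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

random_string <- function(max_len, alphabet = letters[1:6]) {
  n <- sample(0:max_len, 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_mask <- function(h, w, n_cl) {
  label_mask(matrix(sample(0:(n_cl - 1L), h * w, replace = TRUE), h, w))
}

# Small random image/mask pair for augmentation tests
random_pair <- function(h = 12, w = 16, n_cl = 4) {
  img <- rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
  list(image = img, mask = random_mask(h, w, n_cl))
}

# A tiny on-disk dataset of n image/mask pairs; returns their image paths
write_tiny_pairs <- function(dir, n, h = 12, w = 16, n_cl = 4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(seq_len(n), function(i) {
    pair <- random_pair(h, w, n_cl)
    ip <- file.path(dir, sprintf("img%03d.png", i))
    write_image(pair$image, ip)
    write_mask(pair$mask, mask_path_for(ip))
    ip
  }, character(1))
}
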