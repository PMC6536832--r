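#' Build a pixel confusion matrix from a truth/prediction mask pair
#'
#' Entry `(i, j)` counts the pixels whose ground-truth class is `i` and whose
#' predicted class is `j` (classes 0-based; row/column 1 is class 0). The row
#' sums `t_i` are the total ground-truth pixels of each class, and the sum of
#' all entries equals the number of evaluated pixels.
#'
#' @param truth Ground-truth [label_mask()].
#' @param pred Predicted [label_mask()] of the same shape.
#' @param n_cl Number of classes including the background.
#' @return Integer `n_cl x n_cl` matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, pred, n_cl) {
  stopifnot(inherits(truth, "label_mask"), inherits(pred, "label_mask"))
  if (!identical(dim(truth), dim(pred))) stop("truth and prediction shapes differ")
  n_cl <- as.integer(n_cl)
  if (any(truth >= n_cl) || any(pred >= n_cl)) {
    stop("mask contains a label >= n_cl")
  }
  counts <- tabulate(
    as.vector(unclass(truth)) * n_cl + as.vector(unclass(pred)) + 1L,
    nbins = n_cl * n_cl
  )
  cm <- matrix(counts, nrow = n_cl, ncol = n_cl, byrow = TRUE)
  confusion_matrix(cm)
}

#' Construct a confusion matrix object from raw counts
#' @param counts Square matrix of non-negative counts, `n_ij` = pixels of
#'   true class `i` predicted as `j`.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square")
  if (any(counts < 0)) stop("confusion matrix entries must be >= 0")
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Add confusion matrices (pooling across images)
#' @param e1,e2 `confusion_matrix` objects of equal size.
#' @return Their elementwise sum.
#' @export
"+.confusion_matrix" <- function(e1, e2) {
  confusion_matrix(unclass(e1) + unclass(e2))
}

cm_parts <- function(cm) {
  cm <- unclass(cm)
  list(
    diag = diag(cm),
    t_i = rowSums(cm),  # ground-truth pixels per class
    p_j = colSums(cm),  # predicted pixels per class
    total = sum(cm)
  )
}

#' Pixel accuracy
#'
#' Fraction of all pixels classified correctly:
#' `sum_i n_ii / sum_i t_i`.
#'
#' @param cm A `confusion_matrix`.
#' @return Proportion in `[0, 1]`.
#' @export
pixel_accuracy <- function(cm) {
  p <- cm_parts(cm)
  if (p$total == 0) stop("empty confusion matrix")
  sum(p$diag) / p$total
}

#' Mean (per-class) accuracy
#'
#' Unweighted mean of per-class recall `n_ii / t_i` over the classes present
#' in the ground truth (`t_i > 0`); classes with no true pixels are excluded
#' so the mean never divides by zero.
#'
#' @inheritParams pixel_accuracy
#' @return Proportion in `[0, 1]`.
#' @export
mean_accuracy <- function(cm) {
  p <- cm_parts(cm)
  keep <- p$t_i > 0
  if (!any(keep)) stop("no class present in the ground truth")
  mean(p$diag[keep] / p$t_i[keep])
}

per_class_iu <- function(p) {
  denom <- p$t_i + p$p_j - p$diag
  ifelse(denom > 0, p$diag / denom, NA_real_)
}

#' Mean Intersection over Union
#'
#' Unweighted mean of per-class IU, `n_ii / (t_i + sum_j n_ji - n_ii)`, over
#' the classes present in the ground truth or the prediction. A class that is
#' only predicted (never true) contributes an IU of 0; a class absent from
#' both is excluded from the average.
#'
#' @inheritParams pixel_accuracy
#' @return Proportion in `[0, 1]`.
#' @export
mean_iu <- function(cm) {
  p <- cm_parts(cm)
  iu <- per_class_iu(p)
  keep <- (p$t_i + p$p_j) > 0
  if (!any(keep)) stop("empty confusion matrix")
  mean(iu[keep])
}

#' Frequency-weighted Intersection over Union
#'
#' Per-class IU weighted by each class's ground-truth pixel count:
#' `(sum_k t_k)^-1 sum_i t_i n_ii / (t_i + sum_j n_ji - n_ii)`.
#'
#' @inheritParams pixel_accuracy
#' @return Proportion in `[0, 1]`.
#' @export
freq_weighted_iu <- function(cm) {
  p <- cm_parts(cm)
  if (p$total == 0) stop("empty confusion matrix")
  iu <- per_class_iu(p)
  keep <- p$t_i > 0
  sum(p$t_i[keep] * iu[keep]) / sum(p$t_i)
}

#' All four segmentation measures of a confusion matrix
#' @inheritParams pixel_accuracy
#' @return Tibble with columns `pixel_accuracy`, `mean_accuracy`, `mean_iu`,
#'   `freq_weighted_iu`, each a proportion in `[0, 1]`.
#' @export
seg_report <- function(cm) {
  tibble::tibble(
    pixel_accuracy = pixel_accuracy(cm),
    mean_accuracy = mean_accuracy(cm),
    mean_iu = mean_iu(cm),
    freq_weighted_iu = freq_weighted_iu(cm)
  )
}

#' Evaluate predicted masks against a manifest subset
#'
#' Pools one global confusion matrix over all listed image/mask pairs (the
#' sum of the per-image matrices, i.e. pixel-level pooling rather than a mean
#' of per-image scores) and computes the four measures on it. The background
#' is included as a class.
#'
#' @param manifest A `dataset_manifest`.
#' @param pred_dir Directory holding one predicted mask per listed image,
#'   named like the ground-truth mask file.
#' @param registry The [class_registry()]; fixes `n_cl`.
#' @param subset Which subset to evaluate (default `"testing"`).
#' @return List with `report` (see [seg_report()]) and the pooled
#'   `confusion` matrix.
#' @export
evaluate_segmentation <- function(manifest, pred_dir, registry, subset = "testing") {
  stopifnot(inherits(manifest, "dataset_manifest"))
  rows <- manifest[manifest$subset == subset, ]
  if (nrow(rows) == 0) stop("no images in subset '", subset, "'")
  n_cl <- nrow(registry)
  cm <- confusion_matrix(matrix(0L, n_cl, n_cl))
  for (i in seq_len(nrow(rows))) {
    pred_path <- file.path(pred_dir, basename(rows$mask[i]))
    if (!file.exists(pred_path)) {
      stop("missing prediction for image ", rows$image[i], ": ", pred_path)
    }
    truth <- read_mask(rows$mask[i], registry)
    pred <- read_mask(pred_path, registry)
    cm <- cm + confusion(truth, pred, n_cl)
  }
  list(report = seg_report(cm), confusion = cm)
}
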