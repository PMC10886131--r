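# Pixel confusion counts and the derived segmentation metrics: mean
# intersection-over-union, precision and recall (macro-averaged over classes
# by default), plus throughput measurement and qualitative overlays.

#' Empty confusion matrix
#' @param n_classes number of classes including background.
#' @export
empty_confusion <- function(n_classes = 3L) {
  matrix(0, n_classes, n_classes,
         dimnames = list(truth = seq_len(n_classes) - 1L,
                         pred = seq_len(n_classes) - 1L))
}

#' Accumulate pixel confusion counts
#'
#' `cm[t, p]` counts pixels of true class `t` predicted as `p`. Accumulation
#' is associative over images, so batches may be pooled in any order.
#'
#' @param pred,truth integer arrays of equal shape with values in
#'   `0..n_classes-1`.
#' @param cm matrix to accumulate into (created when `NULL`).
#' @param n_classes class count when `cm` is `NULL`.
#' @return the updated confusion matrix.
#' @export
accumulate_confusion <- function(pred, truth, cm = NULL, n_classes = 3L) {
  if (!identical(dim(pred), dim(truth)) && length(pred) != length(truth))
    rds_shape_error("accumulate_confusion: pred and truth shapes differ")
  if (is.null(cm)) cm <- empty_confusion(n_classes)
  k <- nrow(cm)
  if (any(pred < 0 | pred >= k) || any(truth < 0 | truth >= k))
    rds_label_error(sprintf("accumulate_confusion: class index outside 0..%d", k - 1L))
  counts <- tabulate(as.integer(truth) * k + as.integer(pred) + 1L, nbins = k * k)
  cm + matrix(counts, k, k, byrow = TRUE, dimnames = dimnames(cm))
}

per_class_counts <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  list(tp = tp, fp = fp, fn = fn)
}

#' Mean intersection over union
#'
#' Mean over classes of `TP / (TP + FP + FN)`. Classes absent from both truth
#' and prediction (zero denominator) are excluded from the mean rather than
#' scored zero.
#'
#' @param cm confusion matrix from [accumulate_confusion()].
#' @return MIoU in `[0, 1]`.
#' @export
miou <- function(cm) {
  if (sum(cm) == 0) rds_metric_error("miou: empty confusion matrix")
  x <- per_class_counts(cm)
  denom <- x$tp + x$fp + x$fn
  valid <- denom > 0
  if (!any(valid)) rds_metric_error("miou: no class present in truth or prediction")
  mean(x$tp[valid] / denom[valid])
}

#' Macro precision and recall
#'
#' Per-class precision `TP/(TP+FP)` and recall `TP/(TP+FN)`; the returned
#' scalars average over classes with a defined value. `average =
#' "foreground_only"` drops class 0 from the macro mean.
#'
#' @param cm confusion matrix.
#' @param average `"macro"` over all classes or `"foreground_only"`.
#' @return list with `precision`, `recall` and a `per_class` data frame.
#' @export
precision_recall <- function(cm, average = c("macro", "foreground_only")) {
  average <- match.arg(average)
  if (sum(cm) == 0) rds_metric_error("precision_recall: empty confusion matrix")
  x <- per_class_counts(cm)
  prec <- ifelse(x$tp + x$fp > 0, x$tp / (x$tp + x$fp), NA_real_)
  rec <- ifelse(x$tp + x$fn > 0, x$tp / (x$tp + x$fn), NA_real_)
  keep <- if (average == "macro") seq_along(prec) else seq_along(prec)[-1]
  list(precision = mean(prec[keep], na.rm = TRUE),
       recall = mean(rec[keep], na.rm = TRUE),
       per_class = data.frame(class = seq_along(prec) - 1L,
                              precision = prec, recall = rec))
}

#' Measure single-image inference throughput
#'
#' Wall-clock mean over `n_frames` single-image forward passes after
#' `warmup` passes. Hardware dependent; reported for context only.
#'
#' @param model an `rds_model`.
#' @param image_size input side in pixels (multiple of 32).
#' @param n_frames timed passes (>= 1).
#' @param warmup untimed passes.
#' @return frames per second (scalar).
#' @export
measure_fps <- function(model, image_size = 224L, n_frames = 10L, warmup = 2L) {
  if (n_frames < 1) rds_spec_error("measure_fps: n_frames must be >= 1")
  x <- array(stats::rnorm(image_size * image_size * 3), dim = c(image_size, image_size, 3L, 1L))
  for (i in seq_len(warmup)) forward(model, x)
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(n_frames)) forward(model, x)
  dt <- proc.time()[["elapsed"]] - t0
  n_frames / max(dt, 1e-9)
}

#' Class overlay for qualitative inspection
#'
#' Alpha-blends corn pixels green and weed pixels red over the RGB image;
#' background is untouched.
#'
#' @param image `(H, W, 3)` array, 0-255.
#' @param mask `H x W` class-index matrix.
#' @param alpha blend weight of the class color.
#' @return `(H, W, 3)` array, 0-255.
#' @export
render_overlay <- function(image, mask, alpha = 0.5) {
  if (inherits(image, "labeled_scene")) {
    mask <- image$mask
    image <- image$image
  }
  cols <- list(`1` = c(0, 255, 0), `2` = c(255, 0, 0))
  out <- image
  for (cl in names(cols)) {
    sel <- mask == as.integer(cl)
    if (!any(sel)) next
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[sel] <- (1 - alpha) * pl[sel] + alpha * cols[[cl]][ch]
      out[, , ch] <- pl
    }
  }
  out
}

#' Side-by-side comparison panel (image | truth overlay | prediction overlay)
#'
#' @param image `(H, W, 3)` array.
#' @param truth,pred class-index matrices.
#' @param sep separator width in pixels (white).
#' @return `(H, 3W + 2 sep, 3)` array, 0-255.
#' @export
render_panel <- function(image, truth, pred, sep = 4L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  panel <- array(255, dim = c(H, 3L * W + 2L * sep, 3L))
  panel[, seq_len(W), ] <- image
  panel[, W + sep + seq_len(W), ] <- render_overlay(image, truth)
  panel[, 2L * (W + sep) + seq_len(W), ] <- render_overlay(image, pred)
  panel
}

#' Write an RGB array as PNG
#' @param image `(H, W, 3)` array, 0-255.
#' @param path output file.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}
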