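#' Precision, recall and F1 from detection counts
#'
#' Works for either instance counts (e.g. how many stalks were recognised
#' as stalks) or pixel counts — the caller chooses what TP/FP/FN mean.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A one-row tibble with `precision`, `recall`, `f1`.
#' @examples
#' precision_recall_f1(tp = 335, fp = 1, fn = 0)  # stalk confusion counts
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0 || tp + fn == 0) {
    stop(undefined_metric_error("precision/recall undefined: zero denominator"))
  }
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  tibble::tibble(precision = p, recall = r, f1 = 2 * p * r / (p + r))
}

#' Pixel confusion matrix between two label masks
#'
#' @param truth,pred [label_mask()]s of identical dimensions.
#' @param classes Class labels, background first; default `0:2`.
#' @return A `(k+1) x (k+1)` count matrix, rows = true class, columns =
#'   predicted class.
#' @export
pixel_confusion <- function(truth, pred, classes = 0:2) {
  truth <- label_mask(truth); pred <- label_mask(pred)
  stopifnot(all(dim(truth) == dim(pred)))
  as.matrix(table(
    true = factor(as.vector(unclass(truth)), levels = classes),
    pred = factor(as.vector(unclass(pred)), levels = classes)
  ))
}

#' Segmentation quality: MIoU, MPA and PA
#'
#' Mean intersection-over-union, mean per-class pixel accuracy, and overall
#' pixel accuracy over a confusion matrix of k object classes plus
#' background. Per class i, IoU is `p_ii / (row_i + col_i - p_ii)` and
#' class accuracy is `p_ii / row_i`; the means run over all k+1 classes
#' including background by default (set `include_background = FALSE` to
#' average over the object classes only).
#'
#' @param p A square confusion count matrix (true in rows, predicted in
#'   columns), background in the first row/column.
#' @param include_background Include the background class in the means.
#' @return A single number in `[0, 1]`.
#' @export
miou <- function(p, include_background = TRUE) {
  p <- check_confusion(p, include_background)
  iou <- diag(p) / (rowSums(p) + colSums(p) - diag(p))
  if (anyNA(iou) || any(!is.finite(iou))) {
    stop(undefined_metric_error("MIoU undefined: a class has no pixels"))
  }
  mean(iou)
}

#' @rdname miou
#' @export
mpa <- function(p, include_background = TRUE) {
  p <- check_confusion(p, include_background)
  acc <- diag(p) / rowSums(p)
  if (anyNA(acc) || any(!is.finite(acc))) {
    stop(undefined_metric_error("MPA undefined: a class has no true pixels"))
  }
  mean(acc)
}

#' @rdname miou
#' @export
pa <- function(p, include_background = TRUE) {
  p <- check_confusion(p, include_background)
  if (sum(p) == 0) stop(undefined_metric_error("PA undefined: empty confusion"))
  sum(diag(p)) / sum(p)
}

check_confusion <- function(p, include_background = TRUE) {
  p <- as.matrix(p)
  stopifnot(nrow(p) == ncol(p), all(p >= 0))
  if (!include_background && nrow(p) > 1L) p <- p[-1L, -1L, drop = FALSE]
  p
}

#' Grading accuracy: mean of per-grade correct rates
#'
#' The headline grading score: the unweighted average of each grade's
#' correct-classification rate, as a percentage. Reported to two decimals
#' with half-up rounding, matching how such tables are printed.
#'
#' @param total,correct Length-3 vectors of per-grade totals `N_i` and
#'   correct counts `n_i`.
#' @return The accuracy percentage (2 decimals), with the per-grade correct
#'   rates (percent, 2 decimals) attached as attribute `rates`.
#' @examples
#' grading_accuracy(c(50, 50, 50), c(49, 47, 46))  # 94.67
#' @export
grading_accuracy <- function(total, correct) {
  stopifnot(length(total) == length(correct), all(total > 0),
            all(correct >= 0), all(correct <= total))
  rates <- 100 * correct / total
  structure(round_half_up(mean(rates), 2),
            rates = round_half_up(rates, 2))
}

#' Round half away from zero
#'
#' Printed tables in this domain use conventional half-up rounding, not the
#' half-even rounding of [round()].
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Evaluate predicted masks against ground truth
#'
#' Convenience wrapper: accumulates one pixel confusion matrix over pairs
#' of masks (micro-aggregation; set `macro = TRUE` to average the metrics
#' per image instead) and reports MIoU, MPA, PA and per-class IoU.
#'
#' @param truth,pred Lists of [label_mask()]s (or vectors of PNG paths).
#' @param include_background Passed to [miou()] and friends.
#' @param macro Average per-image metrics instead of pooling pixels.
#' @return A one-row tibble: `miou`, `mpa`, `pa`, `iou_cap`, `iou_stalk`.
#' @export
evaluate_masks <- function(truth, pred, include_background = TRUE, macro = FALSE) {
  as_mask <- function(x) if (is.character(x)) read_label_mask(x) else label_mask(x)
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  confs <- purrr::map2(truth, pred, function(a, b) {
    pixel_confusion(as_mask(a), as_mask(b))
  })
  one <- function(p) {
    iou <- diag(p) / (rowSums(p) + colSums(p) - diag(p))
    tibble::tibble(
      miou = miou(p, include_background), mpa = mpa(p, include_background),
      pa = pa(p), iou_cap = iou[2L], iou_stalk = iou[3L]
    )
  }
  if (macro) {
    dplyr::summarise(dplyr::bind_rows(lapply(confs, one)),
                     dplyr::across(dplyr::everything(), mean))
  } else {
    one(Reduce(`+`, confs))
  }
}

undefined_metric_error <- function(msg) {
  structure(
    class = c("mushgrade_undefined_metric", "error", "condition"),
    list(message = msg, call = NULL)
  )
}
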