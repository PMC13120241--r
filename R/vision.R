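#' Intersection over union of two boxes
#'
#' Boxes are `(x1, y1, x2, y2)` in pixel coordinates, origin top-left,
#' with `x1 < x2`, `y1 < y2`.
#'
#' @param a,b numeric vectors `c(x1, y1, x2, y2)`.
#' @return overlap ratio in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  stopifnot(a[3] > a[1], a[4] > a[2], b[3] > b[1], b[4] > b[2])
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Greedy non-maximum suppression
#'
#' Detections are sorted by confidence (descending; ties broken by input
#' order) and visited greedily: a detection is kept unless it overlaps a
#' previously kept detection of the same class with IoU above the
#' threshold. Deterministic for a given input order.
#'
#' @param detections data.frame with columns `x1, y1, x2, y2, cls, conf`.
#' @param iou_threshold suppression threshold in `(0, 1)`.
#' @return the kept subset, in decreasing confidence order.
#' @export
nms <- function(detections, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  if (is.null(detections) || nrow(detections) == 0) return(detections)
  ord <- order(-detections$conf, seq_len(nrow(detections)))
  det <- detections[ord, , drop = FALSE]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    box_i <- as.numeric(det[i, c("x1", "y1", "x2", "y2")])
    suppressed <- FALSE
    for (j in which(keep)) {
      if (det$cls[j] != det$cls[i]) next
      if (iou(box_i, as.numeric(det[j, c("x1", "y1", "x2", "y2")])) > iou_threshold) {
        suppressed <- TRUE
        break
      }
    }
    keep[i] <- !suppressed
  }
  det[keep, , drop = FALSE]
}

#' Reduce detections to an image-level ripeness label
#'
#' Implements the detection-to-classification reduction: boxes below the
#' confidence threshold are filtered out, overlapping boxes are merged with
#' NMS, and the image is labelled `ripe` if any ripe box survives, else
#' `unripe` (including when nothing is detected at all). The confidence of
#' a `ripe` label is the best surviving ripe confidence; for `unripe` it is
#' `1 - (best filtered-out ripe confidence, 0 if none)`, floored at the
#' best surviving unripe confidence. A missing image (night sample) yields
#' an unavailable prediction.
#'
#' @param detections detection data.frame, or `NULL` when no image exists.
#' @param conf_threshold minimum box confidence (default 0.8).
#' @param iou_threshold NMS threshold.
#' @param sample_id id attached to the prediction record.
#' @return one-row prediction data.frame (see [prediction()]).
#' @export
image_label <- function(detections, conf_threshold = 0.8, iou_threshold = 0.5,
                        sample_id = NA_character_) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1)
  if (is.null(detections)) {
    return(prediction(sample_id, NA_character_, NA_real_, "image", available = FALSE))
  }
  kept0 <- detections[detections$conf >= conf_threshold, , drop = FALSE]
  dropped <- detections[detections$conf < conf_threshold, , drop = FALSE]
  kept <- nms(kept0, iou_threshold)
  ripe <- kept[kept$cls == "ripe", , drop = FALSE]
  if (nrow(ripe) > 0) {
    prediction(sample_id, "ripe", max(ripe$conf), "image")
  } else {
    ripe_cand <- if (any(dropped$cls == "ripe")) max(dropped$conf[dropped$cls == "ripe"]) else 0
    floor_conf <- if (any(kept$cls == "unripe")) max(kept$conf[kept$cls == "unripe"]) else 0
    prediction(sample_id, "unripe", max(1 - ripe_cand, floor_conf), "image")
  }
}

#' Accuracy with and without unavailable samples
#'
#' Night samples have no image prediction. `available_only` computes
#' accuracy over available samples only; `all_counting_missing_wrong`
#' projects the result to all samples, counting every unavailable sample
#' as a misclassification. All-mode accuracy can therefore never exceed
#' the available-only accuracy.
#'
#' @param predictions prediction data.frame (rows aligned with `labels`),
#'   with an `available` column.
#' @param labels true labels.
#' @param mode accounting mode.
#' @return accuracy in `[0, 1]`; `NA` for `available_only` when nothing is
#'   available.
#' @export
project_accuracy <- function(predictions, labels,
                             mode = c("available_only", "all_counting_missing_wrong")) {
  mode <- match.arg(mode)
  stopifnot(nrow(predictions) == length(labels))
  avail <- predictions$available
  correct <- avail & predictions$label == as.character(labels)
  if (mode == "available_only") {
    if (!any(avail)) {
      warning("no available samples")
      return(NA_real_)
    }
    sum(correct) / sum(avail)
  } else {
    sum(correct) / length(labels)
  }
}
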