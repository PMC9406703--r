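#' Greedy matching of detections to ground-truth boxes
#'
#' Detections are taken in descending confidence order (capped at
#' `max_detections` per image); each is matched to the still-unmatched
#' ground truth with the highest IoU if that IoU reaches `iou_threshold`,
#' otherwise it is a false positive. Every ground truth is matched at most
#' once.
#'
#' @param detections list of detections (`list(box, confidence)`).
#' @param ground_truths list of `bbox` objects.
#' @param iou_threshold minimum IoU for a match.
#' @param max_detections cap on detections kept per image.
#' @return `list(det_tp, det_match, det_conf, gt_matched, iou_threshold)`:
#'   per-kept-detection TP flags, matched ground-truth index (NA for FP),
#'   confidences, and per-ground-truth matched flags.
#' @export
match_detections <- function(detections, ground_truths, iou_threshold = 0.5,
                             max_detections = 100L) {
  conf <- vapply(detections, `[[`, numeric(1), "confidence")
  ord <- order(-conf)
  if (length(ord) > max_detections) ord <- ord[seq_len(max_detections)]
  dets <- detections[ord]
  n_d <- length(dets); n_g <- length(ground_truths)
  det_tp <- logical(n_d)
  det_match <- rep(NA_integer_, n_d)
  gt_matched <- logical(n_g)
  for (i in seq_len(n_d)) {
    if (n_g == 0) break
    ious <- vapply(ground_truths, iou, numeric(1), a = dets[[i]]$box)
    ious[gt_matched] <- -1
    j <- which.max(ious)               # ties: lowest ground-truth index
    if (length(j) && ious[j] >= iou_threshold) {
      det_tp[i] <- TRUE
      det_match[i] <- j
      gt_matched[j] <- TRUE
    }
  }
  list(det_tp = det_tp, det_match = det_match,
       det_conf = vapply(dets, `[[`, numeric(1), "confidence"),
       gt_matched = gt_matched, iou_threshold = iou_threshold)
}

#' COCO-style average precision from pooled match results
#'
#' Pools the TP/FP flags of all images, ranks them by descending
#' confidence, builds the precision-recall curve and reports the 101-point
#' interpolated AP (mean over recall grid `0, 0.01, ..., 1` of the
#' right-to-left running-maximum precision).
#'
#' @param tp logical TP flags of all detections.
#' @param conf matching confidences.
#' @param n_gt total number of ground truths (> 0).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(tp, conf, n_gt) {
  if (n_gt <= 0) stop("average_precision: no ground truths")
  if (length(tp) == 0) return(0)
  ord <- order(-conf)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  # interpolated precision: running max from the right
  p_interp <- rev(cummax(rev(precision)))
  grid <- seq(0, 1, by = 0.01)
  pr <- vapply(grid, function(r) {
    k <- which(recall >= r - 1e-12)
    if (length(k) == 0) 0 else p_interp[k[1]]
  }, numeric(1))
  mean(pr)
}

#' AP and AR over a range of IoU thresholds
#'
#' Computes average precision and average recall at each IoU threshold in
#' `iou_range` (default 0.50 to 0.95 in steps of 0.05) with at most
#' `max_detections` detections per image, and averages them over the
#' range. AR at one threshold is the fraction of ground truths matched
#' after the cap.
#'
#' @param dataset list of images, each `list(detections, ground_truths)`.
#' @param iou_range IoU thresholds.
#' @param max_detections per-image cap.
#' @return A list of class `detection_metrics`: `ap_at_iou`, `ar_at_iou`
#'   (named by threshold), `mean_ap_range`, `ar_range`, `max_detections`.
#' @export
ap_ar_over_range <- function(dataset, iou_range = seq(0.5, 0.95, by = 0.05),
                             max_detections = 100L) {
  n_gt <- sum(vapply(dataset, function(im) length(im$ground_truths), integer(1)))
  if (n_gt == 0) stop("ap_ar_over_range: dataset has no ground truths")
  ap <- ar <- stats::setNames(numeric(length(iou_range)),
                              formatC(iou_range, format = "f", digits = 2))
  for (t in seq_along(iou_range)) {
    tps <- logical(0); confs <- numeric(0); matched <- 0L
    for (im in dataset) {
      m <- match_detections(im$detections, im$ground_truths, iou_range[t],
                            max_detections)
      tps <- c(tps, m$det_tp)
      confs <- c(confs, m$det_conf)
      matched <- matched + sum(m$gt_matched)
    }
    ap[t] <- average_precision(tps, confs, n_gt)
    ar[t] <- matched / n_gt
  }
  structure(list(ap_at_iou = ap, ar_at_iou = ar,
                 mean_ap_range = mean(ap), ar_range = mean(ar),
                 max_detections = as.integer(max_detections)),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("AP (IoU %s): %.3f | mean AP (IoU %s-%s): %.3f | AR (IoU %s-%s): %.3f | maxDet: %d\n",
              names(x$ap_at_iou)[1], x$ap_at_iou[1],
              names(x$ap_at_iou)[1], names(x$ap_at_iou)[length(x$ap_at_iou)],
              x$mean_ap_range,
              names(x$ar_at_iou)[1], names(x$ar_at_iou)[length(x$ar_at_iou)],
              x$ar_range, x$max_detections))
  invisible(x)
}

#' Confidence-threshold sweep into image-level binary classification
#'
#' Translates detector output into image-level cyst / no-cyst calls: an
#' image is predicted positive at threshold `t` iff it has at least one
#' detection with confidence `>= t`. Reports accuracy, precision,
#' sensitivity, specificity and F1 per threshold; the positive-prediction
#' count is non-increasing in `t`. Specificity is `NA` (with a warning)
#' when the dataset has no negative images.
#'
#' @param dataset list of images (`list(detections, ground_truths)`);
#'   negatives are images with no ground truths.
#' @param thresholds confidence thresholds, sorted ascending.
#' @return A data frame with one row per threshold.
#' @export
image_level_sweep <- function(dataset, thresholds) {
  thresholds <- sort(thresholds)
  truth_pos <- vapply(dataset, function(im) length(im$ground_truths) > 0,
                      logical(1))
  max_conf <- vapply(dataset, function(im) {
    if (length(im$detections) == 0) -Inf else
      max(vapply(im$detections, `[[`, numeric(1), "confidence"))
  }, numeric(1))
  if (!any(!truth_pos)) {
    warning("image_level_sweep: no negative images; specificity undefined")
  }
  rows <- lapply(thresholds, function(t) {
    pred_pos <- max_conf >= t
    tp <- sum(pred_pos & truth_pos); fp <- sum(pred_pos & !truth_pos)
    fn <- sum(!pred_pos & truth_pos); tn <- sum(!pred_pos & !truth_pos)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
      2 * prec * sens / (prec + sens)
    } else NA_real_
    data.frame(threshold = t, n_predicted_positive = sum(pred_pos),
               accuracy = (tp + tn) / length(dataset), precision = prec,
               sensitivity = sens, specificity = spec, f1 = f1)
  })
  do.call(rbind, rows)
}
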