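# Evaluation protocol: IoU matching, detection-level counts, one-vs-rest
# classification metrics, Recall@tau, COCO-style AP/mAP.

#' Intersection over union of two boxes
#'
#' Boxes are `c(x, y, w, h)` in absolute pixels under the 0-based,
#' half-open convention, so the area of a box is exactly `w * h`.
#'
#' @param a,b Numeric length-4 vectors `c(x, y, w, h)`.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 10, 10))  # 50 / 150
#' @export
iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) return(0)
  inter / union
}

# IoU matrix between two box tables (rows of x,y,w,h); n_gt x n_det
iou_matrix <- function(gt, det) {
  if (!nrow(gt) || !nrow(det)) return(matrix(0, nrow(gt), nrow(det)))
  gx2 <- gt$x + gt$w; gy2 <- gt$y + gt$h
  dx2 <- det$x + det$w; dy2 <- det$y + det$h
  ix <- pmax(0, outer(gx2, dx2, pmin) - outer(gt$x, det$x, pmax))
  iy <- pmax(0, outer(gy2, dy2, pmin) - outer(gt$y, det$y, pmax))
  inter <- ix * iy
  union <- outer(gt$w * gt$h, det$w * det$h, "+") - inter
  out <- inter / union
  out[union <= 0] <- 0
  out
}

ensure_det_ids <- function(det) {
  if (is.null(det$id)) det$id <- seq_len(nrow(det))
  if (is.null(det$image_id)) det$image_id <- rep(1L, nrow(det))
  det
}

ensure_gt_ids <- function(gt) {
  if (is.null(gt$id)) gt$id <- seq_len(nrow(gt))
  if (is.null(gt$image_id)) gt$image_id <- rep(1L, nrow(gt))
  gt
}

#' Match detections to ground-truth boxes
#'
#' Greedy one-to-one matching in descending confidence order (the COCO
#' convention): each detection claims the still-unmatched ground truth
#' of the same image with the highest IoU at or above the threshold;
#' IoU ties are broken toward the lower ground-truth id. Unless
#' `class_agnostic`, a detection may only match a ground truth of its
#' own category. Leftover detections are false positives, leftover
#' ground truths false negatives.
#'
#' @param ground_truths Data frame with `x, y, w, h` and optionally
#'   `id`, `image_id`, `category`.
#' @param detections Data frame with `x, y, w, h, confidence` and
#'   optionally `id`, `image_id`, `category`.
#' @param iou_threshold Minimum IoU for a valid pair (default 0.5).
#' @param class_agnostic Ignore category labels when matching.
#' @return An object of class `match_result`: `pairs` (det_id, gt_id,
#'   iou), `unmatched_detections`, `unmatched_ground_truths`, plus the
#'   matching settings and input sizes.
#' @export
match_detections <- function(ground_truths, detections,
                             iou_threshold = 0.5, class_agnostic = FALSE) {
  gt <- ensure_gt_ids(ground_truths)
  det <- ensure_det_ids(detections)
  pairs <- data.frame(det_id = integer(), gt_id = integer(), iou = numeric())
  matched_gt <- logical(nrow(gt))
  if (nrow(det) && nrow(gt)) {
    ord <- order(-det$confidence, det$id)
    M <- iou_matrix(gt, det)
    for (j in ord) {
      ok <- !matched_gt &
        gt$image_id == det$image_id[j] &
        M[, j] >= iou_threshold
      if (!class_agnostic && !is.null(det$category) && !is.null(gt$category) &&
          !is.na(det$category[j])) {
        ok <- ok & gt$category == det$category[j]
      }
      if (!any(ok)) next
      cand <- which(ok)
      best <- cand[order(-M[cand, j], gt$id[cand])][1]
      matched_gt[best] <- TRUE
      pairs <- rbind(pairs, data.frame(det_id = det$id[j],
                                       gt_id = gt$id[best],
                                       iou = M[best, j]))
    }
  }
  structure(
    list(pairs = pairs,
         unmatched_detections = setdiff(det$id, pairs$det_id),
         unmatched_ground_truths = gt$id[!matched_gt],
         iou_threshold = iou_threshold,
         class_agnostic = class_agnostic,
         n_detections = nrow(det), n_ground_truths = nrow(gt)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> IoU>=%.2f%s: %d matched, %d FP, %d FN\n",
    x$iou_threshold, if (x$class_agnostic) " (class-agnostic)" else "",
    nrow(x$pairs), length(x$unmatched_detections),
    length(x$unmatched_ground_truths)))
  invisible(x)
}

#' Detection precision, recall and F1 from TP/FP/FN counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2PR / (P + R)`. A zero denominator yields 0 and sets the
#' `degenerate` flag rather than raising.
#'
#' @param tp,fp,fn Non-negative counts, or `tp` may be a
#'   [match_detections()] result from which the counts are taken.
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `degenerate`.
#' @examples
#' detection_prf(6303, 81, 361)  # Precision 0.9873, Recall 0.9458, F1 0.9661
#' @export
detection_prf <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "match_result")) {
    m <- tp
    tp <- nrow(m$pairs)
    fp <- length(m$unmatched_detections)
    fn <- length(m$unmatched_ground_truths)
  }
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * p * r, p + r)
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1,
       degenerate = (tp + fp == 0) || (tp + fn == 0) || (p + r == 0))
}

#' Macro (unweighted) average
#' @param x Numeric vector of per-class metric values.
#' @return Their unweighted mean.
#' @export
macro_average <- function(x) mean(x)

#' Support-weighted average
#' @param x Numeric vector of per-class metric values.
#' @param support Per-class sample counts.
#' @return `sum(x * support) / sum(support)`.
#' @export
weighted_average <- function(x, support) {
  if (length(x) != length(support)) stop("length mismatch")
  sum(x * support) / sum(support)
}

#' One-vs-rest classification metrics
#'
#' Per-class TP/FP/FN under the one-vs-rest formulation, with
#' precision, recall and F1 per class, overall accuracy (fraction of
#' correct predictions), macro averages (unweighted over the K
#' categories) and support-weighted averages (weights = true-label
#' counts). Zero-denominator metrics are 0 with a `degenerate` flag.
#'
#' @param true,pred Equal-length label vectors drawn from `categories`.
#' @param categories Category names in order, or a [category_map()].
#' @return Object of class `class_metrics`: `per_class` data frame,
#'   `accuracy`, `macro` and `weighted` (precision/recall/f1 lists),
#'   `n`.
#' @export
classification_metrics <- function(true, pred, categories = category_map()) {
  if (inherits(categories, "category_map")) categories <- categories$name
  if (length(true) != length(pred)) stop("label vectors differ in length")
  if (!all(c(true, pred) %in% categories)) {
    stop("labels outside the category map: ",
         paste(unique(setdiff(c(true, pred), categories)), collapse = ", "))
  }
  per <- lapply(categories, function(cc) {
    tp <- sum(true == cc & pred == cc)
    fp <- sum(pred == cc & true != cc)
    fn <- sum(true == cc & pred != cc)
    m <- detection_prf(tp, fp, fn)
    data.frame(category = cc, tp = tp, fp = fp, fn = fn,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               support = sum(true == cc), degenerate = m$degenerate,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(
    list(per_class = per,
         accuracy = mean(true == pred),
         macro = list(precision = macro_average(per$precision),
                      recall = macro_average(per$recall),
                      f1 = macro_average(per$f1)),
         weighted = list(
           precision = weighted_average(per$precision, per$support),
           recall = weighted_average(per$recall, per$support),
           f1 = weighted_average(per$f1, per$support)),
         n = length(true)),
    class = "class_metrics"
  )
}

#' @export
print.class_metrics <- function(x, digits = 4, ...) {
  cat("<class_metrics> n =", x$n, "\n")
  df <- x$per_class
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f1 <- round(df$f1, digits)
  print(df[, c("category", "precision", "recall", "f1", "support")],
        row.names = FALSE)
  cat(sprintf("accuracy %.4f | macro F1 %.4f | weighted F1 %.4f\n",
              x$accuracy, x$macro$f1, x$weighted$f1))
  invisible(x)
}

#' Class-agnostic recall at an IoU threshold
#'
#' Fraction of ground-truth boxes matched by any detection at
#' IoU >= `tau`, ignoring category labels (pure localization quality).
#'
#' @param ground_truths,detections Box tables as in
#'   [match_detections()].
#' @param tau IoU threshold (default 0.75).
#' @return List with `matched`, `total` and `recall`.
#' @export
recall_at_iou <- function(ground_truths, detections, tau = 0.75) {
  m <- match_detections(ground_truths, detections, iou_threshold = tau,
                        class_agnostic = TRUE)
  total <- m$n_ground_truths
  matched <- nrow(m$pairs)
  list(matched = matched, total = total,
       recall = if (total > 0) matched / total else 0)
}

#' COCO-style average precision for one category
#'
#' Sweeps the confidence threshold over the category's detections,
#' accumulating TP/FP under greedy IoU matching per image, and computes
#' 101-point interpolated AP (mean over recalls 0, 0.01, ..., 1 of the
#' maximum precision at or beyond each recall).
#'
#' @param ground_truths,detections Box tables as in
#'   [match_detections()]; `category` columns are required unless
#'   `category = NULL` (class-agnostic AP).
#' @param category Category name to score, or `NULL` for all boxes.
#' @param iou_threshold Matching threshold (default 0.5).
#' @return AP in `[0, 1]`, or `NA` when the category has no ground
#'   truth.
#' @export
average_precision <- function(ground_truths, detections, category = NULL,
                              iou_threshold = 0.5) {
  gt <- ensure_gt_ids(ground_truths)
  det <- ensure_det_ids(detections)
  if (!is.null(category)) {
    gt <- gt[gt$category == category, , drop = FALSE]
    det <- det[!is.na(det$category) & det$category == category, , drop = FALSE]
  }
  n_gt <- nrow(gt)
  if (n_gt == 0L) return(NA_real_)
  if (!nrow(det)) return(0)
  ord <- order(-det$confidence, det$id)
  det <- det[ord, , drop = FALSE]
  matched_gt <- logical(n_gt)
  is_tp <- logical(nrow(det))
  M <- iou_matrix(gt, det)
  for (j in seq_len(nrow(det))) {
    ok <- !matched_gt & gt$image_id == det$image_id[j] &
      M[, j] >= iou_threshold
    if (!any(ok)) next
    cand <- which(ok)
    best <- cand[order(-M[cand, j], gt$id[cand])][1]
    matched_gt[best] <- TRUE
    is_tp[j] <- TRUE
  }
  cum_tp <- cumsum(is_tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(is_tp)
  interpolate_ap(recall, precision)
}

# 101-point interpolation (COCO convention)
interpolate_ap <- function(recall, precision) {
  grid <- seq(0, 1, by = 0.01)
  # precision envelope: max precision at recall >= r
  ap <- vapply(grid, function(r) {
    p <- precision[recall >= r - 1e-12]
    if (length(p)) max(p) else 0
  }, 0)
  mean(ap)
}

#' Mean average precision over categories and IoU thresholds
#'
#' AP per category present in the ground truth, at IoU thresholds 0.50
#' to 0.95 in steps of 0.05 (standard COCO protocol). Categories absent
#' from the ground truth are excluded from the means with a note.
#'
#' @param ground_truths,detections Box tables with `category` columns.
#' @param categories Category names, or a [category_map()].
#' @param thresholds IoU thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @return List with `ap` (category x threshold matrix), `map50`,
#'   `map5095`, and `excluded` (categories without ground truth).
#' @export
map_range <- function(ground_truths, detections,
                      categories = category_map(),
                      thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (inherits(categories, "category_map")) categories <- categories$name
  present <- categories[categories %in% ground_truths$category]
  excluded <- setdiff(categories, present)
  ap <- matrix(NA_real_, length(present), length(thresholds),
               dimnames = list(present, sprintf("AP@%.2f", thresholds)))
  for (ci in seq_along(present)) {
    for (ti in seq_along(thresholds)) {
      ap[ci, ti] <- average_precision(ground_truths, detections,
                                      category = present[ci],
                                      iou_threshold = thresholds[ti])
    }
  }
  list(ap = ap,
       map50 = mean(ap[, which.min(abs(thresholds - 0.5))]),
       map5095 = mean(ap),
       excluded = excluded)
}

#' Assemble a full evaluation report
#'
#' Combines detection-level counts and P/R/F1 at the matching
#' threshold, class-agnostic Recall@tau, per-class one-vs-rest
#' classification metrics with macro and weighted aggregates over the
#' matched boxes, and COCO AP/mAP, in the layout of the standard
#' detection-evaluation and per-class-performance tables.
#'
#' @param ground_truths,detections Box tables with `category` columns;
#'   detections additionally need `confidence`.
#' @param categories A [category_map()] (or names).
#' @param iou_threshold Detection matching threshold (default 0.5).
#' @param recall_tau Threshold for the localization recall row
#'   (default 0.75).
#' @param compute_map Also compute COCO AP/mAP (default `TRUE`; the
#'   threshold sweep is the slow part).
#' @return Object of class `metrics_report`.
#' @export
build_report <- function(ground_truths, detections,
                         categories = category_map(),
                         iou_threshold = 0.5, recall_tau = 0.75,
                         compute_map = TRUE) {
  gt <- ensure_gt_ids(ground_truths)
  det <- ensure_det_ids(detections)
  m_agn <- match_detections(gt, det, iou_threshold, class_agnostic = TRUE)
  detection <- detection_prf(m_agn)
  detection$pred <- m_agn$n_detections
  detection$gt <- m_agn$n_ground_truths
  r_tau <- recall_at_iou(gt, det, tau = recall_tau)
  classification <- NULL
  if (!is.null(det$category) && nrow(m_agn$pairs)) {
    true_lab <- gt$category[match(m_agn$pairs$gt_id, gt$id)]
    pred_lab <- det$category[match(m_agn$pairs$det_id, det$id)]
    keep <- !is.na(pred_lab)
    classification <- classification_metrics(true_lab[keep], pred_lab[keep],
                                             categories)
  }
  ap <- if (compute_map) map_range(gt, det, categories) else NULL
  structure(
    list(detection = detection, recall_at_tau = r_tau,
         recall_tau = recall_tau, iou_threshold = iou_threshold,
         classification = classification, ap = ap),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  d <- x$detection
  cat(sprintf(
    "Detection (IoU >= %.2f): Pred %d  TP %d  FP %d  FN %d  P %.4f  R %.4f  F1 %.4f\n",
    x$iou_threshold, d$pred, d$tp, d$fp, d$fn,
    d$precision, d$recall, d$f1))
  cat(sprintf("Recall@%.2f: %d / %d = %.4f\n", x$recall_tau,
              x$recall_at_tau$matched, x$recall_at_tau$total,
              x$recall_at_tau$recall))
  if (!is.null(x$classification)) print(x$classification)
  if (!is.null(x$ap)) {
    cat(sprintf("mAP@50 %.4f | mAP@50:95 %.4f\n", x$ap$map50, x$ap$map5095))
  }
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#'
#' @param report A [build_report()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; writes `report.json`, `detection.csv` and,
#'   when present, `per_class.csv`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  det <- report$detection
  write.csv(data.frame(pred = det$pred, tp = det$tp, fp = det$fp,
                       fn = det$fn, precision = det$precision,
                       recall = det$recall, f1 = det$f1),
            file.path(dir, "detection.csv"), row.names = FALSE)
  if (!is.null(report$classification)) {
    cl <- report$classification
    per <- cl$per_class
    agg <- data.frame(
      category = c("Macro Avg", "Weighted Avg", "Accuracy"),
      tp = NA, fp = NA, fn = NA,
      precision = c(cl$macro$precision, cl$weighted$precision, NA),
      recall = c(cl$macro$recall, cl$weighted$recall, cl$accuracy),
      f1 = c(cl$macro$f1, cl$weighted$f1, NA),
      support = cl$n, degenerate = NA)
    write.csv(rbind(per, agg), file.path(dir, "per_class.csv"),
              row.names = FALSE)
  }
  json <- list(
    detection = report$detection,
    recall_at_tau = report$recall_at_tau,
    recall_tau = report$recall_tau,
    iou_threshold = report$iou_threshold)
  if (!is.null(report$classification)) {
    json$classification <- list(
      accuracy = report$classification$accuracy,
      macro = report$classification$macro,
      weighted = report$classification$weighted)
  }
  if (!is.null(report$ap)) {
    json$map50 <- report$ap$map50
    json$map5095 <- report$ap$map5095
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
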